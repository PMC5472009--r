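# Shared fixtures, built in code.

# One fixed-width ATOM record (standard PDB columns).
pdbLine <- function(serial, name, resid, chain, resno, x, y, z, b = 0,
                    elem = substr(name, 1, 1), record = "ATOM") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, " ", resid, chain, resno, " ",
          x, y, z, 1.00, b, elem)
}

# Minimal one-residue ALA PDB text (N, CA, C, O, CB).
alaPDB <- function(b = c(10, 20, 30, 40, 50)) {
  c(pdbLine(1, "N", "ALA", "A", 1, -0.525, 1.363, 0, b[1], "N"),
    pdbLine(2, "CA", "ALA", "A", 1, 0, 0, 0, b[2], "C"),
    pdbLine(3, "C", "ALA", "A", 1, 1.526, 0, 0, b[3], "C"),
    pdbLine(4, "O", "ALA", "A", 1, 2.216, -1.16, 0, b[4], "O"),
    pdbLine(5, "CB", "ALA", "A", 1, -0.54, -0.774, -1.205, b[5], "C"),
    "END")
}

writeLinesTmp <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# A bare structure with atoms placed exactly where a test needs them.
# `atoms` rows: name, resid, resno, x, y, z (chain A, elements derived from
# the first character of the name).
fakeStructure <- function(atoms, id = "fake") {
  el <- substr(atoms$name, 1, 1)
  el <- ifelse(el %in% c("C", "N", "O", "S"), el, "other")
  df <- data.frame(serial = seq_len(nrow(atoms)), name = atoms$name,
                   element = el, resno = atoms$resno, resid = atoms$resid,
                   chain = "A", insert = "", x = atoms$x, y = atoms$y,
                   z = atoms$z, bfactor = 0, stringsAsFactors = FALSE)
  df$channel <- df$element %in% c("C", "N", "O", "S")
  new("ProteinStructure", id = id, atoms = df, source = "synthetic")
}

# Residue whose frame is axis-aligned by construction:
# x = (1,0,0), z = (0,0,1), y = (0,1,0), origin = CB = (0,0,1).
axisResidue <- function(extra = NULL) {
  base <- data.frame(name = c("N", "CA", "C", "O", "CB"),
                     resid = "ALA", resno = 1,
                     x = c(1, 0, 0, -1, 0), y = c(0, 0, 1, -1, 0),
                     z = c(0, 0, 0, 0, 1), stringsAsFactors = FALSE)
  if (!is.null(extra)) base <- rbind(base, extra)
  fakeStructure(base)
}

# Tiny CNN used by gradient and saliency tests.
tinyNet <- function(dropout = 0, seed = 3, nClasses = 3) {
  buildVoxelNet(list(convSpec(2, 3), poolSpec(), denseSpec(5)),
                inputShape = c(2L, 6L, 6L, 6L), nClasses = nClasses,
                dropout = dropout, seed = seed)
}
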