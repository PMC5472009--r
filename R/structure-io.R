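# Reading, writing and interrogating protein structures.  Parsing and
# serialization of the fixed-width PDB format go through bio3d; the filters
# applied on top define which atoms take part in microenvironment boxes.

.classifyElement <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  fallback <- el == "" | is.na(el)
  if (any(fallback)) {
    # first alphabetic character of the atom name
    first <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", elety[fallback]))
    el[fallback] <- first
  }
  ifelse(el %in% c("C", "N", "O", "S"), el,
         ifelse(el %in% c("H", "D"), "H", "other"))
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records via bio3d and applies the package's filtering rules:
#' only the first model of multi-model files; HETATM records (including
#' waters) dropped; hydrogens dropped; alternate locations resolved by
#' keeping blank or "A" altloc; only the 20 standard residue types retained.
#' Atoms whose element is outside {C, N, O, S} are kept but flagged as
#' non-channel.
#'
#' @param path Path to a PDB file.
#' @param id Structure identifier; defaults to the file name without suffix.
#' @return A [ProteinStructure-class].
#' @export
readPDB <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0) stop("no ATOM records in ", path)
  alt <- ifelse(is.na(a$alt), "", a$alt)
  a <- a[alt %in% c("", "A"), , drop = FALSE]
  a <- a[a$resid %in% names(.AA3), , drop = FALSE]
  if (nrow(a) == 0) stop("no standard-residue ATOM records in ", path)
  element <- .classifyElement(a$elesy, a$elety)
  keep <- element != "H"
  a <- a[keep, , drop = FALSE]
  element <- element[keep]
  if (nrow(a) == 0) stop("no heavy atoms in ", path)
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = element,
    resno = a$resno,
    resid = a$resid,
    chain = ifelse(is.na(a$chain), "", a$chain),
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    bfactor = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE)
  atoms$channel <- atoms$element %in% .CHANNELS
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  new("ProteinStructure", id = id, atoms = atoms, source = path)
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-width ATOM records (coordinates to 3 decimals,
#' B-factors to 2), so that `readPDB(writePDB(s))` round-trips.
#'
#' @param structure A [ProteinStructure-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(structure, path) {
  a <- structure@atoms
  if (nrow(a) == 0) stop("refusing to write an empty structure")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = a$serial, elety = a$name,
                   chain = ifelse(a$chain == "", " ", a$chain),
                   insert = ifelse(a$insert == "", "", a$insert),
                   b = a$bfactor, o = rep(1, nrow(a)),
                   elesy = ifelse(a$element == "other", "", a$element))
  invisible(path)
}

#' Per-residue summary of a structure
#'
#' @param structure A [ProteinStructure-class].
#' @return Data frame with one row per residue: `key`, `chain`, `resno`,
#'   `insert`, `resid` (3-letter), `aa` (1-letter), `hasBackbone` (TRUE iff
#'   N, CA and C are all present).
#' @export
residueTable <- function(structure) {
  a <- structure@atoms
  key <- residueKey(a$chain, a$resno, a$insert)
  idx <- !duplicated(key)
  tab <- data.frame(key = key[idx], chain = a$chain[idx], resno = a$resno[idx],
                    insert = a$insert[idx], resid = a$resid[idx],
                    stringsAsFactors = FALSE)
  tab$aa <- unname(.AA3[tab$resid])
  bb <- vapply(split(a$name, key), function(nm) all(c("N", "CA", "C") %in% nm),
               logical(1))
  tab$hasBackbone <- unname(bb[tab$key])
  tab[order(match(tab$key, key)), ]
}

.residueAtoms <- function(structure, key) {
  a <- structure@atoms
  a[residueKey(a$chain, a$resno, a$insert) == key, , drop = FALSE]
}

.backbone <- function(structure, key) {
  ra <- .residueAtoms(structure, key)
  if (nrow(ra) == 0) stop("residue not found: ", key)
  pick <- function(nm) {
    i <- which(ra$name == nm)[1]
    if (is.na(i)) return(NULL)
    c(ra$x[i], ra$y[i], ra$z[i])
  }
  bb <- list(N = pick("N"), CA = pick("CA"), C = pick("C"),
             O = pick("O"), CB = pick("CB"))
  if (is.null(bb$N) || is.null(bb$CA) || is.null(bb$C))
    stop("incomplete backbone (need N, CA, C) for residue ", key)
  bb
}

#' Ideal C-beta position from backbone atoms
#'
#' Places a C-beta analytically from N, CA and C coordinates: bond length
#' 1.53 Angstrom, with the N-CA-CB and C-CA-CB angles both at 110.5 degrees
#' and the branch chosen on the L-amino-acid side of the backbone plane.
#'
#' @param n,ca,c Numeric length-3 coordinates of the backbone N, CA, C.
#' @param length C-beta bond length in Angstrom.
#' @param angle N-CA-CB angle in degrees.
#' @return Numeric length-3 C-beta coordinate.
#' @export
cbetaFromBackbone <- function(n, ca, c, length = 1.53, angle = 110.5) {
  u <- unitVec(n - ca)
  v <- unitVec(c - ca)
  w <- crossprod3(u, v)
  if (sqrt(sum(w^2)) < 1e-6) stop("collinear backbone atoms: frame degenerate")
  nrm <- unitVec(w)
  ct <- cos(angle * pi / 180)
  # d = a*(u+v) + b*n with d.u = d.v = cos(angle), |d| = 1
  a <- ct / (1 + sum(u * v))
  rad <- 1 - a^2 * sum((u + v)^2)
  b <- sqrt(max(rad, 0))
  d <- a * (u + v) + b * nrm
  ca + length * unitVec(d)
}

#' C-beta position of a residue, constructing one for glycine
#'
#' Returns the residue's actual CB coordinates when present; otherwise (for
#' glycine, or residues with a missing CB) an ideal C-beta built from the
#' backbone via [cbetaFromBackbone()].
#'
#' @param structure A [ProteinStructure-class].
#' @param residue Residue key string ("chain:resno:insert", see
#'   [residueTable()]).
#' @return Numeric length-3 coordinate.
#' @export
virtualCbeta <- function(structure, residue) {
  bb <- .backbone(structure, residue)
  if (!is.null(bb$CB)) return(bb$CB)
  cbetaFromBackbone(bb$N, bb$CA, bb$C)
}

setMethod("show", "ProteinStructure", function(object) {
  rt <- residueTable(object)
  cat("ProteinStructure", object@id, "--", nrow(rt), "residues,",
      nrow(object@atoms), "atoms (source:", object@source, ")\n")
})
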