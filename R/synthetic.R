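# Synthetic PDB-like structures and planted-pattern classification tasks.
# These emulate the shape of real inputs (helical backbone geometry, valid
# PDB records, balanced labeled voxel datasets) so every pipeline stage can
# be exercised without downloading structures.

.BB_TEMPLATE <- rbind(
  N  = c(-0.525,  1.363,  0.000),
  CA = c( 0.000,  0.000,  0.000),
  C  = c( 1.526,  0.000,  0.000),
  O  = c( 2.216, -1.160,  0.000),
  CB = c(-0.540, -0.774, -1.205))

.BB_ELEMENT <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")

.AA3_REV <- stats::setNames(names(.AA3), .AA3)

#' Generate a synthetic helix-like protein structure
#'
#' Places rigid backbone templates (N, CA, C, O and, except for glycine,
#' CB) on an ideal alpha-helical CA trace (radius 2.3 Angstrom, 100 degrees
#' per residue, 1.5 Angstrom rise), with residue types drawn uniformly from
#' the 20 standard amino acids.  Optional Gaussian coordinate noise is
#' re-drawn (up to 1000 attempts) until the minimum interatomic distance is
#' at least 1.2 Angstrom.  Deterministic given the seed.
#'
#' @param nRes Number of residues.
#' @param seed Integer seed.
#' @param noise Coordinate noise standard deviation in Angstrom.
#' @param id Structure identifier.
#' @param chain Chain identifier.
#' @return A [ProteinStructure-class] with source "synthetic".
#' @export
syntheticStructure <- function(nRes = 30, seed = 1, noise = 0,
                               id = "synthetic", chain = "A") {
  stopifnot(nRes >= 2)
  radius <- 2.3; phase <- 100 * pi / 180; rise <- 1.5
  i <- seq_len(nRes)
  ca <- cbind(radius * cos(i * phase), radius * sin(i * phase), rise * i)
  frames <- lapply(i, function(j) {
    lo <- max(1, j - 1); hi <- min(nRes, j + 1)
    t <- unitVec(ca[hi, ] - ca[lo, ])
    r <- unitVec(c(ca[j, 1], ca[j, 2], 0))
    e3 <- unitVec(t - sum(t * r) * r)
    cbind(r, crossprod3(e3, r), e3)
  })
  withr::with_seed(seed, {
    aa <- sample(aminoAcids(), nRes, replace = TRUE)
    buildAtoms <- function(noisy) {
      rows <- list()
      serial <- 0L
      for (j in i) {
        nm <- rownames(.BB_TEMPLATE)
        if (aa[j] == "G") nm <- setdiff(nm, "CB")
        xyz <- .BB_TEMPLATE[nm, , drop = FALSE] %*% t(frames[[j]])
        xyz <- sweep(xyz, 2, -ca[j, ])
        if (noisy > 0)
          xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noisy),
                              ncol = 3)
        rows[[j]] <- data.frame(
          serial = serial + seq_along(nm), name = nm,
          element = unname(.BB_ELEMENT[nm]), resno = j,
          resid = unname(.AA3_REV[aa[j]]), chain = chain, insert = "",
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], bfactor = 0,
          stringsAsFactors = FALSE)
        serial <- serial + length(nm)
      }
      do.call(rbind, rows)
    }
    atoms <- NULL
    for (attempt in seq_len(if (noise > 0) 1000 else 1)) {
      cand <- buildAtoms(noise)
      d <- stats::dist(as.matrix(cand[, c("x", "y", "z")]))
      if (min(d) >= 1.2) { atoms <- cand; break }
    }
  })
  if (is.null(atoms))
    stop("could not generate a clash-free structure in 1000 attempts")
  atoms$channel <- atoms$element %in% .CHANNELS
  new("ProteinStructure", id = id, atoms = atoms, source = "synthetic")
}

#' Write a set of synthetic structures plus a family table
#'
#' Emits one PDB file per structure and a `families.tsv`
#' (structure_id, family_id) grouping consecutive structures into synthetic
#' families, for exercising family-grouped splitting.
#'
#' @param dir Output directory (created if missing).
#' @param nStructures Number of structures.
#' @param nRes Residues per structure.
#' @param perFamily Structures per synthetic family.
#' @param seed Integer seed.
#' @param noise Coordinate noise in Angstrom.
#' @return Data frame with structure_id, family_id and file paths.
#' @export
writeSyntheticSet <- function(dir, nStructures = 6, nRes = 20,
                              perFamily = 2, seed = 1, noise = 0.1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("syn%03d", seq_len(nStructures))
  paths <- file.path(dir, paste0(ids, ".pdb"))
  for (k in seq_len(nStructures))
    writePDB(syntheticStructure(nRes, seed = seed + k, noise = noise,
                                id = ids[k]), paths[k])
  fam <- data.frame(structure_id = ids,
                    family_id = sprintf("fam%03d",
                                        (seq_len(nStructures) - 1) %/%
                                          perFamily + 1),
                    path = paths, stringsAsFactors = FALSE)
  utils::write.table(fam[, c("structure_id", "family_id")],
                     file.path(dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fam
}

# Deterministic atom motif planted for a class, in local-frame coordinates
# (all within 5 Angstrom of the center so the signal survives frame
# alignment and never collides with the distractor shell).
.motif <- function(class) {
  ring <- function(m, radius, z, element) {
    ang <- 2 * pi * (seq_len(m) - 1) / m
    data.frame(element = element, x = radius * cos(ang),
               y = radius * sin(ang), z = z, stringsAsFactors = FALSE)
  }
  if (class == 1)
    data.frame(element = "N", x = c(3, -3, 0, 0), y = c(0, 0, 3, -3), z = 0)
  else if (class == 2) ring(6, 2.5, 0, "C")
  else if (class == 3)
    data.frame(element = "O", x = c(2, -2, 2, -2), y = c(2, -2, -2, 2),
               z = c(2, 2, -2, -2))
  else if (class == 4)
    data.frame(element = c("S", "S", "C"), x = c(3, -3, 0),
               y = c(3, -3, 0), z = c(0, 0, 4))
  else
    ring(3 + class %% 5, 2 + 0.5 * (class %% 3), -2 + class %% 5,
         .CHANNELS[class %% 4 + 1])
}

#' One planted-pattern microenvironment box
#'
#' The class motif plus uniformly drawn distractor atoms in the 6-10
#' Angstrom shell, with Gaussian coordinate noise.  At zero noise the motif
#' voxels are identical across all examples of a class.
#'
#' @param class Class index (1-based).
#' @param noise Coordinate noise standard deviation in Angstrom.
#' @param nDistract Number of distractor atoms.
#' @param boxSize Box edge length.
#' @return A [MicroenvBox-class] (label "X`class`").
#' @export
makePlantedBox <- function(class, noise = 0.3, nDistract = 12,
                           boxSize = 20) {
  motif <- .motif(class)
  h <- boxSize / 2
  dirs <- matrix(stats::rnorm(3 * nDistract), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rad <- stats::runif(nDistract, 6, 9.5)
  distract <- data.frame(element = sample(.CHANNELS, nDistract,
                                          replace = TRUE),
                         x = dirs[, 1] * rad, y = dirs[, 2] * rad,
                         z = dirs[, 3] * rad, stringsAsFactors = FALSE)
  atoms <- rbind(motif, distract)
  if (noise > 0) {
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), sd = noise)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), sd = noise)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), sd = noise)
  }
  inside <- abs(atoms$x) < h & abs(atoms$y) < h & abs(atoms$z) < h
  atoms <- atoms[inside, , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  new("MicroenvBox", label = "A", atoms = atoms,
      structureId = "planted", centerKey = paste0("motif", class),
      center = c(0, 0, 0), boxSize = boxSize)
}

#' Balanced planted-pattern voxel classification task
#'
#' Generates `nPerClass` voxelized examples for each of `k` motif classes.
#' At zero noise the task is exactly separable; the dataset is balanced by
#' construction and deterministic given the seed.
#'
#' @param nPerClass Examples per class.
#' @param k Number of classes (at most 20).
#' @param noise Coordinate noise standard deviation in Angstrom.
#' @param seed Integer seed.
#' @param smooth Apply Gaussian smoothing (default TRUE).
#' @param split Split tag for the returned dataset.
#' @param nDistract Distractor atoms per example.
#' @return A [LabeledVoxelSet-class] with labels "motif1".."motifk".
#' @export
makePlantedTask <- function(nPerClass, k = 4, noise = 0.3, seed = 1,
                            smooth = TRUE, split = "train", nDistract = 12) {
  stopifnot(k >= 2, k <= 20)
  classes <- paste0("motif", seq_len(k))
  withr::with_seed(seed, {
    grids <- list()
    labels <- character(0)
    for (cl in seq_len(k)) {
      for (r in seq_len(nPerClass)) {
        box <- makePlantedBox(cl, noise = noise, nDistract = nDistract)
        g <- suppressWarnings(discretize(box))  # rare distractor collisions
        if (smooth) g <- smoothGrid(g)
        grids[[length(grids) + 1]] <- g
        labels <- c(labels, classes[cl])
      }
    }
    gridsToDataset(grids, factor(labels, levels = classes), split = split)
  })
}
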