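# Grid sampling of box centers, center-residue selection, backbone local
# frames, and extraction of side-chain-stripped local boxes.

#' Sample box-center positions on a regular 3D grid
#'
#' Places a grid with the given spacing whose origin is the minimum x, y, z
#' corner of the structure's bounding box and which spans the whole box
#' (maximum index per axis = `ceiling(extent / spacing)`).
#'
#' @param structure A [ProteinStructure-class].
#' @param spacing Grid spacing in Angstrom (default 10).
#' @return Numeric matrix, one sampled position per row.
#' @export
sampleGrid <- function(structure, spacing = 10) {
  if (spacing <= 0) stop("spacing must be positive")
  a <- structure@atoms
  lo <- c(min(a$x), min(a$y), min(a$z))
  hi <- c(max(a$x), max(a$y), max(a$z))
  n <- ceiling((hi - lo) / spacing)
  pts <- as.matrix(expand.grid(x = lo[1] + spacing * (0:n[1]),
                               y = lo[2] + spacing * (0:n[2]),
                               z = lo[3] + spacing * (0:n[3])))
  dimnames(pts) <- NULL
  pts
}

.eligibleAtoms <- function(structure) {
  a <- structure@atoms
  rt <- residueTable(structure)
  ok <- rt$key[rt$hasBackbone]
  a[residueKey(a$chain, a$resno, a$insert) %in% ok, , drop = FALSE]
}

#' Pick the center residue for a sampled position
#'
#' Returns the key of the residue owning the Euclidean-nearest atom among
#' residues eligible as box centers (standard residues with a complete
#' N/CA/C backbone).  Ties are broken by the lowest atom serial.
#'
#' @param structure A [ProteinStructure-class].
#' @param point Numeric length-3 position.
#' @return Residue key string.
#' @export
pickCenterResidue <- function(structure, point) {
  a <- .eligibleAtoms(structure)
  if (nrow(a) == 0) stop("no eligible center residue in structure")
  d2 <- (a$x - point[1])^2 + (a$y - point[2])^2 + (a$z - point[3])^2
  best <- which(d2 == min(d2))
  if (length(best) > 1) best <- best[which.min(a$serial[best])]
  residueKey(a$chain[best], a$resno[best], a$insert[best])
}

#' Build the backbone-oriented local frame of a residue
#'
#' The x axis is the unit vector along N-CA; the z axis is the unit normal
#' of the plane spanned by N-CA and C-CA, signed so that it has a positive
#' dot product with CA->CB (CB virtual for glycine); y completes the
#' right-handed system.  The origin is the (possibly virtual) C-beta.
#'
#' @param structure A [ProteinStructure-class].
#' @param residue Residue key string.
#' @return A [LocalFrame-class].
#' @export
buildFrame <- function(structure, residue) {
  bb <- .backbone(structure, residue)
  u <- bb$N - bb$CA
  v <- bb$C - bb$CA
  w <- crossprod3(u, v)
  if (sqrt(sum(w^2)) < 1e-6) stop("degenerate frame: N, CA, C collinear")
  x <- unitVec(u)
  z <- unitVec(w)
  cb <- if (!is.null(bb$CB)) bb$CB else cbetaFromBackbone(bb$N, bb$CA, bb$C)
  if (sum(z * (cb - bb$CA)) < 0) z <- -z
  y <- crossprod3(z, x)
  new("LocalFrame", origin = cb, axes = rbind(x = x, y = y, z = z))
}

#' Coordinates of points in a local frame
#'
#' @param frame A [LocalFrame-class].
#' @param xyz Numeric matrix of global coordinates (one point per row).
#' @return Matrix of local coordinates.
#' @export
toLocalCoords <- function(frame, xyz) {
  sweep(xyz, 2, frame@origin) %*% t(frame@axes)
}

#' Extract a side-chain-stripped local box around a residue
#'
#' Transforms all channel-element atoms of the structure into the residue's
#' local frame and keeps those inside the half-open cube
#' `[-boxSize/2, boxSize/2)^3`.  All atoms of the center residue except its
#' backbone N, CA, C and O -- in particular its CB and side chain -- are
#' removed, and the box is labeled with the removed side-chain type.
#'
#' @param structure A [ProteinStructure-class].
#' @param residue Residue key string.
#' @param frame Optional precomputed [LocalFrame-class]; built if NULL.
#' @param boxSize Box edge length in Angstrom (default 20).
#' @return A [MicroenvBox-class].
#' @export
extractBox <- function(structure, residue, frame = NULL, boxSize = 20) {
  if (is.null(frame)) frame <- buildFrame(structure, residue)
  a <- structure@atoms
  keep <- a$channel
  key <- residueKey(a$chain, a$resno, a$insert)
  sidechain <- key == residue & !(a$name %in% c("N", "CA", "C", "O"))
  keep <- keep & !sidechain
  a <- a[keep, , drop = FALSE]
  loc <- toLocalCoords(frame, as.matrix(a[, c("x", "y", "z")]))
  h <- boxSize / 2
  inside <- loc[, 1] >= -h & loc[, 1] < h &
            loc[, 2] >= -h & loc[, 2] < h &
            loc[, 3] >= -h & loc[, 3] < h
  atoms <- data.frame(element = a$element[inside],
                      x = loc[inside, 1], y = loc[inside, 2],
                      z = loc[inside, 3], serial = a$serial[inside],
                      stringsAsFactors = FALSE)
  rt <- residueTable(structure)
  label <- rt$aa[rt$key == residue]
  if (length(label) != 1 || is.na(label))
    stop("center residue has no standard amino-acid label: ", residue)
  if (nrow(atoms) == 0)
    warning("empty microenvironment box at residue ", residue)
  new("MicroenvBox", label = label, atoms = atoms,
      structureId = structure@id, centerKey = residue,
      center = frame@origin, boxSize = boxSize)
}

#' Extract all boxes of a structure sampled on a grid
#'
#' Runs the full sampling procedure: grid placement, nearest-atom center
#' residue selection, frame construction and box extraction.  Duplicate
#' center residues (several grid points electing the same residue) are kept
#' once.  Residues without a complete backbone are skipped with a warning.
#'
#' @param structure A [ProteinStructure-class].
#' @param spacing Grid spacing in Angstrom.
#' @param boxSize Box edge length in Angstrom.
#' @return List of [MicroenvBox-class] objects.
#' @export
extractAllBoxes <- function(structure, spacing = 10, boxSize = 20) {
  pts <- sampleGrid(structure, spacing)
  keys <- unique(vapply(seq_len(nrow(pts)), function(i)
    pickCenterResidue(structure, pts[i, ]), character(1)))
  boxes <- list()
  for (k in keys) {
    box <- tryCatch(extractBox(structure, k, boxSize = boxSize),
                    error = function(e) {
                      warning("skipping residue ", k, ": ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(box)) boxes[[k]] <- box
  }
  boxes
}

setMethod("show", "MicroenvBox", function(object) {
  cat("MicroenvBox [", object@label, "] ", nrow(object@atoms),
      " atoms, center residue ", object@centerKey, " of ",
      object@structureId, "\n", sep = "")
})

setMethod("show", "LocalFrame", function(object) {
  cat("LocalFrame at (", paste(sprintf("%.2f", object@origin), collapse = ", "),
      ")\n", sep = "")
})
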