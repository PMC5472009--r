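# Conversion of local boxes to channel tensors: hard 1-Angstrom voxel
# occupancy, per-channel Gaussian smoothing, and zero-mean normalization.

#' Default per-channel Gaussian widths (Bondi van der Waals radii, Angstrom)
#'
#' @return Named numeric vector with entries for C, N, O and S.
#' @export
defaultSigmas <- function() c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Discretize a box into a binary channel occupancy tensor
#'
#' An atom at local coordinates (x, y, z) occupies the voxel
#' `(floor(x + s/2), floor(y + s/2), floor(z + s/2))` of its element's
#' channel; occupancy is capped at 1 per voxel per channel (and a cap event
#' is reported via a warning, since at 1 Angstrom resolution two heavy atoms
#' in one voxel indicate unphysical geometry).
#'
#' @param box A [MicroenvBox-class].
#' @param channels Channel ordering (default O, C, N, S).
#' @return A [VoxelGrid-class] with 0/1 entries.
#' @export
discretize <- function(box, channels = .CHANNELS) {
  s <- as.integer(box@boxSize)
  g <- array(0, dim = c(length(channels), s, s, s))
  a <- box@atoms
  if (nrow(a)) {
    h <- box@boxSize / 2
    if (min(a$x, a$y, a$z) < -h || max(a$x, a$y, a$z) >= h)
      stop("atom outside the box cube")
    a <- a[a$element %in% channels, , drop = FALSE]  # 'other' not voxelized
    ci <- match(a$element, channels)
    ix <- floor(a$x + h) + 1L
    iy <- floor(a$y + h) + 1L
    iz <- floor(a$z + h) + 1L
    idx <- cbind(ci, ix, iy, iz)
    if (anyDuplicated(idx))
      warning("multiple atoms of one element in a single voxel; capped at 1")
    g[idx] <- 1
  }
  new("VoxelGrid", data = g, channels = channels, smoothed = FALSE,
      boxId = paste0(box@structureId, ":", box@centerKey))
}

.gauss1d <- function(sigma) {
  r <- ceiling(2 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 3D array with a separable kernel along every axis, zero padding.
.convSep3 <- function(a, k) {
  s <- dim(a)
  r <- (length(k) - 1L) / 2L
  mat1d <- function(n) {
    K <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[off + r + 1L]
    }
    K
  }
  K <- mat1d(s[1])
  a <- array(K %*% matrix(a, s[1]), s)
  a <- aperm(a, c(2, 1, 3))
  a <- array(mat1d(s[2]) %*% matrix(a, s[2]), s[c(2, 1, 3)])
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))
  a <- array(mat1d(s[3]) %*% matrix(a, s[3]), s[c(3, 2, 1)])
  aperm(a, c(3, 2, 1))
}

#' Gaussian-smooth a voxel grid channel by channel
#'
#' Each channel is convolved with a unit-mass 3D Gaussian truncated at
#' 2 sigma (rounded up to whole voxels), approximating atom connectivity and
#' electron delocalization.  Channel mass is conserved up to truncation and
#' boundary loss.
#'
#' @param grid A [VoxelGrid-class].
#' @param sigmas Named per-channel standard deviations in Angstrom
#'   (default [defaultSigmas()]).
#' @return The smoothed [VoxelGrid-class].
#' @export
smoothGrid <- function(grid, sigmas = defaultSigmas()) {
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  d <- grid@data
  for (ch in grid@channels) {
    sg <- sigmas[[ch]]
    if (is.null(sg) || is.na(sg)) stop("no sigma given for channel ", ch)
    i <- match(ch, grid@channels)
    d[i, , , ] <- .convSep3(d[i, , , ], .gauss1d(sg))
  }
  grid@data <- d
  grid@smoothed <- TRUE
  grid
}

#' Voxelize a box end to end
#'
#' [discretize()] followed by [smoothGrid()].
#'
#' @inheritParams discretize
#' @inheritParams smoothGrid
#' @return A smoothed [VoxelGrid-class].
#' @export
voxelize <- function(box, channels = .CHANNELS, sigmas = defaultSigmas()) {
  smoothGrid(discretize(box, channels), sigmas)
}

#' Assemble voxel grids into a labeled dataset
#'
#' @param grids List of [VoxelGrid-class] objects.
#' @param labels Class labels, one per grid (defaults from box labels are
#'   not stored on grids, so labels must be supplied).
#' @param split Split tag: "train", "val" or "test".
#' @param classes Factor levels to enforce (default: the labels' own levels).
#' @return A [LabeledVoxelSet-class].
#' @export
gridsToDataset <- function(grids, labels, split = "train", classes = NULL) {
  stopifnot(length(grids) == length(labels))
  d <- dim(grids[[1]]@data)
  feat <- t(vapply(grids, function(g) as.numeric(g@data),
                   numeric(prod(d))))
  labels <- if (is.null(classes)) factor(labels) else
    factor(labels, levels = classes)
  new("LabeledVoxelSet", features = feat, featureDim = as.integer(d),
      labels = labels, split = split)
}

#' Fit zero-mean normalization statistics on a training set
#'
#' Computes the mean of each channel at each voxel position (or each
#' descriptor component) across the training examples.
#'
#' @param train A [LabeledVoxelSet-class] with split "train".
#' @param scale If TRUE, additionally store the global standard deviation of
#'   the centered training values, so that applying the stats also rescales
#'   to unit variance.  The default (FALSE) is plain zero-mean
#'   normalization; rescaling is a numerical conditioning option for
#'   gradient training and does not change what the network can express.
#' @return A [NormalizationStats-class].
#' @export
fitNormalizer <- function(train, scale = FALSE) {
  if (nrow(train@features) < 1) stop("need at least one training example")
  m <- array(colMeans(train@features), dim = train@featureDim)
  sc <- 1
  if (scale) {
    centered <- sweep(train@features, 2, as.numeric(m))
    sc <- stats::sd(as.numeric(centered))
    if (!is.finite(sc) || sc == 0) sc <- 1
  }
  new("NormalizationStats", mean = m, scale = sc,
      n = nrow(train@features))
}

#' Apply fitted normalization statistics
#'
#' Subtracts the stored training means element-wise.  Accepts a
#' [LabeledVoxelSet-class], a [VoxelGrid-class] or a bare array.
#'
#' @param stats A [NormalizationStats-class].
#' @param x Data to normalize.
#' @return Object of the same type as `x`.
#' @export
applyNormalizer <- function(stats, x) {
  if (is(x, "LabeledVoxelSet")) {
    if (!identical(as.integer(x@featureDim), as.integer(dim(stats@mean))) &&
        prod(x@featureDim) != length(stats@mean))
      stop("normalization statistics do not match the data shape")
    x@features <- sweep(x@features, 2, as.numeric(stats@mean)) / stats@scale
    return(x)
  }
  if (is(x, "VoxelGrid")) {
    if (!identical(dim(x@data), dim(stats@mean)))
      stop("normalization statistics do not match the grid shape")
    x@data <- (x@data - stats@mean) / stats@scale
    return(x)
  }
  if (length(x) != length(stats@mean))
    stop("normalization statistics do not match the input length")
  (x - as.numeric(stats@mean)) / stats@scale
}

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid ", paste(dim(object@data), collapse = "x"),
      if (object@smoothed) " (smoothed)" else " (raw occupancy)",
      ", channels: ", paste(object@channels, collapse = ","), "\n", sep = "")
})

setMethod("show", "LabeledVoxelSet", function(object) {
  cat("LabeledVoxelSet [", object@split, "] ", nrow(object@features),
      " examples x dim (", paste(object@featureDim, collapse = ","),
      "), ", nlevels(object@labels), " classes\n", sep = "")
})
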