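# Gradient-times-input atom importance maps and B-factor export.

#' Gradient-times-input importance map for one example
#'
#' Computes the gradient of the chosen class's pre-softmax score (or
#' post-softmax probability) with respect to the input tensor, multiplies it
#' element-wise by the input value, takes absolute values and min-max
#' normalizes to `[0, 100]` across all positions and channels of the
#' example.  By first-order Taylor approximation the raw score of a voxel
#' approximates the score change caused by zeroing it.
#'
#' @param net A trained [VoxelNet-class].
#' @param grid A [VoxelGrid-class] or numeric array in the network's input
#'   shape (normalized as the network was trained).
#' @param trueClass 1-based class index, or a class name.
#' @param score "logit" (default) or "probability".
#' @return An [ImportanceMap-class].
#' @export
importanceMap <- function(net, grid, trueClass,
                          score = c("logit", "probability")) {
  score <- match.arg(score)
  x <- if (is(grid, "VoxelGrid")) grid@data else grid
  if (is.character(trueClass)) {
    trueClass <- match(trueClass, net@classNames)
    if (is.na(trueClass)) stop("unknown class name")
  }
  if (trueClass < 1 || trueClass > net@nClasses)
    stop("class index outside 1..", net@nClasses)
  g <- inputGradient(net, x, trueClass, score = score)
  raw <- g * as.numeric(x)
  raw <- array(raw, dim = dim(x))
  a <- abs(raw)
  rng <- range(a)
  normalized <- if (rng[2] > 0)
    (a - rng[1]) / (rng[2] - rng[1]) * 100 else array(0, dim = dim(a))
  new("ImportanceMap", raw = raw, normalized = normalized,
      trueClass = as.integer(trueClass))
}

#' Project voxel importance scores onto atoms
#'
#' Each atom receives the sum of normalized voxel scores over its Gaussian
#' smoothing support (voxels within the truncation radius of its element's
#' sigma) in its own channel -- or just its own voxel in "nearest" mode --
#' and atom scores are rescaled so the maximum is 100.  Atoms of elements
#' outside the four channels score 0.
#'
#' @param map An [ImportanceMap-class].
#' @param box The [MicroenvBox-class] the map's input grid came from.
#' @param channels Channel ordering used at voxelization.
#' @param sigmas Per-channel Gaussian widths used at voxelization.
#' @param mode "support" (default) or "nearest".
#' @return Data frame with columns serial, element, score.
#' @export
scoresToAtoms <- function(map, box, channels = .CHANNELS,
                          sigmas = defaultSigmas(),
                          mode = c("support", "nearest")) {
  mode <- match.arg(mode)
  a <- box@atoms
  s <- dim(map@normalized)[2]
  if (dim(map@normalized)[1] != length(channels))
    stop("map channels do not match the channel ordering")
  h <- box@boxSize / 2
  score <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    ci <- match(a$element[i], channels)
    if (is.na(ci)) next
    v <- floor(c(a$x[i], a$y[i], a$z[i]) + h) + 1L
    r <- if (mode == "nearest") 0L else ceiling(2 * sigmas[[a$element[i]]])
    ix <- max(1, v[1] - r):min(s, v[1] + r)
    iy <- max(1, v[2] - r):min(s, v[2] + r)
    iz <- max(1, v[3] - r):min(s, v[3] + r)
    score[i] <- sum(map@normalized[ci, ix, iy, iz])
  }
  if (max(score) > 0) score <- score / max(score) * 100
  data.frame(serial = a$serial, element = a$element, score = score)
}

#' Write importance scores into the B-factor column of a PDB file
#'
#' Atoms inside the analyzed box carry their importance score; all other
#' atoms carry 0.
#'
#' @param structure The source [ProteinStructure-class].
#' @param atomScores Data frame from [scoresToAtoms()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
exportBfactor <- function(structure, atomScores, path) {
  b <- numeric(nrow(structure@atoms))
  idx <- match(atomScores$serial, structure@atoms$serial)
  if (any(is.na(idx))) stop("atom serials not found in structure")
  b[idx] <- atomScores$score
  structure@atoms$bfactor <- b
  writePDB(structure, path)
}

setMethod("show", "ImportanceMap", function(object) {
  cat("ImportanceMap for class", object@trueClass, "- max |raw| =",
      sprintf("%.4g", max(abs(object@raw))), "\n")
})
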