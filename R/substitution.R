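# Substitution matrices derived from prediction confusion statistics, plus
# standard-matrix bundling and matrix comparison.

.LOG_FLOOR <- 1e-10

#' Frequency-based (log-odds) substitution scores from a confusion matrix
#'
#' With `p(i, j) = M[i, j] / sum(M)` and marginals `q_row(i)`, `q_col(j)`,
#' the asymmetric score is `log(p(i, j) / (q_row(i) * q_col(j)))` (natural
#' log; log arguments floored at 1e-10 for empty cells); it is symmetrized
#' by averaging with its transpose.
#'
#' @param cm A [ConfusionMatrix-class].
#' @return A [SubstitutionScores-class] of kind "freq".
#' @export
sFreq <- function(cm) {
  M <- cm@counts
  tot <- sum(M)
  if (tot == 0) stop("all-zero confusion matrix")
  p <- M / tot
  qr <- rowSums(M) / tot
  qc <- colSums(M) / tot
  ratio <- p / (qr %o% qc)
  ratio[!is.finite(ratio)] <- 0  # empty row/column marginals
  sPrime <- log(pmax(ratio, .LOG_FLOOR))
  S <- (sPrime + t(sPrime)) / 2
  dimnames(S) <- list(cm@classes, cm@classes)
  new("SubstitutionScores", matrix = S, kind = "freq",
      metadata = list(logBase = "natural", floor = .LOG_FLOOR,
                      flooredCells = sum(ratio < .LOG_FLOOR),
                      source = "confusion"))
}

#' Dot-product (profile-similarity) substitution scores
#'
#' Row- and column-stochastic normalizations of the confusion matrix are
#' L2-normalized per row/column, and
#' `S_dot[i, j] = log(dot(Row_i, Row_j) + dot(Col_i, Col_j))` (natural log,
#' argument floored at 1e-10).  By Cauchy-Schwarz the diagonal equals
#' log(2) and dominates every off-diagonal entry.
#'
#' @param cm A [ConfusionMatrix-class].
#' @return A [SubstitutionScores-class] of kind "dot".
#' @export
sDot <- function(cm) {
  M <- cm@counts
  flagged <- any(rowSums(M) == 0) || any(colSums(M) == 0)
  if (flagged)
    warning("confusion matrix has empty rows or columns; scores floored")
  nr <- rowNormalized(cm)
  nc <- colNormalized(cm)
  l2row <- sqrt(rowSums(nr^2))
  l2col <- sqrt(colSums(nc^2))
  R <- nr / ifelse(l2row == 0, 1, l2row)
  Cm <- sweep(nc, 2, ifelse(l2col == 0, 1, l2col), "/")
  S <- log(pmax(R %*% t(R) + t(Cm) %*% Cm, .LOG_FLOOR))
  S <- (S + t(S)) / 2  # exact symmetry against rounding in the two products
  dimnames(S) <- list(cm@classes, cm@classes)
  new("SubstitutionScores", matrix = S, kind = "dot",
      metadata = list(logBase = "natural", floor = .LOG_FLOOR,
                      degenerate = flagged, source = "confusion"))
}

#' Compare two score matrices by linear least-squares R-value
#'
#' Pearson correlation of paired entries.  Because both derived matrices
#' and the standard matrices are symmetric, the default pairs each unique
#' entry once (upper triangle including the diagonal); "full" uses all
#' ordered cells.  R is invariant to affine rescaling of either matrix, so
#' the choice of log base cannot change it.
#'
#' @param a,b [SubstitutionScores-class] objects (or bare square matrices)
#'   of equal dimension; when both carry dimnames, `b` is aligned to `a`.
#' @param cells "unique" (default) or "full".
#' @return The Pearson R-value.
#' @export
compareMatrices <- function(a, b, cells = c("unique", "full")) {
  cells <- match.arg(cells)
  A <- if (is(a, "SubstitutionScores")) a@matrix else a
  B <- if (is(b, "SubstitutionScores")) b@matrix else b
  if (!all(dim(A) == dim(B))) stop("matrices differ in shape")
  if (!is.null(rownames(A)) && !is.null(rownames(B))) {
    if (!setequal(rownames(A), rownames(B)))
      stop("matrices are over different class sets")
    B <- B[rownames(A), colnames(A)]
  }
  keep <- if (cells == "unique") upper.tri(A, diag = TRUE) else
    matrix(TRUE, nrow(A), ncol(A))
  x <- A[keep]
  y <- B[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("R-value undefined for a constant matrix")
  stats::cor(x, y)
}

#' Bundled standard substitution matrices
#'
#' Returns the standard BLOSUM62 or PAM250 matrix restricted to the 20
#' standard amino acids in alphabetical one-letter order.
#'
#' @param name "BLOSUM62" or "PAM250".
#' @return A [SubstitutionScores-class] of kind "external".
#' @export
loadStandardMatrix <- function(name = c("BLOSUM62", "PAM250")) {
  name <- match.arg(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- e[[name]][aminoAcids(), aminoAcids()]
  new("SubstitutionScores", matrix = m, kind = "external",
      metadata = list(source = name))
}

#' Read / write a score matrix as a whitespace-delimited square table
#'
#' NCBI-style layout: a header row of one-letter codes and a leading code
#' per row.  The loader validates squareness and consistent row/column
#' ordering.
#'
#' @param path File path.
#' @param scores A [SubstitutionScores-class] to write.
#' @return A [SubstitutionScores-class] / `path` invisibly.
#' @export
readMatrixFile <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                   check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("matrix file is not square")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column orderings differ in matrix file")
  new("SubstitutionScores", matrix = m, kind = "external",
      metadata = list(source = path))
}

#' @rdname readMatrixFile
#' @export
writeMatrixFile <- function(scores, path) {
  m <- if (is(scores, "SubstitutionScores")) scores@matrix else scores
  utils::write.table(format(m, digits = 10), path, quote = FALSE,
                     col.names = NA)
  invisible(path)
}

setMethod("show", "SubstitutionScores", function(object) {
  cat("SubstitutionScores (", object@kind, ") ",
      nrow(object@matrix), "x", ncol(object@matrix), "\n", sep = "")
})
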