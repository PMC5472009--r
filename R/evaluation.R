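# Accuracy metrics, confusion matrices and their normalizations,
# knowledge-based group accuracy, Ward clustering, heatmaps.

#' Build a confusion matrix from true and predicted labels
#'
#' `counts[i, j]` counts examples of true class i predicted as class j.
#'
#' @param truth,pred Equal-length label vectors (characters or factors whose
#'   values are all in `classes`).
#' @param classes Class universe, default the 20 amino acids.
#' @return A [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(truth, pred, classes = aminoAcids()) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  if (!all(truth %in% classes) || !all(pred %in% classes))
    stop("labels outside the class set")
  m <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(classes, classes))
  new("ConfusionMatrix", counts = m, classes = classes)
}

#' Row- and column-stochastic normalizations of a confusion matrix
#'
#' Each nonzero row (column) of the counts is divided by its sum; all-zero
#' rows (columns) are left at zero and reported in the `zeroRows`
#' (`zeroCols`) attribute.
#'
#' @param cm A [ConfusionMatrix-class].
#' @return Numeric matrix of the same shape.
#' @export
rowNormalized <- function(cm) {
  m <- cm@counts
  rs <- rowSums(m)
  out <- m / ifelse(rs == 0, 1, rs)
  attr(out, "zeroRows") <- cm@classes[rs == 0]
  out
}

#' @rdname rowNormalized
#' @export
colNormalized <- function(cm) {
  m <- cm@counts
  cs <- colSums(m)
  out <- sweep(m, 2, ifelse(cs == 0, 1, cs), "/")
  attr(out, "zeroCols") <- cm@classes[cs == 0]
  out
}

#' Individual class accuracy
#'
#' @param cm A [ConfusionMatrix-class].
#' @return trace(M) / sum(M).
#' @export
classAccuracy <- function(cm) {
  tot <- sum(cm@counts)
  if (tot == 0) stop("empty evaluation set")
  sum(diag(cm@counts)) / tot
}

#' Default knowledge-based amino-acid grouping
#'
#' Biochemical partition of the 20 amino acids: nonpolar aliphatic
#' (A, V, L, I, M), aromatic (F, W, Y), polar uncharged (S, T, N, Q),
#' positively charged (K, R, H), negatively charged (D, E) and special
#' (C, G, P).
#'
#' @return Named list of character vectors partitioning [aminoAcids()].
#' @export
defaultAminoGroups <- function() {
  list(nonpolar_aliphatic = c("A", "V", "L", "I", "M"),
       aromatic = c("F", "W", "Y"),
       polar_uncharged = c("S", "T", "N", "Q"),
       positive = c("K", "R", "H"),
       negative = c("D", "E"),
       special = c("C", "G", "P"))
}

.checkScheme <- function(scheme, classes) {
  all_members <- unlist(scheme, use.names = FALSE)
  if (anyDuplicated(all_members)) stop("groups must be disjoint")
  if (!setequal(all_members, classes)) stop("groups must cover all classes")
  invisible(TRUE)
}

#' Knowledge-based group accuracy
#'
#' A prediction counts as correct when it falls in the same predefined
#' amino-acid group as the true class.  With a scheme of singletons this
#' equals the individual class accuracy; for any scheme it dominates it.
#'
#' @param truth,pred Label vectors.
#' @param scheme Named list of character vectors partitioning the class set
#'   (default [defaultAminoGroups()]).
#' @return Group accuracy in `[0, 1]`.
#' @export
groupAccuracy <- function(truth, pred, scheme = defaultAminoGroups()) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) == 0) stop("empty evaluation set")
  classes <- unlist(scheme, use.names = FALSE)
  .checkScheme(scheme, union(classes, union(truth, pred)))
  groupOf <- rep(names(scheme), lengths(scheme))
  names(groupOf) <- classes
  mean(groupOf[truth] == groupOf[pred])
}

#' Read / write a group scheme as JSON
#'
#' @param path JSON file holding a named list of class-name arrays.
#' @param scheme Scheme to write.
#' @return The scheme (named list) / `path` invisibly.
#' @export
readGroupScheme <- function(path) {
  scheme <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(scheme, as.character)
}

#' @rdname readGroupScheme
#' @export
writeGroupScheme <- function(scheme, path) {
  jsonlite::write_json(scheme, path, pretty = TRUE)
  invisible(path)
}

#' Ward hierarchical clustering of a normalized confusion matrix
#'
#' Agglomerative clustering of the row-profile vectors with Ward's linkage
#' on Euclidean distances (hclust method "ward.D2", the Ward variant
#' operating on distances, as in scipy's linkage "ward").
#'
#' @param nrow_matrix Row-normalized confusion matrix (see
#'   [rowNormalized()]).
#' @return An object of class `hclust`.
#' @export
clusterConfusion <- function(nrow_matrix) {
  if (nrow(nrow_matrix) != ncol(nrow_matrix))
    stop("expected a square normalized confusion matrix")
  stats::hclust(stats::dist(nrow_matrix), method = "ward.D2")
}

#' Render a matrix heatmap to a file
#'
#' @param mat Numeric matrix.
#' @param file Output path (".png" for PNG).
#' @param order Optional row/column ordering (character or integer).
#' @param cluster Cluster rows/columns instead of fixed ordering.
#' @return `file`, invisibly.
#' @export
plotHeatmap <- function(mat, file, order = NULL, cluster = FALSE) {
  if (!is.null(order)) mat <- mat[order, order, drop = FALSE]
  pheatmap::pheatmap(mat, cluster_rows = cluster, cluster_cols = cluster,
                     filename = file, silent = TRUE)
  invisible(file)
}

#' Write / read a confusion matrix as TSV with class-name headers
#'
#' @param cm A [ConfusionMatrix-class] (writer) or file path (reader).
#' @param path Output path.
#' @return `path` invisibly / a [ConfusionMatrix-class].
#' @export
writeConfusion <- function(cm, path) {
  utils::write.table(cm@counts, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname writeConfusion
#' @export
readConfusion <- function(cm) {
  m <- as.matrix(utils::read.delim(cm, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  new("ConfusionMatrix", counts = m, classes = rownames(m))
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix over", length(object@classes), "classes,",
      sum(object@counts), "examples; accuracy",
      sprintf("%.3f", classAccuracy(object)), "\n")
})
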