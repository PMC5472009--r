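# Family-grouped splitting, class balancing and validation carve-out.

#' Split protein families into train and test sets
#'
#' Assigns whole families to one side only, so no family is shared between
#' train and test.  The test side receives `floor(testFraction * nFamilies)`
#' families, drawn uniformly at random under the given seed.
#'
#' @param familyIds Character vector of family identifiers (duplicates
#'   collapse to the unique family set).
#' @param testFraction Fraction of families assigned to test (default 0.05).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with `train` and `test` character vectors of family ids.
#' @export
splitFamilies <- function(familyIds, testFraction = 0.05, seed) {
  fams <- unique(familyIds)
  if (length(fams) == 0) stop("empty family set")
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0, 1)")
  nTest <- floor(testFraction * length(fams))
  test <- withr::with_seed(seed, sample(fams, nTest))
  list(train = setdiff(fams, test), test = test)
}

#' Assign structures to splits by family membership
#'
#' @param familyTable Data frame with columns `structure_id` and `family_id`.
#' @param split Result of [splitFamilies()].
#' @param exclude Optional character vector of structure ids to drop (e.g.
#'   an external sequence-similarity exclusion list).
#' @return List with `train` and `test` character vectors of structure ids.
#' @export
assignStructures <- function(familyTable, split, exclude = character()) {
  stopifnot(all(c("structure_id", "family_id") %in% names(familyTable)))
  ft <- familyTable[!familyTable$structure_id %in% exclude, ]
  if (any(is.na(ft$family_id)))
    stop("every structure must carry a family id")
  both <- intersect(ft$structure_id[ft$family_id %in% split$train],
                    ft$structure_id[ft$family_id %in% split$test])
  ft <- ft[!ft$structure_id %in% both, ]
  list(train = unique(ft$structure_id[ft$family_id %in% split$train]),
       test = unique(ft$structure_id[ft$family_id %in% split$test]))
}

#' Balance a dataset to equal per-class counts
#'
#' Identifies the least abundant class, keeps it in full, and randomly
#' subsamples every other class without replacement down to that count.
#'
#' @param dataset A [LabeledVoxelSet-class].
#' @param seed Integer seed.
#' @return The balanced [LabeledVoxelSet-class].
#' @export
balanceDataset <- function(dataset, seed) {
  counts <- table(dataset@labels)
  counts <- counts[counts > 0]
  m <- min(counts)
  idx <- withr::with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      i <- which(dataset@labels == cl)
      if (length(i) > m) sample(i, m) else i
    }))
  })
  idx <- sort(idx)
  dataset@features <- dataset@features[idx, , drop = FALSE]
  dataset@labels <- droplevels(dataset@labels[idx])
  dataset
}

#' Carve a validation set out of a balanced training set
#'
#' Draws `floor(n / (ratio + 1))` validation examples class-stratified from
#' the training set (default ratio 19, i.e. a 1:19 validation:train split).
#'
#' @param train A [LabeledVoxelSet-class] with split "train".
#' @param ratio Train-to-validation ratio (default 19 for 1:19).
#' @param seed Integer seed.
#' @return List with `train` and `val` [LabeledVoxelSet-class] objects.
#' @export
carveValidation <- function(train, ratio = 19, seed) {
  n <- nrow(train@features)
  nVal <- floor(n / (ratio + 1))
  if (nVal == 0) {
    warning("fewer than ", ratio + 1, " examples; validation set is empty")
    val <- train
    val@features <- train@features[0, , drop = FALSE]
    val@labels <- train@labels[0]
    val@split <- "val"
    return(list(train = train, val = val))
  }
  frac <- nVal / n
  lv <- levels(droplevels(train@labels))
  perClass <- vapply(lv, function(cl) sum(train@labels == cl), integer(1))
  base <- floor(perClass * frac)
  # largest-remainder allocation so the class-stratified draw sums exactly
  # to floor(n / (ratio + 1)) while staying within one example of frac
  rem <- nVal - sum(base)
  if (rem > 0) {
    extra <- order(perClass * frac - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  valIdx <- withr::with_seed(seed, {
    unlist(lapply(seq_along(lv), function(j) {
      i <- which(train@labels == lv[j])
      if (base[j] > 0) sample(i, base[j]) else integer(0)
    }))
  })
  valIdx <- sort(valIdx)
  val <- train
  val@features <- train@features[valIdx, , drop = FALSE]
  val@labels <- train@labels[valIdx]
  val@split <- "val"
  train@features <- train@features[-valIdx, , drop = FALSE]
  train@labels <- train@labels[-valIdx]
  list(train = train, val = val)
}

#' Read a family table from TSV
#'
#' @param path TSV file with columns structure_id, family_id.
#' @return Data frame.
#' @export
readFamilyTable <- function(path) {
  ft <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("structure_id", "family_id") %in% names(ft)))
  ft
}
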