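# Variant-site box extraction, substitution-score feature construction and
# cross-validated destabilizing-vs-neutral classifiers, with the bundled
# T4 lysozyme variant table as the reference fixture.

#' Parse a point-mutation variant name
#'
#' @param variant Name like "G77A": wild-type amino acid, residue number,
#'   mutant amino acid.
#' @return List with `wt`, `pos`, `mt`.
#' @export
parseVariant <- function(variant) {
  m <- regmatches(variant, regexec("^([A-Z])([0-9]+)([A-Z])$", variant))[[1]]
  if (length(m) != 4) stop("unparseable variant name: ", variant)
  if (!m[2] %in% aminoAcids() || !m[4] %in% aminoAcids())
    stop("variant amino acids must be standard one-letter codes: ", variant)
  if (m[2] == m[4]) stop("wild-type and mutant amino acids equal: ", variant)
  list(wt = m[2], pos = as.integer(m[3]), mt = m[4])
}

#' The bundled T4 lysozyme variant set
#'
#' 40 point mutants of T4 lysozyme with their mutant-structure PDB ids and
#' literature-assigned stability effects (destabilizing vs neutral).
#' Wild-type and mutant amino acids are parsed from the variant names.
#'
#' @return Data frame with columns variant, mutant_pdb, effect, wt, pos, mt.
#' @export
loadT4Variants <- function() {
  path <- system.file("extdata", "t4_lysozyme_variants.tsv",
                      package = "MicroEnvNet", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  parsed <- lapply(tab$variant, parseVariant)
  tab$wt <- vapply(parsed, `[[`, character(1), "wt")
  tab$pos <- vapply(parsed, `[[`, integer(1), "pos")
  tab$mt <- vapply(parsed, `[[`, character(1), "mt")
  stopifnot(all(tab$effect %in% c("Neutral", "Destabilizing")))
  tab
}

#' Extract the wild-type / mutant microenvironment box pair at a variant site
#'
#' Maps the mutated residue number into both structures, builds the local
#' backbone frame in each and extracts the side-chain-stripped boxes.
#' Because the side chain of the center residue is removed, the two boxes
#' coincide whenever the surrounding backbones match.
#'
#' @param wild,mutant [ProteinStructure-class] objects.
#' @param resno Residue number of the variant site.
#' @param chain Chain id (default: first chain containing `resno`).
#' @param boxSize Box edge length in Angstrom.
#' @return List with `wild` and `mutant` [MicroenvBox-class] objects.
#' @export
extractVariantPair <- function(wild, mutant, resno, chain = NULL,
                               boxSize = 20) {
  findKey <- function(structure) {
    rt <- residueTable(structure)
    cond <- rt$resno == resno
    if (!is.null(chain)) cond <- cond & rt$chain == chain
    hit <- rt[cond, ]
    if (nrow(hit) == 0)
      stop("residue ", resno, " not mappable in structure ", structure@id)
    hit$key[1]
  }
  list(wild = extractBox(wild, findKey(wild), boxSize = boxSize),
       mutant = extractBox(mutant, findKey(mutant), boxSize = boxSize))
}

#' Substitution-score features for a variant site
#'
#' With WT/WP the true/predicted wild-type labels and MT/MP the
#' true/predicted mutant labels, the feature sets are score-matrix lookups:
#' \itemize{
#'   \item 6-Feature: S(WT,WP), S(WT,MT), S(WT,MP), S(WP,MT), S(WP,MP),
#'     S(MT,MP)
#'   \item 3-Feature: S(WT,WP), S(WT,MT), S(WP,MT)
#'   \item 1-Feature: S(WT,MT)
#' }
#'
#' @param wt,mt True wild-type and mutant amino acids (one-letter).
#' @param wp,mp Predicted labels for the wild-type and mutant
#'   microenvironments; required for arity 3 (wp) and 6 (wp, mp).
#' @param scores A [SubstitutionScores-class] or named square matrix.
#' @param arity 1, 3 or 6.
#' @return Named numeric feature vector of length `arity`.
#' @export
buildMutationFeatures <- function(wt, mt, wp = NULL, mp = NULL, scores,
                                  arity = 6) {
  S <- if (is(scores, "SubstitutionScores")) scores@matrix else scores
  if (!arity %in% c(1, 3, 6)) stop("arity must be 1, 3 or 6")
  if (arity >= 3 && is.null(wp))
    stop("predicted wild-type label (wp) required for arity >= 3")
  if (arity == 6 && is.null(mp))
    stop("predicted mutant label (mp) required for arity 6")
  look <- function(i, j) S[i, j]
  feats <- switch(as.character(arity),
    "1" = c(S_WT_MT = look(wt, mt)),
    "3" = c(S_WT_WP = look(wt, wp), S_WT_MT = look(wt, mt),
            S_WP_MT = look(wp, mt)),
    "6" = c(S_WT_WP = look(wt, wp), S_WT_MT = look(wt, mt),
            S_WT_MP = look(wt, mp), S_WP_MT = look(wp, mt),
            S_WP_MP = look(wp, mp), S_MT_MP = look(mt, mp)))
  feats
}

#' Feature matrix for a variant table
#'
#' @param variants Data frame as from [loadT4Variants()], optionally with
#'   `wp` and `mp` prediction columns.
#' @inheritParams buildMutationFeatures
#' @return Numeric matrix, one row per variant.
#' @export
variantFeatureMatrix <- function(variants, scores, arity = 6) {
  rows <- lapply(seq_len(nrow(variants)), function(i)
    buildMutationFeatures(variants$wt[i], variants$mt[i],
                          wp = variants$wp[i], mp = variants$mp[i],
                          scores = scores, arity = arity))
  out <- do.call(rbind, rows)
  rownames(out) <- variants$variant
  out
}

.stratifiedFolds <- function(y, folds, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      i <- sample(which(y == cl))
      fold[i] <- rep_len(seq_len(folds), length(i))
    }
  })
  fold
}

#' Cross-validated mutation-effect classification
#'
#' Stratified k-fold cross validation of a Lasso regression (prediction
#' thresholded at 0.5 against 0/1-coded effects) or an RBF-kernel SVM on
#' substitution-score features.  Features are standardized with statistics
#' fitted on the training folds only.  Effects are coded destabilizing = 1,
#' neutral = 0.
#'
#' @param features Numeric matrix, one row per variant.
#' @param effects Vector coercible to 0/1 (accepts "Neutral"/"Destabilizing"
#'   labels).
#' @param model "lasso" or "svm".
#' @param folds Number of folds (default 4).
#' @param seed Integer seed for the fold assignment.
#' @param lambda Lasso penalty (default 0.01).
#' @param cost,gamma SVM parameters (defaults 1 and 1/ncol(features)).
#' @return List with per-fold train/test accuracies, their means, and the
#'   configuration used.
#' @export
cvClassify <- function(features, effects, model = c("lasso", "svm"),
                       folds = 4, seed = 1, lambda = 0.01, cost = 1,
                       gamma = NULL) {
  model <- match.arg(model)
  features <- as.matrix(features)
  y <- if (is.numeric(effects)) as.integer(effects) else
    as.integer(tolower(as.character(effects)) == "destabilizing")
  if (length(unique(y)) < 2) stop("need both effect classes")
  if (min(table(y)) < folds)
    stop("need at least ", folds, " examples per class")
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  fold <- .stratifiedFolds(y, folds, seed)
  trainAcc <- testAcc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- colMeans(features[tr, , drop = FALSE])
    sdv <- apply(features[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(features[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(features[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    if (model == "lasso") {
      if (all(apply(Xtr, 2, stats::sd) == 0)) {
        # degenerate all-constant features: intercept-only fit
        mu_y <- mean(y[tr])
        predBin <- function(X) rep(as.integer(mu_y > 0.5), nrow(X))
      } else {
        # glmnet needs >= 2 columns; a zero dummy column is inert
        pad <- function(X) if (ncol(X) == 1) cbind(X, 0) else X
        fit <- glmnet::glmnet(pad(Xtr), y[tr], alpha = 1, lambda = lambda,
                              family = "gaussian", standardize = FALSE)
        predBin <- function(X)
          as.integer(drop(stats::predict(fit, pad(X))) > 0.5)
      }
    } else {
      fit <- e1071::svm(Xtr, factor(y[tr], levels = c(0, 1)),
                        kernel = "radial", cost = cost, gamma = gamma,
                        scale = FALSE)
      predBin <- function(X)
        as.integer(as.character(stats::predict(fit, X)))
    }
    trainAcc[f] <- mean(predBin(Xtr) == y[tr])
    testAcc[f] <- mean(predBin(Xte) == y[!tr])
  }
  list(trainAcc = trainAcc, testAcc = testAcc,
       meanTrain = mean(trainAcc), meanTest = mean(testAcc),
       config = list(model = model, folds = folds, seed = seed,
                     lambda = lambda, cost = cost, gamma = gamma))
}
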