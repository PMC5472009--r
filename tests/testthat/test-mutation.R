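test_that("the bundled T4 lysozyme variant table parses cleanly", {
  v <- loadT4Variants()
  expect_equal(nrow(v), 40)
  expect_true(all(v$wt != v$mt))
  expect_true(all(v$wt %in% aminoAcids()) && all(v$mt %in% aminoAcids()))
  g77a <- v[v$variant == "G77A", ]
  expect_equal(g77a$wt, "G")
  expect_equal(g77a$mt, "A")
  expect_equal(g77a$effect, "Neutral")
  expect_equal(g77a$mutant_pdb, "1L23")
  r96d <- v[v$variant == "R96D", ]
  expect_equal(r96d$effect, "Destabilizing")
  # names re-parse consistently
  for (i in seq_len(nrow(v))) {
    p <- parseVariant(v$variant[i])
    expect_equal(c(p$wt, p$mt), c(v$wt[i], v$mt[i]))
  }
  expect_error(parseVariant("G77G"), "equal")
  expect_error(parseVariant("77A"), "unparseable")
})

test_that("feature builders follow the 6/3/1 index pattern exactly", {
  S <- loadStandardMatrix("BLOSUM62")@matrix
  f6 <- buildMutationFeatures("G", "A", wp = "A", mp = "G", S, arity = 6)
  expect_equal(unname(f6),
               c(S["G", "A"], S["G", "A"], S["G", "G"],
                 S["A", "A"], S["A", "G"], S["A", "G"]))
  expect_equal(names(f6), c("S_WT_WP", "S_WT_MT", "S_WT_MP",
                            "S_WP_MT", "S_WP_MP", "S_MT_MP"))
  f3 <- buildMutationFeatures("G", "A", wp = "A", scores = S, arity = 3)
  expect_equal(unname(f3), unname(f6[c(1, 2, 4)]))
  # degenerate case: every lookup is the same cell
  fL <- buildMutationFeatures("L", "W", wp = "L", mp = "L", S, arity = 6)
  expect_equal(unname(fL),
               c(S["L", "L"], S["L", "W"], S["L", "L"],
                 S["L", "W"], S["L", "L"], S["W", "L"]))
  # arity 1 ignores predictions entirely
  expect_equal(buildMutationFeatures("G", "A", scores = S, arity = 1),
               buildMutationFeatures("G", "A", wp = "W", mp = "Y", scores = S,
                                     arity = 1))
  expect_error(buildMutationFeatures("G", "A", scores = S, arity = 3), "wp")
  expect_error(buildMutationFeatures("G", "A", wp = "A", scores = S, arity = 6),
               "mp")
})

test_that("symmetric matrices make the 1-feature swap invariant", {
  S <- sFreq(new("ConfusionMatrix",
                 counts = matrix(c(5L, 2L, 1L, 7L), 2,
                                 dimnames = list(c("A", "C"), c("A", "C"))),
                 classes = c("A", "C")))
  expect_equal(buildMutationFeatures("A", "C", scores = S, arity = 1),
               buildMutationFeatures("C", "A", scores = S, arity = 1),
               ignore_attr = TRUE)
})

test_that("feature lookups are equivariant under joint relabeling", {
  set.seed(70)
  aa <- c("A", "C", "D", "E")
  S <- matrix(rnorm(16), 4, dimnames = list(aa, aa))
  perm <- c(D = "A", A = "C", C = "D", E = "E")
  Sp <- S
  rownames(Sp) <- colnames(Sp) <- perm[aa]
  Sp <- Sp[aa, aa]
  f1 <- buildMutationFeatures("A", "C", wp = "D", mp = "E", S, arity = 6)
  f2 <- buildMutationFeatures(perm[["A"]], perm[["C"]], wp = perm[["D"]],
                              mp = perm[["E"]], Sp, arity = 6)
  expect_equal(unname(f1), unname(f2))
})

test_that("wild/mutant boxes coincide when only the side chain differs", {
  wild <- syntheticStructure(25, seed = 71, noise = 0.05, id = "wt")
  mutant <- wild
  mutant@id <- "mt"
  site <- residueTable(wild)[12, ]
  wild@atoms$resid[wild@atoms$resno == site$resno] <- "ALA"
  mutant@atoms$resid[mutant@atoms$resno == site$resno] <- "ALA"
  site$aa <- "A"
  mutant@atoms$resid[mutant@atoms$resno == site$resno] <- "VAL"
  pair <- extractVariantPair(wild, mutant, site$resno)
  expect_equal(pair$wild@atoms[, c("x", "y", "z")],
               pair$mutant@atoms[, c("x", "y", "z")])
  expect_equal(pair$wild@label, "A")
  expect_equal(pair$mutant@label, "V")
  # a backbone shift at a neighbor changes the box
  shifted <- mutant
  nb <- which(shifted@atoms$resno == site$resno + 1)
  shifted@atoms$x[nb] <- shifted@atoms$x[nb] + 0.5
  pair2 <- extractVariantPair(wild, shifted, site$resno)
  expect_gt(max(abs(as.matrix(pair2$mutant@atoms[, c("x", "y", "z")]) -
                    as.matrix(pair$mutant@atoms[, c("x", "y", "z")]))), 0.1)
  expect_error(extractVariantPair(wild, mutant, 999), "not mappable")
})

test_that("cross-validation separates separable features and respects folds", {
  set.seed(72)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  sep <- cbind(y * 4 + rnorm(n, sd = 0.1), rnorm(n))
  for (m in c("lasso", "svm")) {
    res <- cvClassify(sep, y, m, seed = 1)
    expect_equal(res$meanTest, 1.0)
    expect_length(res$testAcc, 4)
  }
  # constant features predict the majority class
  const <- matrix(1, 40, 2)
  y2 <- rep(c(0, 1), times = c(25, 15))
  res2 <- cvClassify(const, y2, "lasso", seed = 2)
  expect_equal(res2$meanTest, 25 / 40, tolerance = 0.05)
  expect_error(cvClassify(sep, rep(0, n), "svm"), "both effect classes")
})

test_that("fold partitions are disjoint, stratified covers", {
  y <- rep(c(0, 1), times = c(24, 16))
  fold <- MicroEnvNet:::.stratifiedFolds(y, 4, seed = 3)
  expect_equal(sort(unique(fold)), 1:4)
  expect_equal(as.numeric(table(fold)), rep(10, 4))
  for (f in 1:4) expect_equal(sum(y == 1 & fold == f), 4)
})

test_that("permuted labels score at chance", {
  set.seed(73)
  X <- matrix(rnorm(40 * 3), 40)
  accs <- replicate(200, {
    y <- sample(rep(c(0, 1), each = 20))
    cvClassify(X, y, "lasso", seed = 4)$meanTest
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("variant feature matrices score the full fixture", {
  v <- loadT4Variants()
  S <- loadStandardMatrix("BLOSUM62")
  feats <- variantFeatureMatrix(v, S, arity = 1)
  expect_equal(dim(feats), c(40, 1))
  res <- cvClassify(feats, v$effect, "lasso", seed = 5)
  expect_true(res$meanTest >= 0 && res$meanTest <= 1)
  expect_length(res$trainAcc, 4)
})
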