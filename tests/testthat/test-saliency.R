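test_that("all-zero inputs give the all-zero importance map", {
  net <- tinyNet(seed = 80)
  m <- importanceMap(net, array(0, c(2, 6, 6, 6)), 1)
  expect_equal(max(abs(m@raw)), 0)
  expect_equal(max(m@normalized), 0)
  expect_error(importanceMap(net, array(0, c(2, 6, 6, 6)), 7), "class")
})

test_that("gradient-times-input is exact for a purely linear model", {
  # no hidden layers: score_k(x) = W[, k] . x + b, so zeroing voxel v
  # changes the score by exactly W[v, k] * x[v] = the raw importance
  net <- buildVoxelNet(list(), inputShape = c(2L, 4L, 4L, 4L), nClasses = 3,
                       dropout = 0, seed = 81)
  set.seed(82)
  x <- array(rnorm(128), c(2, 4, 4, 4))
  m <- importanceMap(net, x, 2)
  scoreOf <- function(xx) MicroEnvNet:::.forwardOne(net, xx)$logits[2]
  for (v in sample(128, 10)) {
    xz <- x
    xz[v] <- 0
    expect_equal(m@raw[v], scoreOf(x) - scoreOf(xz), tolerance = 1e-10)
  }
})

test_that("importance gradients match finite differences on a small CNN", {
  net <- tinyNet(seed = 83)
  set.seed(84)
  x <- array(rnorm(432), c(2, 6, 6, 6))
  for (sc in c("logit", "probability")) {
    g <- inputGradient(net, x, 2, score = sc)
    scoreOf <- function(xx) {
      z <- MicroEnvNet:::.forwardOne(net, xx)$logits
      if (sc == "logit") z[2] else MicroEnvNet:::.softmax(z)[2]
    }
    eps <- 1e-5
    for (v in sample(432, 8)) {
      xp <- x; xp[v] <- x[v] + eps
      xm <- x; xm[v] <- x[v] - eps
      num <- (scoreOf(xp) - scoreOf(xm)) / (2 * eps)
      expect_lt(abs(num - g[v]) / max(abs(num) + abs(g[v]), 1e-6), 1e-3)
    }
  }
})

test_that("normalization reaches 100, stays in range and is idempotent", {
  net <- tinyNet(seed = 85)
  set.seed(86)
  m <- importanceMap(net, array(rnorm(432), c(2, 6, 6, 6)), 1)
  expect_gte(min(m@normalized), 0)
  expect_equal(max(m@normalized), 100)
  renorm <- function(a) {
    rng <- range(abs(a))
    (abs(a) - rng[1]) / (rng[2] - rng[1]) * 100
  }
  expect_equal(renorm(m@normalized), m@normalized, tolerance = 1e-9)
})

test_that("atom attribution sums support voxels and rescales to 100", {
  oneAtom <- new("MicroenvBox", label = "A",
                 atoms = data.frame(element = "C", x = 0.2, y = 0.2, z = 0.2,
                                    serial = 7L),
                 structureId = "t", centerKey = "c", center = c(0, 0, 0),
                 boxSize = 20)
  norm <- array(0, c(4, 20, 20, 20))
  norm[2, 11, 11, 11] <- 100  # C channel
  map <- new("ImportanceMap", raw = norm, normalized = norm, trueClass = 1L)
  sc <- scoresToAtoms(map, oneAtom)
  expect_equal(sc$score, 100)
  # symmetric voxel mass gives mirrored atoms equal scores
  twoAtoms <- oneAtom
  twoAtoms@atoms <- data.frame(element = c("N", "N", "O"),
                               x = c(3.5, -3.5, 0.5), y = 0.5, z = 0.5,
                               serial = 1:3)
  sym <- array(0, c(4, 20, 20, 20))
  sym[3, 14, 10, 10] <- 100  # N at +3.5 -> voxel 14
  sym[3, 7, 10, 10] <- 100   # N at -3.5 -> voxel 7
  map2 <- new("ImportanceMap", raw = sym, normalized = sym, trueClass = 1L)
  sc2 <- scoresToAtoms(map2, twoAtoms)
  expect_equal(sc2$score[1], sc2$score[2], tolerance = 1e-6)
  # atoms outside the four channels score zero
  other <- oneAtom
  other@atoms <- data.frame(element = c("C", "other"), x = c(0.2, 0.4),
                            y = 0.2, z = 0.2, serial = 1:2)
  sc3 <- scoresToAtoms(map, other)
  expect_equal(sc3$score[sc3$element == "other"], 0)
})

test_that("B-factor export round-trips the score ranking", {
  s <- syntheticStructure(20, seed = 87, noise = 0.05)
  key <- residueTable(s)$key[8]
  box <- extractBox(s, key)
  set.seed(88)
  scores <- data.frame(serial = box@atoms$serial,
                       element = box@atoms$element,
                       score = runif(nrow(box@atoms), 0, 99))
  scores$score[3] <- 100
  f <- tempfile(fileext = ".pdb")
  exportBfactor(s, scores, f)
  s2 <- readPDB(f)
  expect_true(all(s2@atoms$bfactor >= 0 & s2@atoms$bfactor <= 100))
  expect_equal(max(s2@atoms$bfactor), 100)
  inBox <- s2@atoms$bfactor[match(scores$serial, s2@atoms$serial)]
  expect_equal(order(inBox), order(scores$score), tolerance = 0)
  outside <- setdiff(s2@atoms$serial, scores$serial)
  expect_true(all(s2@atoms$bfactor[match(outside, s2@atoms$serial)] == 0))
})

test_that("importance maps inherit the pipeline's rigid-motion invariance", {
  s <- syntheticStructure(25, seed = 89, noise = 0.05)
  key <- residueTable(s)$key[10]
  net <- buildVoxelNet(list(convSpec(2, 3), poolSpec(), denseSpec(4)),
                       inputShape = c(4L, 20L, 20L, 20L), nClasses = 20,
                       dropout = 0, seed = 90)
  g0 <- voxelize(extractBox(s, key))
  m0 <- importanceMap(net, g0, 1)
  s2 <- transformStructure(s, randomRigidMotion(91))
  g1 <- voxelize(extractBox(s2, key))
  m1 <- importanceMap(net, g1, 1)
  expect_equal(m1@raw, m0@raw, tolerance = 1e-6)
})
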