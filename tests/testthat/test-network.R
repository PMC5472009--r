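test_that("conv forward matches the brute-force loop oracle", {
  set.seed(50)
  x <- array(rnorm(4 * 6^3), c(4, 6, 6, 6))
  W <- array(rnorm(4 * 27 * 3), c(4, 3, 3, 3, 3))
  b <- rnorm(3)
  fast <- cpp_conv3d_forward(x, dim(x), W, dim(W), b)
  fast <- fast * (fast > 0)
  expect_lt(max(abs(fast - naiveConv3d(x, W, b))), 1e-5)
})

test_that("conv responses and ReLU behave on hand-computed cases", {
  x <- array(1, c(1, 3, 3, 3))
  W <- array(1, c(1, 3, 3, 3, 1))
  expect_equal(as.numeric(cpp_conv3d_forward(x, dim(x), W, dim(W), 0)), 27)
  # bias -30 drives the response negative; ReLU clamps to 0
  out <- cpp_conv3d_forward(x, dim(x), W, dim(W), -30)
  expect_equal(max(as.numeric(out), 0), 0)
  expect_error(cpp_conv3d_forward(x, dim(x),
                                  array(1, c(2, 3, 3, 3, 1)), c(2, 3, 3, 3, 1),
                                  0),
               "channel mismatch")
})

test_that("max pooling reduces 2x2x2 blocks to their maxima", {
  x <- array(1:8, c(1, 2, 2, 2))
  expect_equal(as.numeric(cpp_maxpool_forward(x, dim(x))$out), 8)
  const <- array(3.5, c(2, 4, 4, 4))
  expect_true(all(cpp_maxpool_forward(const, dim(const))$out == 3.5))
  big <- array(rnorm(200 * 16^3), c(200, 16, 16, 16))
  expect_equal(dim(cpp_maxpool_forward(big, dim(big))$out), c(200, 8, 8, 8))
  odd <- array(0, c(1, 3, 3, 3))
  expect_error(cpp_maxpool_forward(odd, dim(odd)), "even")
})

test_that("shape propagation reproduces the default output volumes", {
  chain <- shapePropagate(defaultVoxelNetLayers())
  expect_equal(chain$conv1, c(100, 18, 18, 18))
  expect_equal(chain$conv2, c(200, 16, 16, 16))
  expect_equal(chain$pool3, c(200, 8, 8, 8))
  expect_equal(chain$conv4, c(400, 6, 6, 6))
  expect_equal(chain$pool5, c(400, 3, 3, 3))
  expect_equal(chain$flatten6, 10800)
  expect_equal(chain$dense6, 1000)
  expect_equal(chain$dense7, 100)
  expect_equal(chain$softmax, 20)
  # full-extent filter leaves a single voxel
  one <- shapePropagate(list(convSpec(5, 20)))
  expect_equal(one$conv1, c(5, 1, 1, 1))
  # non-divisible pooling names the offending layer
  expect_error(shapePropagate(list(convSpec(2, 4), poolSpec())),
               "pool layer 2")
})

test_that("receptive fields follow the recursive rf/jump computation", {
  expect_equal(receptiveField(defaultVoxelNetLayers()), 12)
  expect_equal(receptiveField(list(convSpec(1, 3))), 3)
  expect_equal(receptiveField(list(convSpec(1, 3), convSpec(1, 3))), 5)
})

test_that("MLP and descriptor-head constructors enforce their shapes", {
  expect_error(buildMLP(hidden = integer(0)), "hidden")
  mlp <- buildMLP(hidden = c(8, 4), seed = 2)
  expect_equal(nrow(mlp@layers[[1]]$W), 4 * 20^3)    # flatten = 32000
  head <- buildVectorHead(seed = 2)
  chain <- shapePropagate(list(denseSpec(100)), inputShape = 480L)
  expect_equal(chain$dense1, 100)
  expect_equal(chain$softmax, 20)
  expect_equal(dim(head@layers[[1]]$W), c(480, 100))
  expect_equal(dim(head@layers[[2]]$W), c(100, 20))
})

test_that("predictions live on the probability simplex and are deterministic", {
  net <- tinyNet(seed = 5)
  set.seed(6)
  X <- matrix(rnorm(3 * 432), nrow = 3)
  X <- rbind(X, X[1, ])                      # duplicate input
  pred <- predictNetwork(net, X)
  expect_equal(rowSums(pred$prob), rep(1, 4), tolerance = 1e-6)
  expect_true(all(pred$prob >= 0))
  expect_equal(pred$prob[4, ], pred$prob[1, ])
  # zeroed classifier weights give the uniform distribution
  net0 <- net
  k <- length(net0@layers)
  net0@layers[[k]]$W[] <- 0
  net0@layers[[k]]$b[] <- 0
  p0 <- predictNetwork(net0, X[1, , drop = FALSE])$prob
  expect_equal(as.numeric(p0), rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(predictNetwork(net, matrix(0, 1, 10)), "input length")
})

test_that("a zero learning rate leaves the weights untouched", {
  net <- tinyNet(seed = 7)
  set.seed(8)
  ds <- new("LabeledVoxelSet", features = matrix(rnorm(6 * 432), 6),
            featureDim = c(2L, 6L, 6L, 6L),
            labels = factor(rep(c("class1", "class2", "class3"), 2)),
            split = "train")
  fit <- trainNetwork(net, ds, epochs = 2, lr = 0, seed = 9)
  for (i in seq_along(net@layers))
    if (!is.null(net@layers[[i]]$W))
      expect_identical(fit$final@layers[[i]]$W, net@layers[[i]]$W)
})

test_that("analytic gradients match central finite differences", {
  net <- tinyNet(seed = 10)
  set.seed(11)
  x <- rnorm(432)
  y <- 2L
  lossAt <- function(n) {
    p <- MicroEnvNet:::.softmax(MicroEnvNet:::.forwardOne(n, x)$logits)
    -log(p[y])
  }
  fw <- MicroEnvNet:::.forwardOne(net, x, keepCache = TRUE)
  p <- MicroEnvNet:::.softmax(fw$logits)
  bk <- MicroEnvNet:::.backwardOne(net, fw$cache,
                                   p - MicroEnvNet:::.oneHot(y, 3))
  eps <- 1e-5
  for (li in seq_along(net@layers)) {
    if (is.null(bk$grads[[li]])) next
    W <- net@layers[[li]]$W
    for (j in sample(length(W), 12)) {
      n2 <- net
      n2@layers[[li]]$W[j] <- W[j] + eps
      lp <- lossAt(n2)
      n2@layers[[li]]$W[j] <- W[j] - eps
      lm <- lossAt(n2)
      num <- (lp - lm) / (2 * eps)
      ana <- bk$grads[[li]]$W[j]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-6), 1e-3)
    }
  }
})

test_that("L2 regularization shrinks the weight norm", {
  set.seed(12)
  ds <- new("LabeledVoxelSet", features = matrix(rnorm(20 * 432), 20),
            featureDim = c(2L, 6L, 6L, 6L),
            labels = factor(rep(c("class1", "class2"), 10),
                            levels = c("class1", "class2", "class3")),
            split = "train")
  net <- tinyNet(seed = 13)
  wnorm <- function(m) sqrt(sum(unlist(lapply(m@layers, function(l)
    if (is.null(l$W)) 0 else sum(l$W^2)))))
  f0 <- trainNetwork(net, ds, epochs = 2, lr = 0.05, l2 = 0, seed = 14)
  f1 <- trainNetwork(net, ds, epochs = 2, lr = 0.05, l2 = 0.1, seed = 14)
  expect_lt(wnorm(f1$final), wnorm(f0$final))
})

test_that("training is deterministic given the seed", {
  set.seed(15)
  ds <- new("LabeledVoxelSet", features = matrix(rnorm(9 * 432), 9),
            featureDim = c(2L, 6L, 6L, 6L),
            labels = factor(rep(c("class1", "class2", "class3"), 3)),
            split = "train")
  net <- tinyNet(dropout = 0.3, seed = 16)
  f1 <- trainNetwork(net, ds, epochs = 2, lr = 0.01, seed = 17)
  f2 <- trainNetwork(net, ds, epochs = 2, lr = 0.01, seed = 17)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$final@layers, f2$final@layers)
})
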