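# The 3D convolutional classifier: layer specifications, shape and
# receptive-field arithmetic, forward/backward passes (conv and pooling
# kernels compiled, dense algebra in BLAS), and the SGD training loop.

#' Layer specifications
#'
#' `convSpec(filters, size)` is a stride-1 3D convolution with cubic filters
#' followed by ReLU; `poolSpec()` is 2x2x2 max pooling with stride 2;
#' `denseSpec(units)` is a fully connected ReLU layer (the input is
#' flattened on first use).
#'
#' @param filters Number of filters.
#' @param size Cubic filter side length in voxels.
#' @param units Number of output neurons.
#' @return A layer specification list.
#' @export
convSpec <- function(filters, size = 3) {
  stopifnot(filters >= 1, size >= 1)
  list(type = "conv", filters = as.integer(filters), size = as.integer(size))
}

#' @rdname convSpec
#' @export
poolSpec <- function() list(type = "pool")

#' @rdname convSpec
#' @export
denseSpec <- function(units) {
  stopifnot(units >= 1)
  list(type = "dense", units = as.integer(units))
}

#' The default deep 3DCNN layer stack
#'
#' Conv(100, 3) - Conv(200, 3) - Pool - Conv(400, 3) - Pool -
#' Dense(1000) - Dense(100), followed by a linear softmax classifier over
#' the 20 classes added by [buildVoxelNet()].
#'
#' @return List of layer specifications.
#' @export
defaultVoxelNetLayers <- function() {
  list(convSpec(100, 3), convSpec(200, 3), poolSpec(),
       convSpec(400, 3), poolSpec(),
       denseSpec(1000), denseSpec(100))
}

#' Propagate tensor shapes through a layer stack
#'
#' Reproduces the output-volume arithmetic of the architecture: a conv layer
#' maps spatial side s to s - F + 1, pooling halves each (even) side, dense
#' layers flatten their input.  The softmax classifier output (`nClasses`)
#' terminates the chain.
#'
#' @param layers List of layer specifications (see [convSpec()]).
#' @param inputShape Integer vector, channel-first (e.g. c(4, 20, 20, 20)),
#'   or a single length for vector inputs.
#' @param nClasses Number of classifier outputs appended to the chain.
#' @return List of integer shape vectors, one per stage, including the
#'   flattened dense input sizes and the final class-score length.
#' @export
shapePropagate <- function(layers, inputShape = c(4L, 20L, 20L, 20L),
                           nClasses = 20) {
  shape <- as.integer(inputShape)
  chain <- list(input = shape)
  i <- 0
  for (ly in layers) {
    i <- i + 1
    nm <- paste0(ly$type, i)
    if (ly$type == "conv") {
      if (length(shape) != 4) stop("conv layer ", i, " needs a 4D input")
      side <- shape[2:4] - ly$size + 1L
      if (any(side < 1)) stop("conv layer ", i, " filter exceeds input side")
      shape <- c(ly$filters, side)
    } else if (ly$type == "pool") {
      if (length(shape) != 4) stop("pool layer ", i, " needs a 4D input")
      if (any(shape[2:4] %% 2L != 0L))
        stop("pool layer ", i, " requires even spatial sides, got ",
             paste(shape[2:4], collapse = "x"))
      shape <- c(shape[1], shape[2:4] %/% 2L)
    } else if (ly$type == "dense") {
      if (length(shape) > 1) {
        shape <- prod(shape)
        chain[[paste0("flatten", i)]] <- as.integer(shape)
      }
      shape <- ly$units
    } else stop("unknown layer type: ", ly$type)
    chain[[nm]] <- as.integer(shape)
  }
  chain[["softmax"]] <- as.integer(nClasses)
  chain
}

#' Receptive field of the conv/pool prefix
#'
#' Standard recursive receptive-field/jump computation over the convolution
#' and pooling prefix of a layer stack: each stride-1 conv of size F adds
#' (F - 1) * jump, each 2-stride pool adds jump and doubles it.
#'
#' @param layers List of layer specifications; dense layers terminate the
#'   prefix.
#' @return Receptive-field side length in input voxels.
#' @export
receptiveField <- function(layers) {
  rf <- 1
  jump <- 1
  for (ly in layers) {
    if (ly$type == "conv") {
      rf <- rf + (ly$size - 1) * jump
    } else if (ly$type == "pool") {
      rf <- rf + jump
      jump <- 2 * jump
    } else break
  }
  rf
}

.heInit <- function(fanIn, n) stats::rnorm(n, sd = sqrt(2 / fanIn))

#' Build a voxel classifier network
#'
#' Allocates He-initialized weights for the given layer stack and appends
#' the linear softmax classifier.  Dropout (inverted, applied after conv and
#' dense activations during training only) defaults to 0.3.
#'
#' @param layers Layer specifications (default [defaultVoxelNetLayers()]).
#' @param inputShape Channel-first input shape or vector length.
#' @param nClasses Number of output classes.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param seed Integer seed for weight initialization.
#' @param classNames Optional class labels (default [aminoAcids()] when
#'   nClasses is 20).
#' @return A [VoxelNet-class].
#' @export
buildVoxelNet <- function(layers = defaultVoxelNetLayers(),
                          inputShape = c(4L, 20L, 20L, 20L), nClasses = 20,
                          dropout = 0.3, seed = 1, classNames = NULL) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  chain <- shapePropagate(layers, inputShape, nClasses)  # validates stack
  if (is.null(classNames))
    classNames <- if (nClasses == 20) aminoAcids() else
      paste0("class", seq_len(nClasses))
  stopifnot(length(classNames) == nClasses)
  shape <- as.integer(inputShape)
  built <- list()
  withr::with_seed(seed, {
    for (ly in layers) {
      if (ly$type == "conv") {
        C <- shape[1]; F <- ly$size; L <- ly$filters
        W <- array(.heInit(C * F^3, C * F^3 * L), dim = c(C, F, F, F, L))
        built[[length(built) + 1]] <- list(type = "conv", W = W,
                                           b = numeric(L))
        shape <- c(L, shape[2:4] - F + 1L)
      } else if (ly$type == "pool") {
        built[[length(built) + 1]] <- list(type = "pool")
        shape <- c(shape[1], shape[2:4] %/% 2L)
      } else {
        M <- prod(shape); N <- ly$units
        W <- matrix(.heInit(M, M * N), M, N)
        built[[length(built) + 1]] <- list(type = "dense", W = W,
                                           b = numeric(N))
        shape <- N
      }
    }
    M <- prod(shape)
    built[[length(built) + 1]] <-
      list(type = "linear", W = matrix(.heInit(M, M * nClasses), M, nClasses),
           b = numeric(nClasses))
  })
  new("VoxelNet", layers = built, inputShape = as.integer(inputShape),
      nClasses = as.integer(nClasses), dropout = dropout,
      classNames = classNames)
}

#' Multi-layer perceptron over flattened voxel tensors
#'
#' Flattens the channel tensor (4 * 20^3 = 32000 components by default) and
#' applies fully connected hidden layers; at least one hidden layer is
#' required.
#'
#' @param hidden Integer vector of hidden layer sizes (default c(1000, 100)).
#' @inheritParams buildVoxelNet
#' @return A [VoxelNet-class].
#' @export
buildMLP <- function(hidden = c(1000, 100), inputShape = c(4L, 20L, 20L, 20L),
                     nClasses = 20, dropout = 0.3, seed = 1) {
  if (length(hidden) < 1) stop("the MLP needs at least one hidden layer")
  buildVoxelNet(lapply(hidden, denseSpec), inputShape, nClasses, dropout,
                seed)
}

#' Softmax head for precomputed 480-length microenvironment descriptors
#'
#' Dense(480 -> 100) - Dense(100 -> 20) softmax classifier with dropout 0.3.
#'
#' @param inputLen Descriptor length (default 480).
#' @param hidden Hidden layer size (default 100).
#' @inheritParams buildVoxelNet
#' @return A [VoxelNet-class].
#' @export
buildVectorHead <- function(inputLen = 480, hidden = 100, nClasses = 20,
                            dropout = 0.3, seed = 1) {
  buildVoxelNet(list(denseSpec(hidden)), inputShape = as.integer(inputLen),
                nClasses = nClasses, dropout = dropout, seed = seed)
}

# Forward pass for one example.  Returns logits and, when keepCache, the
# per-layer quantities backprop needs.  Dropout masks are drawn from the
# current RNG state only when train = TRUE.
.forwardOne <- function(net, x, train = FALSE, keepCache = FALSE) {
  cur <- if (length(net@inputShape) > 1)
    array(as.numeric(x), dim = net@inputShape) else as.numeric(x)
  cache <- list()
  p <- net@dropout
  for (i in seq_along(net@layers)) {
    ly <- net@layers[[i]]
    entry <- list(input = cur)
    if (ly$type == "conv") {
      pre <- cpp_conv3d_forward(cur, dim(cur), ly$W, dim(ly$W), ly$b)
      mask <- pre > 0
      cur <- pre * mask
      entry$mask <- mask
      if (train && p > 0) {
        dmask <- (stats::runif(length(cur)) >= p) / (1 - p)
        cur <- cur * dmask
        entry$dmask <- dmask
      }
    } else if (ly$type == "pool") {
      res <- cpp_maxpool_forward(cur, dim(cur))
      entry$argmax <- res$argmax
      entry$indim <- dim(cur)
      cur <- res$out
    } else {  # dense / linear
      flat <- as.numeric(cur)
      entry$flatdim <- dim(cur)
      entry$input <- flat
      pre <- drop(crossprod(ly$W, flat)) + ly$b
      if (ly$type == "dense") {
        mask <- pre > 0
        cur <- pre * mask
        entry$mask <- mask
        if (train && p > 0) {
          dmask <- (stats::runif(length(cur)) >= p) / (1 - p)
          cur <- cur * dmask
          entry$dmask <- dmask
        }
      } else cur <- pre
    }
    if (keepCache) cache[[i]] <- entry
  }
  list(logits = cur, cache = cache)
}

# Backward pass from a gradient on the logits down to the input.
.backwardOne <- function(net, cache, gradLogits) {
  grads <- vector("list", length(net@layers))
  g <- gradLogits
  for (i in rev(seq_along(net@layers))) {
    ly <- net@layers[[i]]
    entry <- cache[[i]]
    if (ly$type %in% c("dense", "linear")) {
      if (ly$type == "dense") {
        if (!is.null(entry$dmask)) g <- g * entry$dmask
        g <- g * entry$mask
      }
      grads[[i]] <- list(W = outer(entry$input, g), b = g)
      g <- drop(ly$W %*% g)
      if (!is.null(entry$flatdim)) g <- array(g, dim = entry$flatdim)
    } else if (ly$type == "pool") {
      g <- cpp_maxpool_backward(g, entry$argmax, entry$indim)
    } else {  # conv
      if (!is.null(entry$dmask)) g <- g * entry$dmask
      g <- g * entry$mask
      bk <- cpp_conv3d_backward(entry$input, dim(entry$input), ly$W,
                                dim(ly$W), g)
      grads[[i]] <- list(W = bk$gw, b = bk$gb)
      g <- bk$gx
    }
  }
  list(grads = grads, gradInput = g)
}

.softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Class probabilities and argmax labels for new examples
#'
#' Dropout is disabled; each row of the probability matrix sums to 1.
#'
#' @param net A trained (or freshly built) [VoxelNet-class].
#' @param x A [LabeledVoxelSet-class], a numeric matrix with one flattened
#'   example per row, or a single array/vector example.
#' @return List with `prob` (N x nClasses matrix), `class` (character vector
#'   of predicted class names) and `logits`.
#' @export
predictNetwork <- function(net, x) {
  feat <- if (is(x, "LabeledVoxelSet")) x@features
          else if (is.matrix(x)) x
          else matrix(as.numeric(x), nrow = 1)
  if (ncol(feat) != prod(net@inputShape))
    stop("input length does not match the network input shape")
  n <- nrow(feat)
  prob <- matrix(NA_real_, n, net@nClasses,
                 dimnames = list(NULL, net@classNames))
  logits <- prob
  for (i in seq_len(n)) {
    z <- .forwardOne(net, feat[i, ], train = FALSE)$logits
    logits[i, ] <- z
    prob[i, ] <- .softmax(z)
  }
  list(prob = prob, class = net@classNames[max.col(prob, ties.method = "first")],
       logits = logits)
}

.oneHot <- function(idx, k) {
  v <- numeric(k)
  v[idx] <- 1
  v
}

.accuracy <- function(net, set) {
  if (is.null(set) || nrow(set@features) == 0) return(NA_real_)
  pred <- predictNetwork(net, set)
  mean(pred$class == as.character(set@labels))
}

#' Train a network by mini-batch stochastic gradient descent
#'
#' Categorical cross-entropy on the softmax outputs, plain SGD with an L2
#' weight penalty and inverted dropout.  Deterministic given the seed.  The
#' history records per-epoch mean training loss and accuracy plus validation
#' accuracy; the returned model is the checkpoint with the best validation
#' accuracy (the final weights when no validation set is given).
#'
#' @param net A [VoxelNet-class].
#' @param train Training [LabeledVoxelSet-class]; labels must be levels of
#'   the network's `classNames`.
#' @param val Optional validation [LabeledVoxelSet-class].
#' @param epochs Number of passes over the training data.
#' @param batchSize Mini-batch size (default 20).
#' @param lr Learning rate (default 0.01, constant).
#' @param l2 L2 regularization constant (default 0).
#' @param momentum Classical momentum coefficient (default 0 = plain SGD).
#' @param seed Integer seed controlling shuffling and dropout.
#' @return List with `model` (best checkpoint), `final` (last weights) and
#'   `history` (data frame epoch/trainLoss/trainAcc/valAcc).
#' @export
trainNetwork <- function(net, train, val = NULL, epochs = 10, batchSize = 20,
                         lr = 0.01, l2 = 0, momentum = 0, seed = 1) {
  labIdx <- match(as.character(train@labels), net@classNames)
  if (any(is.na(labIdx)))
    stop("training labels outside the network's class set")
  n <- nrow(train@features)
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     trainAcc = numeric(), valAcc = numeric())
  best <- net
  bestVal <- -Inf
  vel <- lapply(net@layers, function(l)
    if (is.null(l$W)) NULL else list(W = l$W * 0, b = l$b * 0))
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      correct <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / batchSize))) {
        acc <- NULL
        for (ex in bs) {
          fw <- .forwardOne(net, train@features[ex, ], train = TRUE,
                            keepCache = TRUE)
          pr <- .softmax(fw$logits)
          y <- labIdx[ex]
          loss <- -log(max(pr[y], 1e-300))
          if (!is.finite(loss)) stop("training diverged (non-finite loss)")
          losses <- c(losses, loss)
          correct <- correct + (which.max(pr) == y)
          bk <- .backwardOne(net, fw$cache, pr - .oneHot(y, net@nClasses))
          if (is.null(acc)) acc <- bk$grads
          else for (i in seq_along(acc)) if (!is.null(acc[[i]])) {
            acc[[i]]$W <- acc[[i]]$W + bk$grads[[i]]$W
            acc[[i]]$b <- acc[[i]]$b + bk$grads[[i]]$b
          }
        }
        B <- length(bs)
        for (i in seq_along(net@layers)) {
          if (is.null(acc[[i]])) next
          vel[[i]]$W <- momentum * vel[[i]]$W -
            lr * (acc[[i]]$W / B + l2 * net@layers[[i]]$W)
          vel[[i]]$b <- momentum * vel[[i]]$b - lr * acc[[i]]$b / B
          net@layers[[i]]$W <- net@layers[[i]]$W + vel[[i]]$W
          net@layers[[i]]$b <- net@layers[[i]]$b + vel[[i]]$b
        }
      }
      valAcc <- .accuracy(net, val)
      hist <- rbind(hist, data.frame(epoch = ep, trainLoss = mean(losses),
                                     trainAcc = correct / n,
                                     valAcc = valAcc))
      if (!is.na(valAcc) && valAcc >= bestVal) {
        bestVal <- valAcc
        best <- net
      }
    }
  })
  if (is.null(val)) best <- net
  list(model = best, final = net, history = hist)
}

#' Gradient of a class score with respect to the input
#'
#' Backpropagates from the chosen class's pre-softmax score (or post-softmax
#' probability) down to the input tensor, with dropout disabled.
#'
#' @param net A [VoxelNet-class].
#' @param x One example (array or numeric vector).
#' @param classIdx 1-based class index.
#' @param score "logit" (default) or "probability".
#' @return Numeric array of the input's shape.
#' @export
inputGradient <- function(net, x, classIdx, score = c("logit", "probability")) {
  score <- match.arg(score)
  if (classIdx < 1 || classIdx > net@nClasses) stop("class index out of range")
  fw <- .forwardOne(net, x, train = FALSE, keepCache = TRUE)
  k <- net@nClasses
  gradLogits <- if (score == "logit") .oneHot(classIdx, k) else {
    p <- .softmax(fw$logits)
    p[classIdx] * (.oneHot(classIdx, k) - p)
  }
  g <- .backwardOne(net, fw$cache, gradLogits)$gradInput
  if (length(net@inputShape) > 1) array(g, dim = net@inputShape)
  else as.numeric(g)
}

#' Save / load a model checkpoint
#'
#' Serializes the network (weights, shapes, dropout, class names) together
#' with optional normalization statistics.
#'
#' @param net A [VoxelNet-class].
#' @param path File path (RDS).
#' @param normStats Optional [NormalizationStats-class] stored alongside.
#' @return `path` invisibly / list with `model` and `normStats`.
#' @export
saveCheckpoint <- function(net, path, normStats = NULL) {
  saveRDS(list(model = net, normStats = normStats), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)

setMethod("show", "VoxelNet", function(object) {
  types <- vapply(object@layers, `[[`, character(1), "type")
  cat("VoxelNet: input (", paste(object@inputShape, collapse = ","), ") -> ",
      paste(types, collapse = " -> "), " -> softmax(", object@nClasses,
      "), dropout ", object@dropout, "\n", sep = "")
})
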