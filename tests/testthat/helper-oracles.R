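# Independent brute-force oracles, deliberately written formula-by-formula
# and kept free of the package's implementation paths.

# Direct six-nested-loop evaluation of the conv layer response with ReLU.
naiveConv3d <- function(x, W, b) {
  dx <- dim(x); C <- dx[1]; S <- dx[2]
  dw <- dim(W); F <- dw[2]; L <- dw[5]
  O <- S - F + 1
  out <- array(0, dim = c(L, O, O, O))
  for (l in 1:L) for (i in 1:O) for (j in 1:O) for (k in 1:O) {
    acc <- b[l]
    for (m in 1:F) for (n in 1:F) for (d in 1:F) for (c in 1:C)
      acc <- acc + W[c, m, n, d, l] * x[c, i + m - 1, j + n - 1, k + d - 1]
    out[l, i, j, k] <- max(acc, 0)
  }
  out
}

# Frequency-based substitution scores, computed cell by cell.
naiveSFreq <- function(M, floorVal = 1e-10) {
  k <- nrow(M); tot <- sum(M)
  Sp <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    p <- M[i, j] / tot
    qr <- sum(M[i, ]) / tot
    qc <- sum(M[, j]) / tot
    Sp[i, j] <- log(max(p / (qr * qc), floorVal))
  }
  (Sp + t(Sp)) / 2
}

# Dot-product substitution scores, computed cell by cell.
naiveSDot <- function(M, floorVal = 1e-10) {
  k <- nrow(M)
  Nr <- M / rowSums(M)
  Nc <- sweep(M, 2, colSums(M), "/")
  S <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    ri <- Nr[i, ] / sqrt(sum(Nr[i, ]^2))
    rj <- Nr[j, ] / sqrt(sum(Nr[j, ]^2))
    ci <- Nc[, i] / sqrt(sum(Nc[, i]^2))
    cj <- Nc[, j] / sqrt(sum(Nc[, j]^2))
    S[i, j] <- log(max(sum(ri * rj) + sum(ci * cj), floorVal))
  }
  S
}

# Agglomerative Ward clustering via the Lance-Williams update on squared
# Euclidean distances; returns the merge heights (sqrt scale, as ward.D2).
naiveWardHeights <- function(X) {
  n <- nrow(X)
  d2 <- as.matrix(dist(X))^2
  size <- rep(1, n)
  active <- 1:n
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestVal <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      i <- active[a]; j <- active[b]
      if (d2[i, j] < bestVal) { bestVal <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestVal))
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Nearest-centroid classifier on flattened features.
nearestCentroidAccuracy <- function(features, labels) {
  cents <- sapply(levels(labels), function(cl)
    colMeans(features[labels == cl, , drop = FALSE]))
  pred <- levels(labels)[apply(features, 1, function(x)
    which.min(colSums((cents - x)^2)))]
  mean(pred == as.character(labels))
}
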