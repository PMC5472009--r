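# Small vector helpers shared across modules.

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unitVec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Residue key: chain, residue number and insertion code uniquely identify a
# residue within a structure.
residueKey <- function(chain, resno, insert) {
  paste(chain, resno, ifelse(is.na(insert) | insert == "", ".", insert),
        sep = ":")
}

#' Random rigid motion (rotation + translation), for invariance testing
#'
#' Draws a uniformly random rotation matrix (QR of a Gaussian matrix with
#' sign fix, reflected into SO(3) if needed) and a translation.
#'
#' @param seed Integer seed.
#' @param maxShift Translation components are uniform in `[-maxShift, maxShift]`.
#' @return List with `R` (3x3 rotation) and `t` (length-3 translation).
#' @export
randomRigidMotion <- function(seed, maxShift = 20) {
  withr::with_seed(seed, {
    qr <- qr(matrix(stats::rnorm(9), 3, 3))
    R <- qr.Q(qr) %*% diag(sign(diag(qr.R(qr))))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    list(R = R, t = stats::runif(3, -maxShift, maxShift))
  })
}

#' Apply a rigid motion to all atoms of a structure
#'
#' @param structure A [ProteinStructure-class].
#' @param motion List with rotation `R` and translation `t`
#'   (see [randomRigidMotion()]).
#' @return The transformed [ProteinStructure-class].
#' @export
transformStructure <- function(structure, motion) {
  xyz <- as.matrix(structure@atoms[, c("x", "y", "z")])
  new_xyz <- xyz %*% t(motion$R) + rep(motion$t, each = nrow(xyz))
  structure@atoms$x <- new_xyz[, 1]
  structure@atoms$y <- new_xyz[, 2]
  structure@atoms$z <- new_xyz[, 3]
  structure
}
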