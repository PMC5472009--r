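#' @useDynLib MicroEnvNet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' The 20 standard amino acids, one-letter codes, alphabetical
#'
#' Fixed class ordering used for labels, confusion matrices and substitution
#' matrices throughout the package.
#'
#' @return Character vector of length 20.
#' @export
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.AA3 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
          HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
          PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
          TRP = "W", TYR = "Y")

.CHANNELS <- c("O", "C", "N", "S")

.atomCols <- c("serial", "name", "element", "resno", "resid", "chain",
               "insert", "x", "y", "z", "bfactor", "channel")

#' ProteinStructure: parsed protein coordinates
#'
#' Holds the ATOM records of a (possibly synthetic) protein structure after
#' filtering: hydrogens, waters and other HETATMs removed, first model only,
#' alternate locations resolved, standard residues only.  Atoms are stored as
#' a data frame with one row per atom; `element` is one of C, N, O, S or
#' "other", and `channel` flags membership in the four voxel channels.
#'
#' @slot id Character structure identifier.
#' @slot atoms Data frame of atom records.
#' @slot source Character, originating file path or "synthetic".
#' @export
setClass("ProteinStructure",
         representation(id = "character", atoms = "data.frame",
                        source = "character"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  if (!all(.atomCols %in% names(a)))
    return(paste("atoms must have columns:", paste(.atomCols, collapse = ", ")))
  if (nrow(a) == 0) return("structure has no atoms")
  if (!all(is.finite(c(a$x, a$y, a$z)))) return("non-finite coordinates")
  if (!all(a$element %in% c("C", "N", "O", "S", "other")))
    return("element must be one of C, N, O, S, other")
  TRUE
})

#' LocalFrame: backbone-derived orthonormal coordinate frame
#'
#' Right-handed orthonormal frame anchored on a residue's C-beta atom.  The
#' x axis points along N-CA, the z axis is normal to the N-CA / C-CA plane
#' with its sign fixed so that it has positive dot product with CA->CB.
#'
#' @slot origin Numeric length-3, the C-beta position (Angstrom).
#' @slot axes 3x3 numeric matrix; rows are the x, y, z unit vectors.
#' @export
setClass("LocalFrame",
         representation(origin = "numeric", axes = "matrix"))

setValidity("LocalFrame", function(object) {
  if (length(object@origin) != 3) return("origin must have length 3")
  A <- object@axes
  if (!all(dim(A) == c(3, 3))) return("axes must be 3x3")
  if (max(abs(A %*% t(A) - diag(3))) > 1e-8) return("axes not orthonormal")
  z <- crossprod3(A[1, ], A[2, ])
  if (max(abs(z - A[3, ])) > 1e-8) return("frame not right-handed")
  TRUE
})

#' MicroenvBox: one labeled, frame-aligned local atom neighborhood
#'
#' Atoms of the four channel elements inside the half-open cube
#' `[-boxSize/2, boxSize/2)^3` in local-frame coordinates, with the center
#' residue's side chain (everything but N, CA, C, O -- including CB) removed.
#' The label is the one-letter code of the center residue, i.e. the removed
#' side-chain type.
#'
#' @slot label One-letter amino-acid code of the center residue.
#' @slot atoms Data frame with columns element, x, y, z, serial (local coords).
#' @slot structureId Source structure identifier.
#' @slot centerKey Residue key "chain:resno:insert" of the center residue.
#' @slot center Global-frame C-beta position used as box center.
#' @slot boxSize Box edge length in Angstrom.
#' @export
setClass("MicroenvBox",
         representation(label = "character", atoms = "data.frame",
                        structureId = "character", centerKey = "character",
                        center = "numeric", boxSize = "numeric"))

setValidity("MicroenvBox", function(object) {
  h <- object@boxSize / 2
  a <- object@atoms
  if (nrow(a) &&
      (min(a$x, a$y, a$z) < -h || max(a$x, a$y, a$z) >= h))
    return("box atoms outside the half-open cube")
  if (nrow(a) && !all(a$element %in% c(.CHANNELS, "other")))
    return("box atoms must be channel elements (O, C, N, S) or 'other'")
  TRUE
})

#' VoxelGrid: the (4, 20, 20, 20) channel tensor
#'
#' Channel-first 4D array over 1 Angstrom voxels; channel order (O, C, N, S).
#' Before smoothing, entries are 0/1 atom occupancies; after smoothing each
#' channel holds a Gaussian-spread density.
#'
#' @slot data 4D numeric array, dim (channels, nx, ny, nz).
#' @slot channels Character vector naming the channels.
#' @slot smoothed Logical, whether Gaussian smoothing has been applied.
#' @slot boxId Provenance identifier.
#' @export
setClass("VoxelGrid",
         representation(data = "array", channels = "character",
                        smoothed = "logical", boxId = "character"))

setValidity("VoxelGrid", function(object) {
  d <- dim(object@data)
  if (length(d) != 4) return("data must be a 4D array")
  if (d[1] != length(object@channels)) return("channel count mismatch")
  TRUE
})

#' NormalizationStats: per-position channel means of a training set
#'
#' @slot mean Numeric array with the same dim as one voxel grid (or a
#'   length-d vector for descriptor data).
#' @slot scale Single positive number every value is divided by after mean
#'   subtraction (1 = plain zero-mean normalization).
#' @slot n Number of training examples averaged.
#' @export
setClass("NormalizationStats",
         representation(mean = "array", scale = "numeric", n = "integer"),
         prototype(scale = 1))

#' LabeledVoxelSet: examples with class labels and a split tag
#'
#' Container for a labeled dataset.  Features are stored as a flat
#' `N x prod(featureDim)` matrix so voxel tensors (featureDim =
#' c(4, 20, 20, 20)) and descriptor vectors (featureDim = 480) share one
#' representation.
#'
#' @slot features Numeric matrix, one example per row.
#' @slot featureDim Integer vector; original dim of one example.
#' @slot labels Factor of class labels.
#' @slot split Character: "train", "val" or "test".
#' @export
setClass("LabeledVoxelSet",
         representation(features = "matrix", featureDim = "integer",
                        labels = "factor", split = "character"))

setValidity("LabeledVoxelSet", function(object) {
  if (nrow(object@features) != length(object@labels))
    return("features and labels disagree in length")
  if (prod(object@featureDim) != ncol(object@features))
    return("featureDim inconsistent with feature matrix")
  if (!object@split %in% c("train", "val", "test"))
    return("split must be train, val or test")
  TRUE
})

#' ConfusionMatrix: raw prediction counts and their normalizations
#'
#' `counts[i, j]` is the number of evaluated examples with true class i
#' predicted as class j.  Row and column stochastic normalizations are
#' available through [rowNormalized()] and [colNormalized()]; all-zero rows
#' or columns are left at zero and flagged.
#'
#' @slot counts Square non-negative integer matrix with class dimnames.
#' @slot classes Character vector of class names.
#' @export
setClass("ConfusionMatrix",
         representation(counts = "matrix", classes = "character"))

setValidity("ConfusionMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("counts must be square")
  if (any(m < 0)) return("counts must be non-negative")
  if (nrow(m) != length(object@classes)) return("class name length mismatch")
  TRUE
})

#' SubstitutionScores: a 20x20 (or kxk) amino-acid score matrix
#'
#' @slot matrix Square numeric matrix with class dimnames.
#' @slot kind One of "freq", "dot", "external".
#' @slot metadata List of derivation details (log base, flooring, source).
#' @export
setClass("SubstitutionScores",
         representation(matrix = "matrix", kind = "character",
                        metadata = "list"))

setValidity("SubstitutionScores", function(object) {
  if (nrow(object@matrix) != ncol(object@matrix)) return("matrix must be square")
  if (!object@kind %in% c("freq", "dot", "external"))
    return("kind must be freq, dot or external")
  if (object@kind %in% c("freq", "dot") &&
      max(abs(object@matrix - t(object@matrix))) > 1e-9)
    return("derived score matrices must be symmetric")
  TRUE
})

#' VoxelNet: a feed-forward 3D convolutional classifier
#'
#' Layers are held as a list of parameterized layer descriptions (conv, pool,
#' flatten, dense, softmax head).  Training state (best weights, history) is
#' attached by [trainNetwork()].
#'
#' @slot layers List of layer objects with weights.
#' @slot inputShape Integer vector, e.g. c(4, 20, 20, 20) or 480.
#' @slot nClasses Integer number of output classes.
#' @slot dropout Dropout rate applied after conv/dense activations.
#' @slot classNames Character labels for the softmax outputs.
#' @export
setClass("VoxelNet",
         representation(layers = "list", inputShape = "integer",
                        nClasses = "integer", dropout = "numeric",
                        classNames = "character"))

#' ImportanceMap: gradient-times-input atom attribution for one example
#'
#' @slot raw Gradient-times-input scores, same dim as the input tensor.
#' @slot normalized Absolute scores min-max scaled to `[0, 100]`.
#' @slot trueClass Integer (1-based) class index the gradient was taken for.
#' @export
setClass("ImportanceMap",
         representation(raw = "array", normalized = "array",
                        trueClass = "integer"))

setValidity("ImportanceMap", function(object) {
  n <- object@normalized
  if (min(n) < 0 || max(n) > 100) return("normalized scores outside [0, 100]")
  if (any(abs(n) > 0) && abs(max(n) - 100) > 1e-9)
    return("nonzero normalized maps must attain 100")
  TRUE
})
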