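#' @import methods
NULL

BASES <- c("A", "C", "G", "T")

## Biostrings-compatible ordering of the 64 trinucleotides (AAA, AAC, ...).
TRIPLETS <- as.vector(t(outer(
  as.vector(t(outer(BASES, BASES, paste0))), BASES, paste0)))

DISTANCE_MEASURES <- c("HI", "MD", "BD", "JS", "TAU")

#' TrinucleotideModel: second-order Markov model of a DNA corpus
#'
#' Holds the pooled trinucleotide counts \eqn{N_{xyz}} of a set of DNA
#' sequences, the conditional probabilities
#' \eqn{P(z|xy) = N_{xyz} / \sum_s N_{xys}}, and the self-information
#' weighting factors \eqn{w = -\log_2 P(z|xy)} in bits.  Probabilities and
#' weights are \code{NA} for contexts \eqn{xy} never observed in the corpus
#' (and weights additionally for zero-probability triplets); consumers fall
#' back to weight 1 for such positions.
#'
#' @slot counts integer vector of length 64, named by triplet.
#' @slot probabilities numeric vector of length 64; \code{NA} where the
#'   doublet context was never observed.
#' @slot weights numeric vector of length 64, in bits; \code{NA} where the
#'   probability is \code{NA} or zero.
#'
#' @seealso [buildTrinucleotideModel()], [sequenceWeights()]
#' @export
setClass("TrinucleotideModel",
  representation(
    counts = "integer",
    probabilities = "numeric",
    weights = "numeric"
  )
)

setValidity("TrinucleotideModel", function(object) {
  msg <- character()
  for (sl in c("counts", "probabilities", "weights")) {
    v <- slot(object, sl)
    if (length(v) != 64L || !identical(names(v), TRIPLETS))
      msg <- c(msg, sprintf("'%s' must be length 64, named by triplet", sl))
  }
  if (length(msg)) return(msg)
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  p <- object@probabilities
  if (any(!is.na(p) & (p < 0 | p > 1)))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  ## per-context distribution must sum to 1 where defined
  ctx <- substr(TRIPLETS, 1L, 2L)
  for (cx in unique(ctx)) {
    pc <- p[ctx == cx]
    if (all(!is.na(pc)) && abs(sum(pc) - 1) > 1e-9)
      msg <- c(msg, sprintf("P(.|%s) does not sum to 1", cx))
  }
  w <- object@weights
  if (any(!is.na(w) & w < 0))
    msg <- c(msg, "weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' AssignmentScheme: base-to-vector assignment on the xy-plane
#'
#' Maps each of A, C, G, T to one of the four diagonal unit-square vectors
#' (1,1), (-1,1), (-1,-1), (1,-1).  The label records the counterclockwise
#' order of the bases starting from the (1,1) quadrant.
#'
#' @slot label character scalar, one of \code{"ATGC"}, \code{"ATCG"},
#'   \code{"AGTC"}.
#' @slot vectors 4 x 2 numeric matrix with rownames A, C, G, T; each row one
#'   of the four diagonal vectors, each vector used exactly once.
#'
#' @seealso [assignmentVectors()]
#' @export
setClass("AssignmentScheme",
  representation(label = "character", vectors = "matrix")
)

setValidity("AssignmentScheme", function(object) {
  v <- object@vectors
  if (!is.numeric(v) || !identical(dim(v), c(4L, 2L)) ||
      !setequal(rownames(v), BASES))
    return("'vectors' must be a 4 x 2 matrix with rownames A, C, G, T")
  if (!all(abs(v) == 1))
    return("all vectors must be diagonal: components in {-1, +1}")
  key <- paste(v[, 1], v[, 2])
  if (anyDuplicated(key))
    return("each diagonal vector must be used exactly once")
  TRUE
})

#' Trajectory: cumulative 2D graph of a DNA sequence
#'
#' The points \eqn{R_0 = (0,0), R_1, \ldots, R_L} with
#' \eqn{R_i = R_{i-1} + w_i V(s_i)}, where \eqn{V(s_i)} is the vector
#' assigned to base \eqn{s_i} and \eqn{w_i} its weighting factor.
#'
#' @slot points (L+1) x 2 numeric matrix of coordinates, first row (0, 0).
#' @slot id character scalar identifying the source sequence.
#'
#' @seealso [buildTrajectory()]
#' @export
setClass("Trajectory",
  representation(points = "matrix", id = "character")
)

setValidity("Trajectory", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 1L)
    return("'points' must be a numeric matrix with 2 columns and >= 1 row")
  if (any(p[1L, ] != 0))
    return("trajectory must start at the origin")
  TRUE
})

#' BinaryImage: rasterized trajectory with a marked-block index
#'
#' The set of black pixels of a binary image together with the block index
#' used to restrict pattern counting: the pixel grid is divided into
#' \code{blockSize} x \code{blockSize} squares and a block is marked iff it
#' contains at least one black pixel.  Pixel (i, j) covers the closed square
#' [i, i+1] x [j, j+1] in trajectory units divided by \code{pixelSize};
#' the y axis points up and negative indices are allowed.
#'
#' @slot black n x 2 numeric matrix of integer-valued pixel coordinates
#'   (x, y), unique rows.
#' @slot blocks m x 2 numeric matrix of marked block coordinates
#'   \code{floor(pixel / blockSize)}.
#' @slot blockSize integer scalar, side of the block grid (default 10).
#' @slot pixelSize numeric scalar, side of one pixel in trajectory units.
#'
#' @seealso [rasterize()], [markBlocks()], [countPatterns()]
#' @export
setClass("BinaryImage",
  representation(
    black = "matrix",
    blocks = "matrix",
    blockSize = "integer",
    pixelSize = "numeric"
  )
)

setValidity("BinaryImage", function(object) {
  b <- object@black
  if (ncol(b) != 2L)
    return("'black' must have 2 columns")
  if (nrow(b) && any(b != round(b)))
    return("pixel coordinates must be integers")
  if (length(object@blockSize) != 1L || object@blockSize < 1L)
    return("'blockSize' must be a positive integer")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("'pixelSize' must be positive")
  want <- unique(floor(b / object@blockSize))
  have <- object@blocks
  if (nrow(want) != nrow(have) ||
      !setequal(paste(want[, 1], want[, 2]), paste(have[, 1], have[, 2])))
    return("'blocks' must be exactly the blocks containing black pixels")
  TRUE
})

#' PatternHistogram: occurrence counts of 3x3 local bitmap patterns
#'
#' Counts of the 511 non-empty 3 x 3 local patterns (serial numbers 1..511;
#' serial 0, the all-white window, is excluded as image background) obtained
#' by sliding a 3 x 3 window one pixel at a time over a binary image.
#' \code{frequencies} is empty until [normalizeHistogram()] is called, after
#' which it holds \eqn{p_i = n_i / \sum n_i}.
#'
#' @slot counts integer vector of length 511; element i is the count of
#'   serial number i.
#' @slot frequencies numeric vector of length 0 (raw) or 511 (normalized).
#' @slot window integer scalar window side, fixed at 3.
#'
#' @seealso [countPatterns()], [serialNumber()]
#' @export
setClass("PatternHistogram",
  representation(
    counts = "integer",
    frequencies = "numeric",
    window = "integer"
  )
)

setValidity("PatternHistogram", function(object) {
  n <- 2L^(object@window^2) - 1L
  if (length(object@counts) != n)
    return(sprintf("'counts' must have length %d", n))
  if (any(object@counts < 0L))
    return("counts must be non-negative")
  f <- object@frequencies
  if (length(f) && (length(f) != n || abs(sum(f) - 1) > 1e-8))
    return("'frequencies' must be empty or length 511 summing to 1")
  TRUE
})

#' DistanceMatrix: pairwise histogram distances between sequences
#'
#' A symmetric matrix of non-negative distances with zero diagonal, labelled
#' by sequence id, under one of the five supported measures: HI (one minus
#' histogram intersection), MD (Manhattan / L1), BD (Bhattacharyya), JS
#' (Jensen-Shannon divergence, base-2 logs), TAU (Kendall rank-correlation
#' distance).
#'
#' @slot values symmetric numeric matrix with matching dimnames.
#' @slot measure character scalar, one of HI, MD, BD, JS, TAU.
#'
#' @seealso [distanceMatrix()], [upgma()]
#' @export
setClass("DistanceMatrix",
  representation(values = "matrix", measure = "character")
)

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v))
    return("'values' must be a square numeric matrix")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("'values' must carry identical row and column labels")
  if (anyDuplicated(rownames(v)))
    return("labels must be unique")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12)))
    return("matrix must be symmetric")
  if (any(diag(v) != 0))
    return("diagonal must be zero")
  if (any(v < 0))
    return("distances must be non-negative")
  if (!(object@measure %in% DISTANCE_MEASURES))
    return(sprintf("measure must be one of %s",
                   paste(DISTANCE_MEASURES, collapse = ", ")))
  TRUE
})
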