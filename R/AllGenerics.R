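#' Accessors for lphist S4 containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an lphist S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelCounts", function(object) standardGeneric("modelCounts"))

#' @rdname accessors
#' @export
setGeneric("modelProbabilities",
           function(object) standardGeneric("modelProbabilities"))

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(object) standardGeneric("modelWeights"))

#' @rdname accessors
#' @export
setGeneric("trajectoryPoints",
           function(object) standardGeneric("trajectoryPoints"))

#' @rdname accessors
#' @export
setGeneric("blackPixels", function(object) standardGeneric("blackPixels"))

#' @rdname accessors
#' @export
setGeneric("markedBlocks", function(object) standardGeneric("markedBlocks"))

#' @rdname accessors
#' @export
setGeneric("blockSize", function(object) standardGeneric("blockSize"))

#' @rdname accessors
#' @export
setGeneric("patternCounts", function(object) standardGeneric("patternCounts"))

#' @rdname accessors
#' @export
setGeneric("patternFrequencies",
           function(object) standardGeneric("patternFrequencies"))

#' @rdname accessors
#' @export
setGeneric("distanceMeasure",
           function(object) standardGeneric("distanceMeasure"))

setMethod("modelCounts", "TrinucleotideModel", function(object) object@counts)
setMethod("modelProbabilities", "TrinucleotideModel",
          function(object) object@probabilities)
setMethod("modelWeights", "TrinucleotideModel", function(object) object@weights)

setMethod("trajectoryPoints", "Trajectory", function(object) object@points)

setMethod("blackPixels", "BinaryImage", function(object) object@black)
setMethod("markedBlocks", "BinaryImage", function(object) object@blocks)
setMethod("blockSize", "BinaryImage", function(object) object@blockSize)

setMethod("patternCounts", "PatternHistogram", function(object) object@counts)
setMethod("patternFrequencies", "PatternHistogram",
          function(object) object@frequencies)

setMethod("distanceMeasure", "DistanceMatrix", function(object) object@measure)

#' @describeIn accessors distance matrix as a plain labelled matrix.
#' @param x a \code{DistanceMatrix}.
#' @param ... unused.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

#' @describeIn accessors sequence labels of a distance matrix.
#' @export
setMethod("labels", "DistanceMatrix", function(object, ...) rownames(object@values))

## ---- show methods ----------------------------------------------------------

setMethod("show", "TrinucleotideModel", function(object) {
  n <- sum(object@counts)
  cat("TrinucleotideModel: second-order Markov model\n")
  cat(sprintf("  %d triplet windows counted; %d/64 triplets observed\n",
              n, sum(object@counts > 0L)))
  w <- object@weights
  if (any(!is.na(w)))
    cat(sprintf("  weights (bits): min %.3g, max %.3g\n",
                min(w, na.rm = TRUE), max(w, na.rm = TRUE)))
})

setMethod("show", "AssignmentScheme", function(object) {
  cat(sprintf("AssignmentScheme \"%s\"\n", object@label))
  v <- object@vectors
  for (b in BASES)
    cat(sprintf("  %s -> (%+d, %+d)\n", b, v[b, 1], v[b, 2]))
})

setMethod("show", "Trajectory", function(object) {
  p <- object@points
  cat(sprintf("Trajectory \"%s\": %d points, terminus (%.4g, %.4g)\n",
              object@id, nrow(p), p[nrow(p), 1], p[nrow(p), 2]))
})

setMethod("show", "BinaryImage", function(object) {
  cat(sprintf(
    "BinaryImage: %d black pixels, %d marked %dx%d blocks (pixel size %g)\n",
    nrow(object@black), nrow(object@blocks), object@blockSize,
    object@blockSize, object@pixelSize))
})

setMethod("show", "PatternHistogram", function(object) {
  cat(sprintf("PatternHistogram (%dx%d): %d windows, %d distinct patterns%s\n",
              object@window, object@window, sum(object@counts),
              sum(object@counts > 0L),
              if (length(object@frequencies)) ", normalized" else ""))
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (%s): %d sequences\n",
              object@measure, nrow(object@values)))
  print(round(object@values, 4))
})
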