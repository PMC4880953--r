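## Base-to-vector assignment schemes and the weighted cumulative trajectory
## R_i = sum_{k<=i} w_k V_k.

#' Base-to-vector assignment schemes
#'
#' The four bases are mapped to the four diagonal unit-square vectors of the
#' xy-plane, which are pairwise perpendicular or opposite.  The label names
#' the counterclockwise order of the bases starting from the (+1, +1)
#' quadrant; the three labels are the three independent assignment classes
#' (see [enumerateAssignmentClasses()]).  \code{"ATGC"} places A and T in
#' the upper quadrants and G and C in the lower ones, so the terminal
#' y-coordinate of an unweighted trajectory reads out AT- vs GC-content.
#'
#' @param label one of \code{"ATGC"} (default), \code{"ATCG"}, \code{"AGTC"}.
#' @return an [AssignmentScheme-class] object.
#' @export
assignmentVectors <- function(label = c("ATGC", "ATCG", "AGTC")) {
  label <- match.arg(label)
  ccw <- matrix(c(1, 1, -1, 1, -1, -1, 1, -1), nrow = 4L, byrow = TRUE)
  order <- strsplit(label, "")[[1L]]
  v <- ccw
  rownames(v) <- order
  colnames(v) <- c("x", "y")
  new("AssignmentScheme", label = label, vectors = v[BASES, , drop = FALSE])
}

## The 24 bijections {A,T,G,C} -> four diagonal vectors, as complex numbers.
.allAssignments <- function() {
  vecs <- c(1 + 1i, -1 + 1i, -1 - 1i, 1 - 1i)
  perms <- list()
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (d in 1:4) {
    p <- c(a, b, cc, d)
    if (!anyDuplicated(p)) perms[[length(perms) + 1L]] <- vecs[p]
  }
  perms
}

#' Count the independent assignment classes
#'
#' Enumerates all 4! = 24 bijections from the bases to the four diagonal
#' vectors and groups them into orbits under the symmetry group of the plane
#' generated by 90-degree rotation and axis reflection (order 8): two
#' assignments related by such a transformation produce congruent
#' trajectories and are equivalent.  There are 24 / 8 = 3 classes.
#'
#' @param detail if \code{TRUE}, return a list with the class count, the
#'   total number of assignments, and the orbit sizes.
#' @return integer class count, or a detail list.
#' @export
enumerateAssignmentClasses <- function(detail = FALSE) {
  assignments <- .allAssignments()
  ## group elements as functions on complex vectors: rotations i^k, and
  ## reflection about the x axis (conjugation) followed by rotations
  group <- list()
  for (k in 0:3) {
    group <- c(group, local({
      r <- 1i^k
      list(function(z) r * z, function(z) r * Conj(z))
    }))
  }
  canon <- vapply(assignments, function(a) {
    images <- vapply(group, function(g) paste(format(g(a)), collapse = "|"),
                     character(1L))
    min(images)
  }, character(1L))
  sizes <- table(canon)
  if (detail)
    list(classes = length(sizes),
         assignments = length(assignments),
         orbitSizes = as.integer(sizes))
  else
    length(sizes)
}

#' Build the weighted trajectory of a sequence
#'
#' Computes the cumulative points \eqn{R_0 = (0,0)},
#' \eqn{R_i = R_{i-1} + w_i V(s_i)}, where \eqn{V} is the scheme's vector
#' for base \eqn{s_i} and \eqn{w_i} the weighting factor (the weight scales
#' both components).  With \code{weights = NULL} all weights are 1.
#'
#' @param seq a single sequence (character scalar, \code{DNAString}, or a
#'   length-one \code{DNAStringSet}); bases must be A, C, G, T.
#' @param scheme an [AssignmentScheme-class]; default \code{"ATGC"}.
#' @param weights \code{NULL} or a numeric vector with one weight per base.
#' @param id trajectory id; defaults to the sequence name when present.
#' @return a [Trajectory-class] with \code{length(seq) + 1} points.
#' @export
buildTrajectory <- function(seq, scheme = assignmentVectors("ATGC"),
                            weights = NULL, id = NULL) {
  if (is.null(id))
    id <- if (!is.null(names(seq)) && length(names(seq))) names(seq)[1L]
          else "sequence"
  s <- .asSequenceString(seq)
  chars <- strsplit(s, "")[[1L]]
  if (length(chars) && !all(chars %in% BASES))
    stop("sequence contains non-ACGT characters; clean it first")
  if (is.null(weights))
    weights <- rep(1, length(chars))
  if (length(weights) != length(chars))
    stop(sprintf("weights length (%d) != sequence length (%d)",
                 length(weights), length(chars)))
  if (!length(chars)) {
    pts <- matrix(0, nrow = 1L, ncol = 2L)
  } else {
    v <- scheme@vectors[chars, , drop = FALSE]
    steps <- v * weights
    pts <- rbind(c(0, 0),
                 cbind(cumsum(steps[, 1L]), cumsum(steps[, 2L])))
  }
  dimnames(pts) <- list(NULL, c("x", "y"))
  new("Trajectory", points = pts, id = id)
}

#' Export a trajectory as TSV of (i, x, y)
#'
#' @param traj a [Trajectory-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectoryTSV <- function(traj, path) {
  p <- trajectoryPoints(traj)
  utils::write.table(
    data.frame(i = seq_len(nrow(p)) - 1L, x = p[, 1L], y = p[, 2L]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
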