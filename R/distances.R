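## The five histogram distance measures, pairwise distance matrices, and
## Pearson correlation between distance matrices.
##
## All measures operate on normalized occurrence-frequency vectors p, q over
## the serial numbers 1..511; serials absent from a histogram have
## frequency 0 (the index range is fixed, so supports are aligned).

## Normalized frequency vector from a PatternHistogram or numeric vector.
.freqVector <- function(h, what = "histogram") {
  if (is(h, "PatternHistogram")) {
    if (!length(h@frequencies))
      stop(what, " is not normalized; call normalizeHistogram() first")
    return(h@frequencies)
  }
  if (!is.numeric(h))
    stop(what, " must be a PatternHistogram or numeric vector")
  if (abs(sum(h) - 1) > 1e-6)
    stop(what, " is not normalized: frequencies must sum to 1")
  h
}

.freqPair <- function(P, Q) {
  p <- .freqVector(P, "P")
  q <- .freqVector(Q, "Q")
  if (length(p) != length(q))
    stop("histograms have different lengths")
  list(p = p, q = q)
}

#' Histogram-intersection distance
#'
#' \eqn{D_{HI}(P, Q) = 1 - \sum_i \min(p_i, q_i)}; 0 when P = Q, 1 for
#' disjoint supports.
#'
#' @param P,Q normalized histograms ([PatternHistogram-class] or numeric
#'   frequency vectors of equal length).
#' @return distance in [0, 1].
#' @export
hiDistance <- function(P, Q) {
  v <- .freqPair(P, Q)
  1 - sum(pmin(v$p, v$q))
}

#' Manhattan (L1, city-block) distance
#'
#' \eqn{D_{MD}(P, Q) = \sum_i |p_i - q_i|}; 0 when P = Q, 2 for disjoint
#' supports.  For normalized histograms \eqn{D_{HI} = D_{MD} / 2} exactly.
#'
#' @inheritParams hiDistance
#' @return distance in [0, 2].
#' @export
mdDistance <- function(P, Q) {
  v <- .freqPair(P, Q)
  sum(abs(v$p - v$q))
}

#' Bhattacharyya distance
#'
#' \eqn{DIV(P, Q) = \sum_i \sqrt{p_i q_i}} (1 when P = Q), converted to the
#' distance \eqn{D_{BD} = -\ln DIV}; \code{Inf} for disjoint supports.
#'
#' @inheritParams hiDistance
#' @return distance in [0, Inf].
#' @export
bdDistance <- function(P, Q) {
  v <- .freqPair(P, Q)
  div <- sum(sqrt(v$p * v$q))
  if (div <= 0)
    return(Inf)
  -log(min(div, 1))
}

#' Jensen-Shannon divergence (base-2 logarithms)
#'
#' \deqn{D_{JS} = \tfrac12 \sum_i p_i \log_2 \frac{2 p_i}{p_i + q_i}
#'              + \tfrac12 \sum_i q_i \log_2 \frac{2 q_i}{p_i + q_i}}
#' Terms with a zero numerator contribute 0 and serials with
#' \eqn{p_i = q_i = 0} are excluded.  Bounded by 1, attained exactly for
#' disjoint supports.
#'
#' @inheritParams hiDistance
#' @return divergence in [0, 1].
#' @export
jsDivergence <- function(P, Q) {
  v <- .freqPair(P, Q)
  m <- v$p + v$q
  half <- function(a) {
    i <- a > 0
    sum(a[i] * log2(2 * a[i] / m[i]))
  }
  max(0, 0.5 * (half(v$p) + half(v$q)))
}

#' Kendall rank-correlation distance
#'
#' Over all serial pairs i > j not doubly tied
#' (\eqn{p_i = p_j} and \eqn{q_i = q_j} simultaneously), let X be the
#' concordant pairs (\eqn{(p_i - p_j)(q_i - q_j) > 0}), Y the discordant
#' pairs, r the pairs tied only in p, and s the pairs tied only in q.  The
#' tau-b estimator \eqn{\tau = (X - Y) / \sqrt{(X + Y + r)(X + Y + s)}} is
#' converted to the distance \eqn{D_\tau = (1 - \tau) / 2}, in [0, 1].
#'
#' @inheritParams hiDistance
#' @return distance in [0, 1].
#' @export
kendallTauDistance <- function(P, Q) {
  v <- .freqPair(P, Q)
  iu <- upper.tri(matrix(0, length(v$p), length(v$p)))
  sp <- sign(outer(v$p, v$p, "-"))[iu]
  sq <- sign(outer(v$q, v$q, "-"))[iu]
  prod <- sp * sq
  X <- sum(prod > 0)
  Y <- sum(prod < 0)
  r <- sum(sp == 0 & sq != 0)
  s <- sum(sp != 0 & sq == 0)
  den1 <- X + Y + r
  den2 <- X + Y + s
  if (den1 == 0 && den2 == 0)
    stop("Kendall tau undefined: all pairs are doubly tied")
  if (den1 == 0 || den2 == 0)
    stop("Kendall tau undefined: one histogram is constant over all serials")
  tau <- (X - Y) / (sqrt(den1) * sqrt(den2))
  (1 - tau) / 2
}

.distanceFun <- function(measure) {
  switch(measure,
         HI = hiDistance, MD = mdDistance, BD = bdDistance,
         JS = jsDivergence, TAU = kendallTauDistance,
         stop("unknown measure: ", measure))
}

#' Distance between two histograms under a named measure
#'
#' @inheritParams hiDistance
#' @param measure one of \code{"HI"}, \code{"MD"}, \code{"BD"}, \code{"JS"},
#'   \code{"TAU"}.
#' @return the scalar distance.
#' @export
histogramDistance <- function(P, Q, measure = c("HI", "MD", "BD", "JS", "TAU")) {
  measure <- match.arg(measure)
  .distanceFun(measure)(P, Q)
}

#' Pairwise distance matrix over labelled histograms
#'
#' @param hists a named list of normalized histograms (>= 2, unique names).
#' @param measure distance measure, as in [histogramDistance()].
#' @return a [DistanceMatrix-class].
#' @export
distanceMatrix <- function(hists, measure = c("HI", "MD", "BD", "JS", "TAU")) {
  measure <- match.arg(measure)
  n <- length(hists)
  if (n < 2L)
    stop("need at least 2 histograms")
  labs <- names(hists)
  if (is.null(labs) || anyDuplicated(labs) || any(!nzchar(labs)))
    stop("histograms must carry unique non-empty names")
  fun <- .distanceFun(measure)
  freqs <- lapply(seq_len(n), function(i) .freqVector(hists[[i]], labs[i]))
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- fun(freqs[[i]], freqs[[j]])
      if (!is.finite(d))
        stop(sprintf("non-finite %s distance between '%s' and '%s'",
                     measure, labs[i], labs[j]))
      m[i, j] <- m[j, i] <- d
    }
  }
  new("DistanceMatrix", values = m, measure = measure)
}

#' Pearson correlation between two distance matrices
#'
#' Correlates the strict upper-triangle entries (the diagonal zeros and the
#' duplicated lower triangle would bias r).
#'
#' @param m1,m2 [DistanceMatrix-class] objects with identical labels in
#'   identical order, >= 3 taxa.
#' @return Pearson's r.
#' @export
matrixCorrelation <- function(m1, m2) {
  a <- as.matrix(m1)
  b <- as.matrix(m2)
  if (!identical(rownames(a), rownames(b)))
    stop("distance matrices must carry the same labels in the same order")
  if (nrow(a) < 3L)
    stop("need at least 3 taxa")
  iu <- upper.tri(a)
  x <- a[iu]
  y <- b[iu]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant distance matrix")
  stats::cor(x, y)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm a [DistanceMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePhylipMatrix <- function(dm, path) {
  m <- as.matrix(dm)
  labs <- rownames(m)
  width <- max(10L, nchar(labs) + 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste0(formatC(labs[i], width = -width),
                      paste(sprintf("%.6f", m[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @inheritParams writePhylipMatrix
#' @export
writeDistanceTSV <- function(dm, path) {
  m <- as.matrix(dm)
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
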