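# Independent oracles and fixture generators used across the suite.

# Exact closed-square / segment intersection (Liang-Barsky with closed
# inequalities): does pixel (i, j), covering [i, i+1] x [j, j+1], touch the
# segment (x0, y0) -> (x1, y1)?
oracleSegmentIntersects <- function(i, j, x0, y0, x1, y1) {
  p0 <- c(x0, y0)
  d <- c(x1 - x0, y1 - y0)
  lo <- c(i, j)
  tmin <- 0
  tmax <- 1
  for (ax in 1:2) {
    if (d[ax] == 0) {
      if (p0[ax] < lo[ax] || p0[ax] > lo[ax] + 1)
        return(FALSE)
    } else {
      t1 <- (lo[ax] - p0[ax]) / d[ax]
      t2 <- (lo[ax] + 1 - p0[ax]) / d[ax]
      if (t1 > t2) {
        tmp <- t1; t1 <- t2; t2 <- tmp
      }
      tmin <- max(tmin, t1)
      tmax <- min(tmax, t2)
    }
  }
  tmin <= tmax + 1e-12
}

# Brute-force supercover: test every pixel of the (padded) bounding box.
oracleSegmentPixels <- function(x0, y0, x1, y1) {
  is <- (floor(min(x0, x1)) - 1L):(floor(max(x0, x1)) + 1L)
  js <- (floor(min(y0, y1)) - 1L):(floor(max(y0, y1)) + 1L)
  out <- list()
  for (i in is) {
    for (j in js) {
      if (oracleSegmentIntersects(i, j, x0, y0, x1, y1))
        out[[length(out) + 1L]] <- c(i, j)
    }
  }
  do.call(rbind, out)
}

pixelKey <- function(m) sort(paste(m[, 1], m[, 2]))

# Brute-force 3x3 pattern counter: full scan of every window position over
# the black-pixel bounding box expanded by 2 pixels on each side.
bruteCountPatterns <- function(image) {
  black <- blackPixels(image)
  if (!nrow(black))
    return(integer(511L))
  xr <- range(black[, 1L])
  yr <- range(black[, 2L])
  W <- xr[2L] - xr[1L] + 5L
  H <- yr[2L] - yr[1L] + 5L
  M <- matrix(0, nrow = H, ncol = W)  # rows indexed by y ascending
  M[cbind(black[, 2L] - yr[1L] + 3L, black[, 1L] - xr[1L] + 3L)] <- 1
  S <- matrix(0, H - 2L, W - 2L)
  for (r in 0:2) {            # window row, 0 = top
    for (cc in 0:2) {
      bit <- 2^(8 - (3 * r + cc))
      S <- S + bit * M[(1:(H - 2L)) + 2L - r, (1:(W - 2L)) + cc]
    }
  }
  tabulate(as.integer(S[S > 0]), nbins = 511L)
}

randomBinaryImage <- function(nPixels = 30L, span = 25L, blockSize = 10L) {
  black <- unique(cbind(sample.int(span, nPixels, replace = TRUE) - 8L,
                        sample.int(span, nPixels, replace = TRUE) - 8L))
  lphist:::.binaryImage(black, blockSize = blockSize)
}

randomHistogram <- function(support = 40L) {
  v <- numeric(511L)
  idx <- sample.int(511L, support)
  v[idx] <- stats::runif(support)
  v / sum(v)
}

# Random ultrametric distance matrix (from a random coalescent tree) plus
# the tree it came from.
randomUltrametric <- function(n) {
  tr <- ape::rcoal(n, tip.label = sprintf("t%02d", seq_len(n)))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
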