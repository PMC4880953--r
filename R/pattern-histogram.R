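## 3x3 local-pattern serial numbering and fast occurrence counting over the
## marked blocks of a binary image.

#' Serial number of a 3x3 local pattern
#'
#' The nine pixels are lined up from the upper-left corner to the
#' lower-right, row by row, and read as a binary number with the upper-left
#' pixel as the highest bit (value 256) and the lower-right as the lowest
#' (value 1).
#'
#' @param window a 3 x 3 matrix of 0/1, row 1 = top row.
#' @return integer in [0, 511].
#' @examples
#' serialNumber(matrix(1, 3, 3))  # 511
#' @export
serialNumber <- function(window) {
  if (!is.matrix(window) || !identical(dim(window), c(3L, 3L)))
    stop("window must be a 3 x 3 matrix")
  if (!all(window %in% c(0, 1)))
    stop("window entries must be 0 or 1")
  bits <- as.vector(t(window))  # row-major, top-left first
  as.integer(sum(bits * 2^(8:0)))
}

.emptyHistogram <- function() {
  new("PatternHistogram", counts = integer(511L),
      frequencies = numeric(0L), window = 3L)
}

## Collision-free integer key for pixel coordinates within a known range.
.coordEncoder <- function(xs, ys) {
  xmin <- min(xs) - 3
  ymin <- min(ys) - 3
  span <- max(ys) - ymin + 7
  function(x, y) (x - xmin) * span + (y - ymin)
}

#' Count 3x3 local patterns of a binary image
#'
#' Counts, for every window position obtained by sliding a 3 x 3 window one
#' pixel per move, the serial number of the enclosed pattern; all-white
#' windows (serial 0, the image background) are excluded.  The counter
#' enumerates only window positions whose 3 x 3 extent intersects a marked
#' block (each block is expanded by a 2-pixel halo and the union is
#' deduplicated), which makes the count identical to a full scan while
#' touching O(marked area) positions.
#'
#' @param image a [BinaryImage-class] with its block index built.
#' @return a raw (unnormalized) [PatternHistogram-class].
#' @export
countPatterns <- function(image) {
  black <- image@black
  if (!nrow(black))
    return(.emptyHistogram())
  B <- as.integer(image@blockSize)
  blk <- image@blocks
  ## candidate window anchors: anchor (i, j) = lower-left pixel of the
  ## window, window extent [i, i+2] x [j, j+2]; it intersects block
  ## (bx, by) iff i in [bx*B - 2, bx*B + B - 1] (same for j)
  d <- 0:(B + 1L)
  nCell <- length(d)^2
  dx <- rep(d, times = length(d))
  dy <- rep(d, each = length(d))
  ax <- rep(blk[, 1L] * B - 2L, each = nCell) + rep(dx, nrow(blk))
  ay <- rep(blk[, 2L] * B - 2L, each = nCell) + rep(dy, nrow(blk))
  enc <- .coordEncoder(c(ax, black[, 1L]), c(ay, black[, 2L]))
  keep <- !duplicated(enc(ax, ay))
  ax <- ax[keep]
  ay <- ay[keep]
  blackKeys <- enc(black[, 1L], black[, 2L])
  serial <- integer(length(ax))
  for (r in 0:2) {
    for (cc in 0:2) {
      ## window row r (0 = top) column cc maps to pixel (i+cc, j+2-r)
      bit <- 2L^(8L - (3L * r + cc))
      hit <- enc(ax + cc, ay + 2L - r) %in% blackKeys
      serial <- serial + bit * hit
    }
  }
  serial <- serial[serial > 0L]
  new("PatternHistogram", counts = tabulate(serial, nbins = 511L),
      frequencies = numeric(0L), window = 3L)
}

#' Normalize a pattern histogram
#'
#' Sets \eqn{p_i = n_i / \sum_i n_i} so the frequencies sum to 1.
#' Idempotent; errors on an empty histogram.
#'
#' @param hist a [PatternHistogram-class].
#' @return the histogram with its \code{frequencies} slot filled.
#' @export
normalizeHistogram <- function(hist) {
  total <- sum(hist@counts)
  if (total == 0L)
    stop("cannot normalize empty histogram")
  hist@frequencies <- hist@counts / total
  hist
}

#' Total number of counted windows
#'
#' @param hist a [PatternHistogram-class].
#' @return integer: the number of window positions containing at least one
#'   black pixel.
#' @export
totalWindows <- function(hist) {
  sum(hist@counts)
}

#' Histogram export/import as TSV
#'
#' Columns \code{serial}, \code{count}, \code{frequency} (NA when the
#' histogram is unnormalized), serials ascending; only non-zero serials are
#' written.
#'
#' @param hist a [PatternHistogram-class].
#' @param path TSV path.
#' @return \code{path} (write) / a [PatternHistogram-class] (read).
#' @export
writeHistogram <- function(hist, path) {
  nz <- which(hist@counts > 0L)
  freq <- if (length(hist@frequencies)) hist@frequencies[nz] else NA_real_
  utils::write.table(
    data.frame(serial = nz, count = hist@counts[nz], frequency = freq),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHistogram
#' @export
readHistogram <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("serial", "count") %in% names(df)))
    stop("not a histogram TSV: ", path)
  if (any(df$serial < 1L | df$serial > 511L))
    stop("serial numbers must lie in 1..511")
  counts <- integer(511L)
  counts[df$serial] <- as.integer(df$count)
  h <- new("PatternHistogram", counts = counts,
           frequencies = numeric(0L), window = 3L)
  if ("frequency" %in% names(df) && !anyNA(df$frequency))
    h <- normalizeHistogram(h)
  h
}
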