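## Rasterization of a trajectory into a binary image.  Pixel (i, j) covers
## the CLOSED square [i, i+1] x [j, j+1] (in trajectory units / pixelSize)
## and is black iff the square intersects at least one trajectory segment.
## Closed membership means a segment passing exactly through a lattice
## corner marks all four adjacent pixels (no gaps at corner crossings).

.SNAP <- 1e-9  # coordinates this close to an integer are treated as exact

## Pixels whose closed unit square contains the point (x, y).
.pixelsAtPoint <- function(x, y) {
  colsOf <- function(v) {
    r <- round(v)
    if (abs(v - r) < .SNAP) c(r - 1, r) else floor(v)
  }
  ix <- colsOf(x)
  iy <- colsOf(y)
  cbind(rep(ix, times = length(iy)), rep(iy, each = length(ix)))
}

## Supercover pixel set of one segment by parametric grid walking: collect
## the parameters where the segment crosses an integer x or y line, take
## the (closed) pixel sets at every crossing point and the single interior
## pixel between consecutive crossings.
.segmentPixels <- function(x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  ts <- c(0, 1)
  if (abs(dx) > 0) {
    ks <- seq(ceiling(min(x0, x1) - .SNAP), floor(max(x0, x1) + .SNAP))
    if (length(ks))
      ts <- c(ts, (ks - x0) / dx)
  }
  if (abs(dy) > 0) {
    ks <- seq(ceiling(min(y0, y1) - .SNAP), floor(max(y0, y1) + .SNAP))
    if (length(ks))
      ts <- c(ts, (ks - y0) / dy)
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  if (length(ts) > 1L)
    ts <- ts[c(TRUE, diff(ts) > 1e-12)]
  pieces <- vector("list", 2L * length(ts))
  n <- 0L
  for (idx in seq_along(ts)) {
    t <- ts[idx]
    n <- n + 1L
    pieces[[n]] <- .pixelsAtPoint(x0 + t * dx, y0 + t * dy)
    if (idx < length(ts)) {
      tm <- (t + ts[idx + 1L]) / 2
      n <- n + 1L
      pieces[[n]] <- .pixelsAtPoint(x0 + tm * dx, y0 + tm * dy)
    }
  }
  unique(do.call(rbind, pieces[seq_len(n)]))
}

## Internal constructor: builds the block index from the black set.
.binaryImage <- function(black, blockSize = 10L, pixelSize = 1) {
  black <- unique(black)
  if (!nrow(black))
    stop("binary image has no black pixels")
  dimnames(black) <- list(NULL, c("x", "y"))
  blocks <- unique(floor(black / blockSize))
  dimnames(blocks) <- list(NULL, c("bx", "by"))
  new("BinaryImage", black = black, blocks = blocks,
      blockSize = as.integer(blockSize), pixelSize = pixelSize)
}

#' Rasterize a trajectory into a binary image
#'
#' Marks black every pixel whose closed square intersects at least a portion
#' of a trajectory segment (supercover rasterization); a degenerate
#' one-point trajectory marks the pixel(s) containing the point.  The block
#' index ([markBlocks()]) is built during generation at \code{blockSize}.
#'
#' @param traj a [Trajectory-class].
#' @param pixelSize side of a pixel in trajectory units (> 0, default 1, so
#'   an unweighted step spans exactly one pixel diagonal).
#' @param blockSize side of the block grid in pixels (default 10).
#' @return a [BinaryImage-class].
#' @export
rasterize <- function(traj, pixelSize = 1, blockSize = 10L) {
  if (pixelSize <= 0)
    stop("pixelSize must be positive")
  pts <- trajectoryPoints(traj) / pixelSize
  if (nrow(pts) == 1L) {
    black <- .pixelsAtPoint(pts[1L, 1L], pts[1L, 2L])
  } else {
    segs <- vector("list", nrow(pts) - 1L)
    for (k in seq_len(nrow(pts) - 1L))
      segs[[k]] <- .segmentPixels(pts[k, 1L], pts[k, 2L],
                                  pts[k + 1L, 1L], pts[k + 1L, 2L])
    black <- unique(do.call(rbind, segs))
  }
  .binaryImage(black, blockSize = blockSize, pixelSize = pixelSize)
}

#' Marked blocks of a binary image
#'
#' Divides the pixel grid into \code{blockSize} x \code{blockSize} squares;
#' block (bi, bj) is marked iff some black pixel (i, j) satisfies
#' \code{floor(i / blockSize) == bi} and \code{floor(j / blockSize) == bj}.
#' Pattern counting is restricted to marked blocks (plus a halo), which
#' keeps it linear in sequence length.
#'
#' @param image a [BinaryImage-class].
#' @param blockSize block side; defaults to the image's own.
#' @return m x 2 matrix of marked block coordinates.
#' @export
markBlocks <- function(image, blockSize = NULL) {
  if (is.null(blockSize))
    return(image@blocks)
  blocks <- unique(floor(image@black / blockSize))
  dimnames(blocks) <- list(NULL, c("bx", "by"))
  blocks
}

#' Width and height of the aggregate marked region
#'
#' Extents, in pixels, of the bounding box of the marked blocks.
#'
#' @param image a [BinaryImage-class].
#' @return named numeric vector \code{c(width, height)}.
#' @export
imageExtents <- function(image) {
  b <- image@blocks
  s <- image@blockSize
  c(width = (max(b[, 1L]) - min(b[, 1L]) + 1) * s,
    height = (max(b[, 2L]) - min(b[, 2L]) + 1) * s)
}

## ---- image I/O -------------------------------------------------------------

## Dense 0/1 raster over the black-pixel bounding box, row 1 = top (max y).
.rasterMatrix <- function(image) {
  b <- image@black
  xr <- range(b[, 1L])
  yr <- range(b[, 2L])
  w <- xr[2L] - xr[1L] + 1L
  h <- yr[2L] - yr[1L] + 1L
  m <- matrix(0L, nrow = h, ncol = w)
  m[cbind(yr[2L] - b[, 2L] + 1L, b[, 1L] - xr[1L] + 1L)] <- 1L
  attr(m, "offset") <- c(xr[1L], yr[1L])
  m
}

#' Write a binary image as plain PBM (P1)
#'
#' Bit-exact export: 1 = black, 0 = white.  Row 0 of the raster is the top
#' of the image, i.e. the largest y in trajectory space (y points up).  The
#' pixel-coordinate offset of the lower-left corner is recorded in a header
#' comment so that [readPBM()] restores the exact black set.
#'
#' @param image a non-empty [BinaryImage-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePBM <- function(image, path) {
  if (!nrow(image@black))
    stop("empty image")
  m <- .rasterMatrix(image)
  off <- attr(m, "offset")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1",
               sprintf("# offset %d %d", off[1L], off[2L]),
               sprintf("%d %d", ncol(m), nrow(m))), con)
  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    ## plain PBM lines should stay short; chunk at 60 samples
    for (start in seq(1L, length(row), by = 60L))
      writeLines(paste(row[start:min(start + 59L, length(row))],
                       collapse = " "), con)
  }
  invisible(path)
}

#' Read a plain PBM (P1) file written by [writePBM()]
#'
#' @param path PBM path.
#' @return a [BinaryImage-class] (block index rebuilt at the default size).
#' @export
readPBM <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1L]) != "P1")
    stop("not a plain PBM (P1) file: ", path)
  off <- c(0L, 0L)
  body <- lines[-1L]
  comments <- grep("^#", body)
  for (cm in comments) {
    toks <- strsplit(trimws(body[cm]), "\\s+")[[1L]]
    if (length(toks) >= 4L && toks[2L] == "offset")
      off <- as.integer(toks[3:4])
  }
  if (length(comments))
    body <- body[-comments]
  toks <- as.integer(unlist(strsplit(trimws(body[nzchar(trimws(body))]),
                                     "\\s+")))
  w <- toks[1L]
  h <- toks[2L]
  bits <- toks[-(1:2)]
  if (length(bits) != w * h)
    stop("PBM payload size mismatch")
  m <- matrix(bits, nrow = h, ncol = w, byrow = TRUE)
  idx <- which(m == 1L, arr.ind = TRUE)
  black <- cbind(x = idx[, 2L] - 1L + off[1L],
                 y = (h - idx[, 1L]) + off[2L])
  .binaryImage(black, blockSize = 10L, pixelSize = 1)
}

#' Write a binary image as PNG
#'
#' Black pixels on a white background; same raster orientation as
#' [writePBM()].
#'
#' @param image a non-empty [BinaryImage-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeImagePNG <- function(image, path) {
  if (!nrow(image@black))
    stop("empty image")
  m <- .rasterMatrix(image)
  png::writePNG(1 - m, target = path)
  invisible(path)
}
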