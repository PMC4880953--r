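trajFromPoints <- function(pts) new("Trajectory", points = pts, id = "t")

test_that("rasterization marks every pixel a segment touches", {
  # horizontal segment through three pixels
  img <- rasterize(trajFromPoints(rbind(c(0, 0), c(0.5, 0.5), c(2.5, 0.5))))
  # first segment (0,0)->(0.5,0.5) passes the lattice corner (0,0):
  # its four adjacent pixels are all touched
  expect_true(all(c("0 0", "1 0", "2 0") %in% pixelKey(blackPixels(img))))

  # diagonal through an exact lattice corner marks all four adjacent pixels
  img2 <- rasterize(trajFromPoints(rbind(c(0, 0), c(0.5, 0.5), c(1.5, 1.5))))
  expect_true(all(c("0 0", "0 1", "1 0", "1 1") %in%
                  pixelKey(blackPixels(img2))))
  expect_identical(pixelKey(lphist:::.segmentPixels(0.5, 0.5, 1.5, 1.5)),
                   sort(c("0 0", "0 1", "1 0", "1 1")))

  # degenerate one-point trajectory marks the pixel containing the point
  expect_identical(pixelKey(lphist:::.pixelsAtPoint(0.2, 0.3)), "0 0")
  img3 <- rasterize(buildTrajectory(""))   # single point at a lattice corner
  expect_identical(pixelKey(blackPixels(img3)),
                   sort(c("-1 -1", "-1 0", "0 -1", "0 0")))

  expect_error(rasterize(trajFromPoints(matrix(0, 1, 2)), pixelSize = 0),
               "positive")
})

test_that("rasterizer agrees with the geometric intersection oracle", {
  set.seed(301)
  for (k in 1:300) {
    p <- stats::runif(4, min = -4, max = 4)
    got <- lphist:::.segmentPixels(p[1], p[2], p[3], p[4])
    want <- oracleSegmentPixels(p[1], p[2], p[3], p[4])
    expect_identical(pixelKey(got), pixelKey(want))
  }
  # segments with exact integer endpoints (lattice corner contacts)
  for (k in 1:100) {
    p <- sample(-3:3, 4, replace = TRUE)
    got <- lphist:::.segmentPixels(p[1], p[2], p[3], p[4])
    want <- oracleSegmentPixels(p[1], p[2], p[3], p[4])
    expect_identical(pixelKey(got), pixelKey(want))
  }
})

test_that("segment pixel sets are connected and contain both endpoints", {
  set.seed(302)
  for (k in 1:50) {
    p <- stats::runif(4, min = -5, max = 5)
    pix <- lphist:::.segmentPixels(p[1], p[2], p[3], p[4])
    expect_true(all(pixelKey(lphist:::.pixelsAtPoint(p[1], p[2])) %in%
                    pixelKey(pix)))
    expect_true(all(pixelKey(lphist:::.pixelsAtPoint(p[3], p[4])) %in%
                    pixelKey(pix)))
    # connectivity under 8-adjacency
    n <- nrow(pix)
    seen <- rep(FALSE, n)
    queue <- 1L
    seen[1L] <- TRUE
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      adj <- which(!seen &
                   abs(pix[, 1] - pix[cur, 1]) <= 1 &
                   abs(pix[, 2] - pix[cur, 2]) <= 1)
      seen[adj] <- TRUE
      queue <- c(queue, adj)
    }
    expect_true(all(seen))
  }
})

test_that("rasterization is monotone under adding segments", {
  s <- as.character(generateRandomSequence(60L, seed = 8))[[1L]]
  full <- rasterize(buildTrajectory(s))
  half <- rasterize(buildTrajectory(substr(s, 1L, 30L)))
  expect_true(all(pixelKey(blackPixels(half)) %in%
                  pixelKey(blackPixels(full))))
})

test_that("blocks are marked exactly where black pixels fall", {
  img <- lphist:::.binaryImage(rbind(c(3, 4)), blockSize = 10L)
  expect_identical(pixelKey(markedBlocks(img)), "0 0")
  img2 <- lphist:::.binaryImage(rbind(c(3, 4), c(15, 4)), blockSize = 10L)
  expect_identical(pixelKey(markedBlocks(img2)), sort(c("0 0", "1 0")))
  # negative coordinates land in negative blocks
  img3 <- lphist:::.binaryImage(rbind(c(-1, -11)), blockSize = 10L)
  expect_identical(pixelKey(markedBlocks(img3)), "-1 -2")

  # every black pixel lies inside some marked block (validity + property)
  set.seed(303)
  img4 <- randomBinaryImage(40L)
  blk <- floor(blackPixels(img4) / blockSize(img4))
  expect_true(all(pixelKey(blk) %in% pixelKey(markedBlocks(img4))))

  w <- imageExtents(img2)
  expect_equal(unname(w), c(20, 10))
})

test_that("PBM export is bit-exact and round-trips the black set", {
  set.seed(304)
  img <- randomBinaryImage(25L)
  f <- tempfile(fileext = ".pbm")
  writePBM(img, f)
  lines <- readLines(f)
  expect_identical(lines[1L], "P1")
  payload <- paste(lines[-(1:3)], collapse = " ")
  ones <- sum(strsplit(payload, "\\s+")[[1L]] == "1")
  expect_equal(ones, nrow(blackPixels(img)))

  back <- readPBM(f)
  expect_identical(pixelKey(blackPixels(back)), pixelKey(blackPixels(img)))

  one <- lphist:::.binaryImage(rbind(c(0, 0)))
  f2 <- tempfile(fileext = ".pbm")
  writePBM(one, f2)
  expect_identical(pixelKey(blackPixels(readPBM(f2))), "0 0")

  expect_error(lphist:::.binaryImage(matrix(numeric(0), 0L, 2L)),
               "no black pixels")
})

test_that("PNG export writes a raster with the right dimensions", {
  set.seed(305)
  img <- randomBinaryImage(15L)
  f <- tempfile(fileext = ".png")
  writeImagePNG(img, f)
  m <- png::readPNG(f)
  b <- blackPixels(img)
  expect_equal(dim(m), c(diff(range(b[, 2])) + 1L, diff(range(b[, 1])) + 1L))
  expect_equal(sum(m == 0), nrow(b))
})
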