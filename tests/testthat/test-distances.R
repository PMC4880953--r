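pad511 <- function(x) {
  v <- numeric(511L)
  v[seq_along(x)] <- x
  v
}

test_that("histogram intersection distance", {
  p <- pad511(c(0.5, 0.5, 0))
  q <- pad511(c(0.5, 0, 0.5))
  expect_equal(hiDistance(p, p), 0)
  expect_equal(hiDistance(p, q), 0.5)
  expect_equal(hiDistance(pad511(c(1, 0)), pad511(c(0, 1))), 1)
  expect_error(hiDistance(pad511(c(0.5, 0.4)), p), "not normalized")
})

test_that("Manhattan distance", {
  p <- pad511(c(0.5, 0.5, 0))
  q <- pad511(c(0.5, 0, 0.5))
  expect_equal(mdDistance(p, p), 0)
  expect_equal(mdDistance(p, q), 1.0)
  expect_equal(mdDistance(pad511(c(1, 0)), pad511(c(0, 1))), 2)
})

test_that("Bhattacharyya distance", {
  p <- pad511(c(1, 0))
  q <- pad511(c(0.5, 0.5))
  expect_equal(bdDistance(p, p), 0)
  expect_equal(bdDistance(p, q), -log(sqrt(0.5)))
  expect_identical(bdDistance(p, pad511(c(0, 1))), Inf)
})

test_that("Jensen-Shannon divergence", {
  p <- pad511(c(1, 0))
  q <- pad511(c(0.5, 0.5))
  expect_equal(jsDivergence(p, p), 0)
  expect_equal(jsDivergence(p, q),
               0.5 * (1 * log2(2 * 1 / 1.5)) +
               0.5 * (0.5 * log2(2 * 0.5 / 1.5) + 0.5 * log2(2 * 0.5 / 0.5)))
  expect_equal(jsDivergence(p, pad511(c(0, 1))), 1)
})

test_that("Kendall rank-correlation distance with tie corrections", {
  p <- pad511(c(0.1, 0.2, 0.3, 0.4))
  q <- pad511(c(0.1, 0.3, 0.2, 0.4))
  # brute-force over the 4 informative serials: X=5, Y=1, r=s=0 among them;
  # the 507 shared zeros are doubly tied with each other but each pairs
  # against the 4 non-zero serials concordantly
  # independent oracle: tau-b from stats::cor
  tauB <- stats::cor(p, q, method = "kendall")
  expect_equal(kendallTauDistance(p, q), (1 - tauB) / 2)

  # no ties, identical ranks -> distance 0; reversed ranks -> 1
  a <- (1:20) / sum(1:20)
  expect_equal(kendallTauDistance(a, a), 0)
  expect_equal(kendallTauDistance(a, rev(a)), 1)

  uniform <- rep(1 / 511, 511L)
  expect_error(kendallTauDistance(uniform, uniform), "doubly tied")
  set.seed(500)
  expect_error(kendallTauDistance(uniform, randomHistogram()), "constant")
})

test_that("tau-b agrees with stats::cor on random tied histograms", {
  set.seed(501)
  for (k in 1:20) {
    # small integer counts force plenty of ties
    cp <- sample(0:4, 30L, replace = TRUE)
    cq <- sample(0:4, 30L, replace = TRUE)
    if (sum(cp) == 0 || sum(cq) == 0) next
    p <- cp / sum(cp)
    q <- cq / sum(cq)
    skipDegenerate <- (stats::sd(p) == 0 || stats::sd(q) == 0)
    if (skipDegenerate) next
    expect_equal(kendallTauDistance(p, q),
                 (1 - stats::cor(p, q, method = "kendall")) / 2,
                 tolerance = 1e-12)
  }
})

test_that("all measures are symmetric and zero on identical inputs", {
  set.seed(502)
  for (k in 1:10) {
    p <- randomHistogram()
    q <- randomHistogram()
    for (ms in c("HI", "MD", "BD", "JS", "TAU")) {
      expect_equal(histogramDistance(p, q, ms), histogramDistance(q, p, ms))
      if (ms != "TAU")  # tau needs non-tied pairs, identical is still 0
        expect_equal(histogramDistance(p, p, ms), 0)
    }
    expect_equal(kendallTauDistance(p, p), 0)
  }
})

test_that("HI equals MD/2 exactly for normalized histograms", {
  set.seed(503)
  for (k in 1:30) {
    p <- randomHistogram(sample(5:200, 1L))
    q <- randomHistogram(sample(5:200, 1L))
    expect_equal(hiDistance(p, q), mdDistance(p, q) / 2, tolerance = 1e-12)
  }
})

test_that("MD satisfies the triangle inequality", {
  set.seed(504)
  for (k in 1:20) {
    p <- randomHistogram()
    q <- randomHistogram()
    r <- randomHistogram()
    expect_lte(mdDistance(p, r), mdDistance(p, q) + mdDistance(q, r) + 1e-12)
  }
})

test_that("JS lies in [0, 1] and attains 1 exactly on disjoint supports", {
  set.seed(505)
  for (k in 1:20) {
    p <- randomHistogram()
    q <- randomHistogram()
    d <- jsDivergence(p, q)
    expect_gte(d, 0)
    expect_lte(d, 1)
    disjoint <- !any(p > 0 & q > 0)
    if (disjoint) expect_equal(d, 1) else expect_lt(d, 1)
  }
  # constructed disjoint pair
  p <- pad511(c(0.4, 0.6, 0, 0))
  q <- pad511(c(0, 0, 0.3, 0.7))
  expect_equal(jsDivergence(p, q), 1)
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(506)
  hists <- replicate(4L, randomHistogram(), simplify = FALSE)
  names(hists) <- letters[1:4]
  for (ms in c("HI", "MD", "BD", "JS", "TAU")) {
    dm <- distanceMatrix(hists, ms)
    m <- as.matrix(dm)
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 4L))
    expect_identical(labels(dm), letters[1:4])
    expect_identical(distanceMeasure(dm), ms)
  }
  # the HI matrix is the MD matrix halved, entrywise
  expect_equal(as.matrix(distanceMatrix(hists, "HI")),
               as.matrix(distanceMatrix(hists, "MD")) / 2,
               tolerance = 1e-12)
})

test_that("an infinite Bhattacharyya entry fails loudly with the pair named", {
  hists <- list(a = pad511(c(1, 0)), b = pad511(c(0, 1)),
                c = pad511(c(0.5, 0.5)))
  expect_error(distanceMatrix(hists, "BD"), "'a' and 'b'")
  # identical histograms are fine
  two <- list(x = pad511(c(0.5, 0.5)), y = pad511(c(0.5, 0.5)))
  expect_equal(unname(as.matrix(distanceMatrix(two, "HI"))),
               matrix(0, 2, 2))
})

test_that("matrix correlation is scale-invariant over the upper triangle", {
  set.seed(507)
  hists <- replicate(5L, randomHistogram(), simplify = FALSE)
  names(hists) <- letters[1:5]
  m1 <- distanceMatrix(hists, "HI")
  expect_equal(matrixCorrelation(m1, m1), 1.0)

  double <- new("DistanceMatrix", values = 2 * as.matrix(m1), measure = "MD")
  expect_equal(matrixCorrelation(m1, double), 1.0)

  v <- as.matrix(m1)
  rev <- max(v) - v
  diag(rev) <- 0
  revm <- new("DistanceMatrix", values = rev, measure = "MD")
  expect_equal(matrixCorrelation(m1, revm), -1.0)

  const <- new("DistanceMatrix",
               values = matrix(1, 5, 5, dimnames = dimnames(v)) -
                        diag(5), measure = "MD")
  expect_error(matrixCorrelation(m1, const), "constant")
})

test_that("PHYLIP and TSV matrix exports are readable", {
  set.seed(508)
  hists <- replicate(3L, randomHistogram(), simplify = FALSE)
  names(hists) <- c("alpha", "beta", "gamma")
  dm <- distanceMatrix(hists, "HI")
  f <- tempfile(fileext = ".phy")
  writePhylipMatrix(dm, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1L])), 3L)
  expect_length(lines, 4L)

  f2 <- tempfile(fileext = ".tsv")
  writeDistanceTSV(dm, f2)
  df <- utils::read.table(f2, header = TRUE, sep = "\t")
  expect_equal(df$id, c("alpha", "beta", "gamma"))
})
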