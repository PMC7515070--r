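test_that("width and symmetry fields satisfy their defining identities", {
  sp <- analyticSpectrum(c(0.5, 0.3, 0.2))
  m <- widthAndSymmetry(sp)
  expect_equal(m@deltaAlpha, m@deltaRight + m@deltaLeft, tolerance = 1e-12)
  expect_equal(m@r, m@deltaRight / m@deltaLeft, tolerance = 1e-12)
  pts <- spectrumPoints(sp)
  expect_equal(m@alphaMax, pts$alpha[1])          # q = -10 endpoint
  expect_equal(m@alphaMin, pts$alpha[nrow(pts)])  # q = +10 endpoint
  expect_equal(m@alpha0, pts$alpha[pts$q == 0])   # f max at q = 0
})

test_that("a deterministic binomial cascade has a symmetric spectrum", {
  sp <- computeSpectrum(makeCascade(c(0.6, 0.4), levels = 14))
  m <- widthAndSymmetry(sp)
  expect_equal(m@r, 1, tolerance = 0.02)
  expect_equal(m@skewLabel, "symmetric")
})

test_that("skew labels follow the configurable thresholds", {
  expect_equal(classifySkew(6.65), "sharply_right")
  expect_equal(classifySkew(2.5), "sharply_right")
  expect_equal(classifySkew(1.5), "right")
  expect_equal(classifySkew(1.0), "symmetric")
  expect_equal(classifySkew(0.9), "left")
  expect_equal(classifySkew(0.4), "sharply_left")
  expect_equal(classifySkew(0.4, skewThresholds(sharpLow = 0.3)), "left")
  expect_error(classifySkew(-1), "positive")
})

test_that("a near-monofractal spectrum flags r as infinite", {
  sp <- computeSpectrum(makeCascade(c(0.5, 0.5), levels = 10),
                        qgrid = makeQGrid(step = 0.5))
  expect_warning(m <- widthAndSymmetry(sp), "degenerate")
  expect_true(is.infinite(m@r))
  expect_true(m@degenerate)
})

test_that("finite differences are exact on lines and quadratics", {
  a <- seq(0, 2, length.out = 201)
  lin <- spectrumDerivatives(specFromXY(a, a))
  expect_equal(lin$first, rep(1, 200), tolerance = 1e-9)
  expect_equal(lin$d2, rep(0, 199), tolerance = 1e-9)

  quadY <- 1 - (a - 1)^2
  for (mode in c("paper_uniform", "nonuniform")) {
    d <- spectrumDerivatives(specFromXY(a, quadY), mode = mode)
    expect_equal(d$d2, rep(-2, 199), tolerance = 1e-6)
  }
  expect_length(lin$first, 200)
  expect_length(lin$d2, 199)
})

test_that("curvature recovers circle and parabola geometry within 1%", {
  # upper arc of a circle of radius 2: K = 1/rho = 0.5
  x <- seq(-0.5, 0.5, length.out = 201)
  circ <- specFromXY(x, sqrt(4 - x^2))
  for (mode in c("nonuniform", "paper_uniform")) {
    k <- curvatureValues(curvatureProfile(circ, mode = mode))
    expect_lt(max(abs(k - 0.5) / 0.5), 0.01)
  }
  # parabola vertex with zero slope: K = 2c
  cc <- 3
  a <- seq(0.5, 1.5, length.out = 201)
  par <- curvatureProfile(specFromXY(a, 1 - cc * (a - 1)^2))
  kc <- curvatureValues(par)[centerIndex(par)]
  expect_lt(abs(kc - 2 * cc) / (2 * cc), 0.01)
})

test_that("the curvature profile has 199 points centred on q = 0", {
  sp <- computeSpectrum(makeCascade(c(0.6, 0.4), levels = 14))
  prof <- curvatureProfile(sp)
  expect_length(curvatureValues(prof), 199)
  expect_equal(centerIndex(prof), 100L)
  expect_equal(qValues(prof)[100], 0)
  expect_true(all(curvatureValues(prof) >= 0))
  # curvature vanishes far from the spectrum maximum
  k <- curvatureValues(prof)
  expect_lt(max(k[c(1:20, 180:199)]), 0.05 * max(k))
})

test_that("curvature is symmetric for symmetric spectra and reversal-invariant", {
  sp <- analyticSpectrum(c(0.6, 0.4))
  prof <- curvatureProfile(sp, mode = "nonuniform")
  k <- curvatureValues(prof)
  expect_lt(max(abs(k - rev(k))), 1e-6)

  # reversing the traversal direction of the (alpha, f) points
  pts <- spectrumPoints(sp)
  revsp <- specFromXY(rev(pts$alpha), rev(pts$f), q = -rev(pts$q))
  krev <- curvatureValues(curvatureProfile(revsp, mode = "nonuniform"))
  expect_equal(krev, rev(k), tolerance = 1e-9)
})

test_that("narrowing the spectrum scales the vertex curvature as 1/s^2", {
  base <- analyticSpectrum(c(0.6, 0.4))
  pts <- spectrumPoints(base)
  a0 <- pts$alpha[pts$q == 0]
  kv <- function(s) {
    sq <- specFromXY(a0 + s * (pts$alpha - a0), pts$f, q = pts$q)
    p <- curvatureProfile(sq, mode = "nonuniform")
    maxCurvature(p)$kMax
  }
  expect_equal(kv(0.5) / kv(1), 4, tolerance = 0.05 * 4)
  # a near-uniform trinomial is spikier than a broad one
  kNarrow <- maxCurvature(curvatureProfile(
    analyticSpectrum(c(0.4, 0.33, 0.27))))$kMax
  kBroad <- maxCurvature(curvatureProfile(
    analyticSpectrum(c(0.55, 0.3, 0.15))))$kMax
  expect_gt(kNarrow, kBroad)
})

test_that("maxCurvature restricts to the q window and breaks ties to |q|", {
  prof <- profileFromK(c(0.1, 5.0, 0.2), q = c(-0.1, 0, 0.1))
  mk <- maxCurvature(prof)
  expect_equal(mk$kMax, 5.0)
  expect_equal(mk$kArgmaxQ, 0)

  tie <- profileFromK(c(3, 1, 3), q = c(-2, 0, 1))
  expect_equal(maxCurvature(tie)$kArgmaxQ, 1)       # smaller |q| wins
  expect_equal(maxCurvature(tie, windowHalfwidthQ = 1.5)$kMax, 3)
  expect_equal(maxCurvature(tie, windowHalfwidthQ = 0.5)$kMax, 1)
})

test_that("a monofractal spectrum yields a degenerate profile with infinite k", {
  sp <- computeSpectrum(makeCascade(c(0.5, 0.5), levels = 10),
                        qgrid = makeQGrid(step = 0.5))
  prof <- curvatureProfile(sp)
  expect_true(prof@degenerate)
  mk <- maxCurvature(prof)
  expect_true(is.infinite(mk$kMax))
  expect_warning(m <- computeShapeMetrics(sp), "degenerate")
  expect_true(is.infinite(m@kMax))
})

test_that("metrics and curvature CSV exports carry the contracted columns", {
  tg <- makeRRSurrogate("healthy_like", levels = 6, seed = 5)
  rec <- analyzeTachogram(tg, base = 3)
  f <- tempfile(fileext = ".csv")
  writeMetricsCSV(list(rec), f)
  got <- read.csv(f)
  expect_equal(names(got),
               c("subject_id", "condition", "nyha", "segment", "alpha_min",
                 "alpha_max", "alpha_0", "delta_alpha", "delta_right",
                 "delta_left", "r", "skew_label", "k_max", "k_argmax_q"))
  expect_equal(got$condition, "healthy")

  f2 <- tempfile(fileext = ".csv")
  writeCurvatureCSV(curvatureProfileOf(rec), f2)
  cv <- read.csv(f2)
  expect_equal(names(cv), c("index", "q", "K"))
  expect_equal(cv$index, 1:199)
})
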