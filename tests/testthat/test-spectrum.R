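test_that("makeQGrid reproduces the default 201-point moment grid", {
  q <- makeQGrid()
  expect_length(q, 201)
  expect_equal(q[1], -10)
  expect_equal(q[201], 10)
  expect_true(any(q == 0) && any(q == 1))
  expect_length(makeQGrid(step = 0.2), 101)
  expect_error(makeQGrid(step = 0.3), "multiple")
})

test_that("boxProbabilities sums contiguous boxes and conserves mass", {
  uni <- makeCascade(c(0.5, 0.5), levels = 3)
  expect_equal(boxProbabilities(uni, 1), c(0.5, 0.5))

  casc <- makeCascade(c(0.6, 0.4), levels = 3)
  expect_equal(boxProbabilities(casc, 1), c(0.6, 0.4))
  expect_equal(boxProbabilities(casc, 2), c(0.36, 0.24, 0.24, 0.16))
  for (n in 1:3) expect_equal(sum(boxProbabilities(casc, n)), 1)
  expect_error(boxProbabilities(casc, 4), "1\\.\\.m")
})

test_that("muFamily matches hand-computed warped weights and edge cases", {
  P <- c(0.6, 0.4)
  expect_equal(muFamily(P, 1), P)                       # q = 1 replicates P
  expect_equal(muFamily(P, 2), c(0.36, 0.16) / 0.52)    # hand computation
  expect_equal(muFamily(c(0.5, 0, 0.5), 0), c(0.5, 0.5))  # zero boxes dropped
  expect_error(muFamily(c(0, 0, 0) + 0, 2), "sum to 1")
  # stability at |q| = 10 on tiny masses
  P <- boxProbabilities(makeCascade(c(0.6, 0.4), 16), 14)
  mu <- muFamily(P, -10)
  expect_true(all(is.finite(mu)))
  expect_equal(sum(mu), 1, tolerance = 1e-12)
})

test_that("scaling sums are exact on the uniform measure and always <= 0", {
  uni <- makeCascade(c(0.5, 0.5), levels = 6)
  for (q in c(-5, 0, 1, 5)) {
    s <- scalingSums(uni, q)
    expect_equal(s$Sf, -s$n * log(2), tolerance = 1e-12)
    expect_equal(s$Salpha, -s$n * log(2), tolerance = 1e-12)
  }
  casc <- makeCascade(c(0.6, 0.4), levels = 8)
  for (q in c(-10, -1, 0, 2, 10)) {
    expect_true(all(scalingSums(casc, q)$Sf <= 1e-12))
  }
})

test_that("mu normalisation holds at every (q, L) on an irregular measure", {
  set.seed(11)
  p <- runif(2^8)
  meas <- new("BoxMeasure", p = p / sum(p), base = 2L, m = 8L,
              sourceId = "rand")
  for (q in c(-10, -3, 0, 1, 3, 10)) {
    for (n in c(1, 4, 7)) {
      mu <- muFamily(boxProbabilities(meas, n), q)
      expect_lt(abs(sum(mu) - 1), 1e-10)
    }
  }
})

test_that("spectrum points recover the binomial closed forms", {
  casc <- makeCascade(c(0.6, 0.4), levels = 14)
  alpha0 <- -(log2(0.6) + log2(0.4)) / 2
  p0 <- spectrumPoint(casc, 0)
  expect_equal(p0$alpha, alpha0, tolerance = 1e-3)
  expect_equal(p0$f, 1.0, tolerance = 1e-3)
  infoDim <- -(0.6 * log2(0.6) + 0.4 * log2(0.4))
  p1 <- spectrumPoint(casc, 1)
  expect_equal(p1$alpha, infoDim, tolerance = 1e-3)
  expect_equal(p1$f, infoDim, tolerance = 1e-3)
  expect_true(all(c(p0$r2_alpha, p0$r2_f) > 0.999))
})

test_that("uniform and p=0.5 cascades are monofractal with alpha = f = 1", {
  sp <- computeSpectrum(makeCascade(c(0.5, 0.5), levels = 10),
                        qgrid = makeQGrid(step = 0.5))
  expect_equal(alphaValues(sp), rep(1, 41), tolerance = 1e-12)
  expect_equal(fValues(sp), rep(1, 41), tolerance = 1e-12)
})

test_that("the estimator matches the closed-form cascade spectrum", {
  # central oracle equivalence on an asymmetric trinomial (depth 9, base 3)
  w <- c(0.5, 0.3, 0.2)
  sp <- computeSpectrum(makeCascade(w, levels = 9))
  an <- t(vapply(qValues(sp), function(q) cascadeAlphaF(w, q), numeric(2)))
  expect_lt(max(abs(alphaValues(sp) - an[, "alpha"])), 0.02)
  expect_lt(max(abs(fValues(sp) - an[, "f"])), 0.02)
  # and the packaged analytic oracle agrees with the independent one
  ansp <- analyticSpectrum(w)
  expect_equal(alphaValues(ansp), an[, "alpha"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fValues(ansp), an[, "f"], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("estimated cascade spectra satisfy the structural identities", {
  sp <- computeSpectrum(makeCascade(c(0.6, 0.4), levels = 14))
  pts <- spectrumPoints(sp)
  # alpha non-increasing in q
  expect_true(all(diff(pts$alpha) <= 1e-6))
  # f(q=0) equals the support dimension
  expect_equal(pts$f[pts$q == 0], 1, tolerance = 1e-3)
  # f = alpha at q = 1 (both estimate the information dimension)
  expect_lt(abs(pts$f[abs(pts$q - 1) < 1e-9] -
                  pts$alpha[abs(pts$q - 1) < 1e-9]), 1e-6)
  # binomial symmetry identity alpha(q) + alpha(-q) = 2 alpha0
  alpha0 <- pts$alpha[pts$q == 0]
  rev_alpha <- rev(pts$alpha)
  expect_lt(max(abs(pts$alpha + rev_alpha - 2 * alpha0)), 1e-3)
  expect_lt(max(abs(pts$f - rev(pts$f))), 1e-3)
})

test_that("regression diagnostics agree with lm on the scaling sums", {
  # an irregular measure, so the scaling fits have genuine residuals
  set.seed(31)
  p <- runif(2^8)
  casc <- new("BoxMeasure", p = p / sum(p), base = 2L, m = 8L,
              sourceId = "rand")
  s <- scalingSums(casc, 2.5)
  fitA <- lm(Salpha ~ logL, data = s)
  fitF <- lm(Sf ~ logL, data = s)
  pt <- spectrumPoint(casc, 2.5)
  expect_equal(pt$alpha, unname(coef(fitA)[2]), tolerance = 1e-12)
  expect_equal(pt$f, unname(coef(fitF)[2]), tolerance = 1e-12)
  expect_equal(pt$stderr_alpha, summary(fitA)$coefficients[2, 2],
               tolerance = 1e-9)
  expect_equal(pt$r2_f, summary(fitF)$r.squared, tolerance = 1e-9)
})

test_that("spectrum CSV export has the contracted header and row count", {
  sp <- computeSpectrum(makeCascade(c(0.6, 0.4), levels = 8))
  f <- tempfile(fileext = ".csv")
  writeSpectrumCSV(sp, f)
  got <- read.csv(f)
  expect_equal(names(got),
               c("q", "alpha", "f", "r2_alpha", "r2_f",
                 "stderr_alpha", "stderr_f"))
  expect_equal(nrow(got), 201)
  expect_equal(got$alpha, alphaValues(sp), tolerance = 1e-4)
})
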