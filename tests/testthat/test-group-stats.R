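test_that("summarizeSymmetry counts and averages the skew classes", {
  s <- summarizeSymmetry(c(2, 3, 0.5))
  expect_equal(s$rightCount, 2)
  expect_equal(s$leftCount, 1)
  expect_equal(s$rMeanRight, 2.5)
  expect_equal(s$rMeanLeft, 0.5)
  expect_equal(s$rightCount + s$leftCount + s$symmetricCount, s$n)

  allSym <- summarizeSymmetry(rep(1, 4))
  expect_equal(allSym$symmetricCount, 4)
  expect_equal(allSym$rightCount, 0)
  expect_equal(allSym$leftCount, 0)
  expect_true(is.na(allSym$rMeanRight))
})

test_that("averageProfile is linear, permutation-invariant and tracks mvac", {
  mkrec <- function(peak, id) {
    q <- seq(-1, 1, 0.5)
    prof <- profileFromK(c(0.1, 0.5, peak, 0.5, 0.1), q)
    met <- new("ShapeMetrics", alphaMin = 0.8, alphaMax = 1.4, alpha0 = 1.1,
               deltaAlpha = 0.6, deltaRight = 0.3, deltaLeft = 0.3, r = 1,
               skewLabel = "symmetric", kMax = peak, kArgmaxQ = 0,
               degenerate = FALSE)
    newSubjectRecord(met, prof, subjectId = id)
  }
  r2 <- mkrec(2, "a"); r4 <- mkrec(4, "b")
  g <- averageProfile(list(r2, r4), "pair")
  expect_equal(mvac(g), 3)                       # mean of peaks 2 and 4
  expect_equal(g@mvacArgmaxQ, 0)
  expect_equal(mvac(g), max(g@meanProfile))

  # identical profiles: zero dispersion, mean equals either
  gid <- averageProfile(list(r2, mkrec(2, "c")), "same")
  expect_equal(gid@profileSd, rep(0, 5))
  expect_equal(gid@meanProfile, curvatureValues(curvatureProfileOf(r2)))

  # permutation invariance
  gswap <- averageProfile(list(r4, r2), "swap")
  expect_equal(gswap@meanProfile, g@meanProfile)

  # mixed lengths are rejected
  short <- newSubjectRecord(r2@metrics, profileFromK(c(1, 2, 1), c(-1, 0, 1)),
                            subjectId = "d")
  expect_error(averageProfile(list(r2, short)), "mixed lengths")
})

test_that("welchTest flags separated groups and is symmetric in its arguments", {
  expect_equal(welchTest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  z <- welchTest(c(5, 5, 5), c(5, 5, 5))        # zero variance, equal means
  expect_equal(z$p, 1)
  expect_false(z$significant)
  expect_equal(welchTest(c(5, 5, 5), c(7, 7, 7))$p, 0)

  set.seed(101)
  a <- rnorm(50); b <- rnorm(50, mean = 2)
  t1 <- welchTest(a, b)
  expect_true(t1$significant)
  t2 <- welchTest(b, a)
  expect_equal(t1$p, t2$p)
  expect_equal(t1$t, -t2$t)
  expect_error(welchTest(1, c(1, 2)), "n >= 2")
})

test_that("the permutation test agrees with Welch on well-separated groups", {
  set.seed(202)
  a <- rnorm(15); b <- rnorm(15, mean = 3)
  pt <- permutationTest(a, b, nPerm = 2000, seed = 7)
  expect_true(pt$significant)
  # reproducible under the same seed
  pt2 <- permutationTest(a, b, nPerm = 2000, seed = 7)
  expect_equal(pt$p, pt2$p)
  # null case: p well away from significance most of the time
  pn <- permutationTest(rnorm(15), rnorm(15), nPerm = 2000, seed = 8)
  expect_gt(pn$p, 0.001)
})

test_that("NYHA stratification orders mvac by severity and tests neighbours", {
  sev <- nyhaSeverity()
  classes <- c("I", "II", "III", "III-IV")
  records <- unlist(lapply(classes, function(cl) {
    tgs <- simulateCohort(6, "chf_like", severity = sev[[cl]], levels = 7,
                          seed = 1000 + match(cl, classes), nyha = cl)
    lapply(tgs, analyzeTachogram, base = 3)
  }), recursive = FALSE)
  expect_warning(strat <- stratifyByNyha(records), "omitted: IV")
  expect_equal(names(strat$summaries), classes)
  mv <- vapply(strat$summaries, mvac, numeric(1))
  expect_true(all(diff(mv) > 0))                 # severity monotone
  expect_equal(nrow(strat$tests), 3)             # I-II, II-III, III-(III-IV)
  expect_equal(strat$tests$group1, c("I", "II", "III"))

  # single class present: one summary, no tests
  one <- suppressWarnings(stratifyByNyha(records[1:6]))
  expect_length(one$summaries, 1)
  expect_null(one$tests)
  expect_error(stratifyByNyha(list()), "no NYHA labels|at least")
})

test_that("assessSubject applies the three criteria with a 2-of-3 rule", {
  ref <- list(deltaAlphaRef = 0.5, kRef = 30)
  mk <- function(dA, r, k) {
    new("ShapeMetrics", alphaMin = 1, alphaMax = 1 + dA, alpha0 = 1 + dA / 2,
        deltaAlpha = dA, deltaRight = dA / 2, deltaLeft = dA / 2, r = r,
        skewLabel = classifySkew(r), kMax = k, kArgmaxQ = 0,
        degenerate = FALSE)
  }
  healthy <- assessSubject(mk(0.8, 2, 10), ref)
  expect_equal(healthy$label, "healthy_like")
  expect_equal(healthy$score, 3)

  chf <- assessSubject(mk(0.2, 0.4, 200), ref)
  expect_equal(chf$label, "chf_like")
  expect_equal(chf$score, 0)

  # small curvature rescues a slightly left-skewed wide spectrum
  borderline <- assessSubject(mk(0.8, 0.9, 10), ref)
  expect_equal(borderline$label, "healthy_like")
  expect_equal(borderline$score, 2)

  expect_error(assessSubject(mk(0.8, 2, 10), list(kRef = 1)),
               "deltaAlphaRef")
})

test_that("group JSON and mean-profile exports round-trip", {
  tgs <- c(simulateCohort(3, "healthy_like", levels = 6, seed = 31),
           simulateCohort(3, "chf_like", severity = 0.7, levels = 6,
                          seed = 32))
  recs <- lapply(tgs, analyzeTachogram, base = 3)
  conds <- vapply(recs, condition, character(1))
  gh <- averageProfile(recs[conds == "healthy"], "healthy")
  gc <- averageProfile(recs[conds == "chf"], "chf")
  tt <- welchTest(gh@kMaxValues, gc@kMaxValues)
  f <- tempfile(fileext = ".json")
  writeGroupJSON(list(healthy = gh, chf = gc),
                 data.frame(group1 = "healthy", group2 = "chf", stat = tt$t,
                            p = tt$p, significant = tt$significant),
                 f)
  back <- jsonlite::read_json(f)
  expect_named(back$groups, c("healthy", "chf"))
  expect_equal(back$groups$healthy$n, 3)
  expect_equal(back$groups$chf$mvac, mvac(gc))
  expect_length(back$tests, 1)

  fp <- tempfile(fileext = ".csv")
  writeMeanProfileCSV(gh, fp)
  prof <- read.csv(fp)
  expect_equal(names(prof), c("index", "q", "mean_K", "sd", "sem"))
  expect_equal(nrow(prof), length(gh@meanProfile))
})
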