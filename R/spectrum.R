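## Direct (Chhabra-Jensen) estimation of the singularity spectrum.
##
## For each moment order q the box masses P_i(L) at box size L = b^-n are
## warped into the normalised family mu_i(q, L) = P_i^q / sum P_j^q; the
## slopes of  sum mu log mu  and  sum mu log P  against log L give f(q) and
## alpha(q) directly, with no Legendre transform. All powers are taken in
## log space (max-shifted) so |q| = 10 on masses ~1e-6 neither overflows
## nor underflows.

#' Moment-order grid for spectrum estimation
#'
#' @param qMin,qMax,step grid limits and spacing; the defaults (-10, 10,
#'   0.1) give 201 values with 0 and 1 on the grid.
#' @return numeric vector `qMin, qMin+step, ..., qMax`.
#' @export
makeQGrid <- function(qMin = -10, qMax = 10, step = 0.1) {
  if (step <= 0) stop("step must be positive")
  if (qMax <= qMin) stop("qMax must exceed qMin")
  n <- round((qMax - qMin) / step)
  if (abs(qMin + n * step - qMax) > 1e-9) {
    stop("(qMax - qMin) must be an integer multiple of step")
  }
  qMin + step * (0:n)
}

#' Partition levels usable for the scaling fits
#'
#' Levels n index box sizes L = b^-n. The default uses every informative
#' level 1..m-1 of a depth-m measure: at least b boxes and at least b
#' samples per box.
#'
#' @param measure a [BoxMeasure-class].
#' @param levels optional integer vector overriding the default range.
#' @return integer vector of levels.
#' @export
scaleLevels <- function(measure, levels = NULL) {
  stopifnot(is(measure, "BoxMeasure"))
  m <- measureLevels(measure)
  if (is.null(levels)) levels <- seq_len(max(m - 1L, 0L))
  levels <- as.integer(levels)
  if (length(levels) == 0 || any(levels < 1L) || any(levels > m)) {
    stop("levels must lie in 1..m (m = ", m, ")")
  }
  sort(unique(levels))
}

#' Box masses of a measure at one partition level
#'
#' Sums the measure over `base^n` contiguous boxes of `base^(m-n)` samples
#' each; conservation of mass means the result sums to 1.
#'
#' @param measure a [BoxMeasure-class].
#' @param n integer(1), partition level (1 <= n <= m).
#' @return numeric of length `base^n` summing to 1.
#' @export
boxProbabilities <- function(measure, n) {
  stopifnot(is(measure, "BoxMeasure"))
  n <- as.integer(n)
  m <- measureLevels(measure)
  if (length(n) != 1 || n < 1L || n > m) {
    stop("n must lie in 1..m (m = ", m, ")")
  }
  b <- measureBase(measure)
  block <- b^(m - n)
  .colSumsBlocks(boxMasses(measure), block)
}

.colSumsBlocks <- function(p, block) {
  if (block == 1) return(p)
  colSums(matrix(p, nrow = block))
}

#' q-warped normalised box weights
#'
#' `mu_i = P_i^q / sum_j P_j^q` over the positive-mass boxes (zero-mass
#' boxes are excluded: the 0 * log 0 -> 0 convention). Computed in log
#' space for numerical stability at large |q|.
#'
#' @param P numeric box masses, non-negative, summing to 1.
#' @param q numeric(1), moment order.
#' @return numeric of `sum(P > 0)` weights summing to 1.
#' @export
muFamily <- function(P, q) {
  if (any(P < 0)) stop("box masses must be non-negative")
  if (abs(sum(P) - 1) > 1e-9) stop("box masses must sum to 1")
  P <- P[P > 0]
  if (length(P) == 0) stop("all boxes have zero mass")
  s <- q * log(P)
  s <- s - max(s)
  e <- exp(s)
  e / sum(e)
}

#' Per-scale scaling sums for one moment order
#'
#' Evaluates, for each level n, the numerators of the two scaling laws:
#' `S_f = sum mu log mu` (an entropy, always <= 0) and
#' `S_alpha = sum mu log P` (natural logs). Their slopes versus
#' `log L = -n log b` are f(q) and alpha(q).
#'
#' @param measure a [BoxMeasure-class].
#' @param q numeric(1), moment order.
#' @param levels integer vector of partition levels (default
#'   [scaleLevels()]).
#' @return data.frame with columns `n`, `logL`, `Sf`, `Salpha`.
#' @export
scalingSums <- function(measure, q, levels = NULL) {
  levels <- scaleLevels(measure, levels)
  b <- measureBase(measure)
  out <- t(vapply(levels, function(n) {
    P <- boxProbabilities(measure, n)
    P <- P[P > 0]
    mu <- muFamily(P, q)
    lmu <- log(mu)
    lmu[mu == 0] <- 0
    c(Sf = sum(mu * lmu), Salpha = sum(mu * log(P)))
  }, numeric(2)))
  data.frame(n = levels, logL = -levels * log(b),
             Sf = out[, "Sf"], Salpha = out[, "Salpha"])
}

# OLS slope, R^2 and slope standard error of y on x, vectorised over the
# columns of Y. Verified against lm() in the test suite.
.olsSlopes <- function(x, Y) {
  nlev <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx <= 0) stop("degenerate regression: all log L equal")
  slope <- colSums(xc * Y) / sxx
  fitted <- outer(xc, slope) + rep(colMeans(Y), each = nlev)
  res <- Y - fitted
  sse <- colSums(res^2)
  sst <- colSums((Y - rep(colMeans(Y), each = nlev))^2)
  r2 <- ifelse(sst > 0, 1 - sse / sst, 1)
  r2 <- pmin(pmax(r2, 0), 1)
  se <- if (nlev > 2) sqrt(pmax(sse, 0) / (nlev - 2) / sxx) else rep(NA_real_, ncol(Y))
  list(slope = slope, r2 = r2, se = se)
}

# Scaling-sum matrices (levels x length(q)) for a vector of q values.
.scalingSumMatrices <- function(measure, q, levels) {
  nq <- length(q)
  Sf <- Sa <- matrix(NA_real_, length(levels), nq)
  for (i in seq_along(levels)) {
    P <- boxProbabilities(measure, levels[i])
    P <- P[P > 0]
    lp <- log(P)
    nb <- length(lp)
    W <- outer(lp, q)                         # q * log P_i
    # columnwise max of W: q >= 0 pairs with max(lp), q < 0 with min(lp)
    cmax <- ifelse(q >= 0, q * max(lp), q * min(lp))
    E <- exp(W - rep(cmax, each = nb))
    Z <- colSums(E)
    mu <- E / rep(Z, each = nb)
    logmu <- W - rep(cmax + log(Z), each = nb)
    Sf[i, ] <- colSums(mu * logmu)
    Sa[i, ] <- colSums(mu * lp)
  }
  list(Sf = Sf, Sa = Sa)
}

#' Estimate one spectrum point
#'
#' Least-squares slopes of the scaling sums versus `log L` at a single
#' moment order, with goodness-of-fit diagnostics.
#'
#' @inheritParams scalingSums
#' @return one-row data.frame `q, alpha, f, r2_alpha, r2_f, stderr_alpha,
#'   stderr_f`.
#' @export
spectrumPoint <- function(measure, q, levels = NULL) {
  levels <- scaleLevels(measure, levels)
  if (length(levels) < 3) stop("need at least 3 scales for the fits")
  sp <- computeSpectrum(measure, qgrid = q, levels = levels)
  spectrumPoints(sp)
}

#' Compute the full multifractal spectrum
#'
#' Runs the direct estimator independently at every q of the grid: box
#' masses at each level are warped by q, the two scaling sums are formed,
#' and ordinary least squares over `log L` yields `alpha(q)` and `f(q)`
#' with per-fit R-squared and slope standard errors. 201 points under the
#' default grid.
#'
#' @param measure a [BoxMeasure-class].
#' @param qgrid numeric vector of moment orders (default [makeQGrid()]).
#' @param levels integer vector of partition levels (default
#'   [scaleLevels()]: 1..m-1).
#' @return A [MultifractalSpectrum-class].
#' @examples
#' cascade <- makeCascade(c(0.6, 0.4), levels = 12)
#' sp <- computeSpectrum(cascade)
#' nrow(spectrumPoints(sp))  # 201
#' @export
computeSpectrum <- function(measure, qgrid = makeQGrid(), levels = NULL) {
  stopifnot(is(measure, "BoxMeasure"))
  levels <- scaleLevels(measure, levels)
  if (length(levels) < 3) stop("need at least 3 scales for the fits")
  x <- -levels * log(measureBase(measure))
  S <- .scalingSumMatrices(measure, qgrid, levels)
  fitF <- .olsSlopes(x, S$Sf)
  fitA <- .olsSlopes(x, S$Sa)
  ord <- order(qgrid)
  pts <- data.frame(
    q = qgrid, alpha = fitA$slope, f = fitF$slope,
    r2_alpha = fitA$r2, r2_f = fitF$r2,
    stderr_alpha = fitA$se, stderr_f = fitF$se
  )[ord, , drop = FALSE]
  rownames(pts) <- NULL
  new("MultifractalSpectrum", points = pts,
      base = measureBase(measure), levels = levels,
      sourceId = measure@sourceId)
}

#' Write a spectrum to CSV
#'
#' One row per q with the header
#' `q,alpha,f,r2_alpha,r2_f,stderr_alpha,stderr_f` (201 rows under the
#' default grid). Numbers are written with 6 significant digits.
#'
#' @param spec a [MultifractalSpectrum-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectrumCSV <- function(spec, path) {
  stopifnot(is(spec, "MultifractalSpectrum"))
  pts <- spectrumPoints(spec)
  .writeNumericCSV(pts, path)
}

.fmt6 <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (!is.finite(v)) as.character(v) else formatC(signif(v, 6), format = "g",
                                                      digits = 6)
    }, character(1))
    out
  } else {
    as.character(x)
  }
}

.writeNumericCSV <- function(df, path) {
  out <- as.data.frame(lapply(df, .fmt6), stringsAsFactors = FALSE,
                       optional = TRUE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
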