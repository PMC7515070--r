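## Reduction of a singularity spectrum to its shape statistics: width,
## asymmetry about the maximum, symmetry ratio r, and the finite-difference
## curvature profile K(q) with its maximum.

#' Width and asymmetry of a multifractal spectrum
#'
#' `alphaMax` and `alphaMin` are read at the q-grid endpoints (q min and
#' q max respectively; alpha is non-increasing in q, so these are the
#' spectrum extrema on the grid); `alpha0` is alpha at the f-maximising
#' point (ties broken toward q = 0, the theoretical maximiser). The width
#' `deltaAlpha = alphaMax - alphaMin` measures the degree of
#' multifractality; the symmetry ratio `r = deltaRight / deltaLeft`
#' quantifies the skew: r > 1 right-skewed, r < 1 left-skewed, r = 1
#' symmetric.
#'
#' @param spec a [MultifractalSpectrum-class] with at least 3 points.
#' @param thresholds skew-label thresholds, see [classifySkew()].
#' @return A [ShapeMetrics-class] with the width/asymmetry fields set
#'   (curvature fields NA; see [computeShapeMetrics()] for the full set).
#'   When the left half-width is numerically zero (near-monofractal
#'   spectrum) `r` is `Inf` and the object is flagged degenerate, with a
#'   warning.
#' @export
widthAndSymmetry <- function(spec, thresholds = skewThresholds()) {
  stopifnot(is(spec, "MultifractalSpectrum"))
  pts <- spectrumPoints(spec)
  n <- nrow(pts)
  if (n < 3) stop("spectrum needs at least 3 points")
  alphaMax <- pts$alpha[1]                  # q = q_min
  alphaMin <- pts$alpha[n]                  # q = q_max
  fmax <- max(pts$f)
  cand <- which(pts$f >= fmax - 1e-12)
  i0 <- cand[which.min(abs(pts$q[cand]))]   # tie-break toward q = 0
  alpha0 <- pts$alpha[i0]
  dR <- alphaMax - alpha0
  dL <- alpha0 - alphaMin
  degenerate <- FALSE
  if (dL <= 1e-9) {
    warning("left half-width is numerically zero; r reported as Inf ",
            "(degenerate, near-monofractal spectrum)")
    r <- Inf
    degenerate <- TRUE
  } else {
    r <- dR / dL
  }
  new("ShapeMetrics",
      alphaMin = alphaMin, alphaMax = alphaMax, alpha0 = alpha0,
      deltaAlpha = alphaMax - alphaMin, deltaRight = dR, deltaLeft = dL,
      r = r, skewLabel = classifySkew(r, thresholds),
      kMax = NA_real_, kArgmaxQ = NA_real_, degenerate = degenerate)
}

#' Skew-label thresholds
#'
#' @param sharpLow,low,high,sharpHigh boundaries of the five skew classes
#'   on the symmetry ratio r: below `sharpLow` the spectrum is sharply
#'   left-skewed, above `sharpHigh` sharply right-skewed; `[low, high]`
#'   counts as symmetric.
#' @return named numeric vector of thresholds.
#' @export
skewThresholds <- function(sharpLow = 0.5, low = 0.95, high = 1.05,
                           sharpHigh = 2.0) {
  c(sharpLow = sharpLow, low = low, high = high, sharpHigh = sharpHigh)
}

#' Classify the spectrum skew from the symmetry ratio
#'
#' @param r positive symmetry ratio (Inf allowed: sharply right).
#' @param thresholds see [skewThresholds()].
#' @return one of `"sharply_left"`, `"left"`, `"symmetric"`, `"right"`,
#'   `"sharply_right"`.
#' @examples
#' classifySkew(6.65)  # sharply_right
#' classifySkew(0.4)   # sharply_left
#' @export
classifySkew <- function(r, thresholds = skewThresholds()) {
  if (length(r) != 1 || is.na(r) || r <= 0) stop("r must be a positive scalar")
  t <- thresholds
  if (r < t["sharpLow"]) "sharply_left"
  else if (r < t["low"]) "left"
  else if (r <= t["high"]) "symmetric"
  else if (r <= t["sharpHigh"]) "right"
  else "sharply_right"
}

# Merge consecutive spectrum points whose alpha values are closer than
# `tol` (duplicate abscissae would blow up the difference quotients):
# within a run, alpha and q are averaged and f is averaged.
.mergeDegenerateSteps <- function(q, alpha, f, tol = 1e-9) {
  grp <- cumsum(c(TRUE, abs(diff(alpha)) >= tol))
  if (max(grp) == length(alpha)) return(list(q = q, alpha = alpha, f = f))
  list(q = as.numeric(tapply(q, grp, mean)),
       alpha = as.numeric(tapply(alpha, grp, mean)),
       f = as.numeric(tapply(f, grp, mean)))
}

#' Finite-difference derivatives of the spectrum curve f(alpha)
#'
#' Differentiates the (alpha, f) points of the spectrum in grid order.
#' In mode `"paper_uniform"` the first derivative is the chain of
#' successive difference quotients (one per gap: 200 values for a
#' 201-point spectrum) and the second derivative at each interior point is
#' the classical three-point formula with the local mean spacing as h (199
#' values); this mimics a uniform-grid construction applied to the
#' (slightly) non-uniform alpha spacing. Mode `"nonuniform"` uses the
#' exact three-point formulas for unequal spacing. Consecutive points
#' closer than 1e-9 in alpha are merged first (see Details).
#'
#' @param spec a [MultifractalSpectrum-class].
#' @param mode `"paper_uniform"` (default) or `"nonuniform"`.
#' @return list with `q`, `alpha`, `f` (after merging), `first` (length
#'   n-1 difference quotients), `qInterior`, `d1` and `d2` (first and
#'   second derivative at the n-2 interior points).
#' @export
spectrumDerivatives <- function(spec, mode = c("paper_uniform", "nonuniform")) {
  stopifnot(is(spec, "MultifractalSpectrum"))
  mode <- match.arg(mode)
  pts <- spectrumPoints(spec)
  m <- .mergeDegenerateSteps(pts$q, pts$alpha, pts$f)
  n <- length(m$alpha)
  if (n < 3) stop("fewer than 3 usable points after merging degenerate steps")
  a <- m$alpha; f <- m$f
  da <- diff(a)
  first <- diff(f) / da                     # successive difference quotients
  i <- 2:(n - 1)
  if (mode == "paper_uniform") {
    h <- (a[i + 1] - a[i - 1]) / 2          # local mean spacing
    d2 <- (f[i + 1] - 2 * f[i] + f[i - 1]) / h^2
    d1 <- (first[i] + first[i - 1]) / 2     # mean of forward and backward
  } else {
    h1 <- a[i] - a[i - 1]
    h2 <- a[i + 1] - a[i]
    d1 <- (-h2 / (h1 * (h1 + h2))) * f[i - 1] +
      ((h2 - h1) / (h1 * h2)) * f[i] +
      (h1 / (h2 * (h1 + h2))) * f[i + 1]
    d2 <- 2 * (f[i - 1] / (h1 * (h1 + h2)) - f[i] / (h1 * h2) +
                 f[i + 1] / (h2 * (h1 + h2)))
  }
  list(q = m$q, alpha = a, f = f, first = first,
       qInterior = m$q[i], d1 = d1, d2 = d2)
}

#' Curvature profile of a multifractal spectrum
#'
#' Pointwise curvature `K = |f''| / (1 + f'^2)^(3/2)` of the (alpha, f)
#' curve at the interior grid points (the first and last point are
#' dropped by the finite differences): 199 values under the default
#' 201-point grid, with the centre entry aligned to q = 0. K is the
#' reciprocal of the local radius of curvature; it is large where the
#' spectrum is spiky around its maximum and falls to zero for large |q|.
#'
#' @inheritParams spectrumDerivatives
#' @return A [CurvatureProfile-class]; degenerate (empty, flagged) when
#'   the spectrum is too narrow to differentiate.
#' @export
curvatureProfile <- function(spec, mode = c("paper_uniform", "nonuniform")) {
  mode <- match.arg(mode)
  d <- tryCatch(spectrumDerivatives(spec, mode), error = function(e) NULL)
  if (is.null(d)) {
    return(new("CurvatureProfile", k = numeric(), q = numeric(),
               centerIndex = NA_integer_, degenerate = TRUE,
               sourceId = spec@sourceId))
  }
  k <- abs(d$d2) / (1 + d$d1^2)^1.5
  ci <- which.min(abs(d$qInterior))
  new("CurvatureProfile", k = k, q = d$qInterior,
      centerIndex = as.integer(ci), degenerate = FALSE,
      sourceId = spec@sourceId)
}

#' Maximum of a curvature profile
#'
#' The maximum of K restricted to `|q| <= windowHalfwidthQ` (the default
#' window spans the whole default grid; K is near zero away from the
#' spectrum maximum, so the unrestricted maximum is the vertex curvature).
#' Ties are broken toward the smallest |q|. A degenerate (point-like)
#' profile reports `kMax = Inf`.
#'
#' @param profile a [CurvatureProfile-class].
#' @param windowHalfwidthQ half-width of the q window (default 10).
#' @return list with `kMax` and `kArgmaxQ`.
#' @export
maxCurvature <- function(profile, windowHalfwidthQ = 10) {
  stopifnot(is(profile, "CurvatureProfile"))
  if (profile@degenerate || length(profile@k) == 0) {
    return(list(kMax = Inf, kArgmaxQ = NA_real_))
  }
  sel <- which(abs(profile@q) <= windowHalfwidthQ + 1e-12)
  if (length(sel) == 0) sel <- seq_along(profile@k)
  kmax <- max(profile@k[sel])
  ties <- sel[profile@k[sel] == kmax]
  arg <- ties[which.min(abs(profile@q[ties]))]
  list(kMax = kmax, kArgmaxQ = profile@q[arg])
}

#' Full per-subject shape statistics of one spectrum
#'
#' Combines [widthAndSymmetry()] with the curvature reduction: the
#' curvature profile is computed, its maximum located, and the result
#' returned as a complete [ShapeMetrics-class]. For a degenerate
#' (near-monofractal) spectrum `kMax` is `Inf`.
#'
#' @inheritParams widthAndSymmetry
#' @param mode derivative mode, see [spectrumDerivatives()].
#' @param windowHalfwidthQ window for the curvature maximum, see
#'   [maxCurvature()].
#' @return A [ShapeMetrics-class].
#' @export
computeShapeMetrics <- function(spec, mode = c("paper_uniform", "nonuniform"),
                                windowHalfwidthQ = 10,
                                thresholds = skewThresholds()) {
  mode <- match.arg(mode)
  wm <- widthAndSymmetry(spec, thresholds)
  prof <- curvatureProfile(spec, mode)
  mk <- maxCurvature(prof, windowHalfwidthQ)
  wm@kMax <- mk$kMax
  wm@kArgmaxQ <- mk$kArgmaxQ
  wm@degenerate <- wm@degenerate || prof@degenerate
  wm
}

#' Tabulate subject records as the metrics export table
#'
#' @param records list of [SubjectRecord-class] objects.
#' @return data.frame with one row per subject and the columns
#'   `subject_id, condition, nyha, segment, alpha_min, alpha_max, alpha_0,
#'   delta_alpha, delta_right, delta_left, r, skew_label, k_max,
#'   k_argmax_q`.
#' @export
metricsTable <- function(records) {
  stopifnot(length(records) > 0)
  do.call(rbind, lapply(records, function(rec) {
    stopifnot(is(rec, "SubjectRecord"))
    m <- rec@metrics
    data.frame(subject_id = rec@subjectId, condition = rec@condition,
               nyha = rec@nyha, segment = rec@segment,
               alpha_min = m@alphaMin, alpha_max = m@alphaMax,
               alpha_0 = m@alpha0, delta_alpha = m@deltaAlpha,
               delta_right = m@deltaRight, delta_left = m@deltaLeft,
               r = m@r, skew_label = m@skewLabel, k_max = m@kMax,
               k_argmax_q = m@kArgmaxQ, stringsAsFactors = FALSE)
  }))
}

#' Write per-subject shape metrics to CSV
#'
#' @param records list of [SubjectRecord-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMetricsCSV <- function(records, path) {
  .writeNumericCSV(metricsTable(records), path)
}

#' Write a curvature profile to CSV
#'
#' Columns `index,q,K`, index 1..199 under the default grid (the
#' "number of data" axis of the profile plots).
#'
#' @param profile a [CurvatureProfile-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCurvatureCSV <- function(profile, path) {
  stopifnot(is(profile, "CurvatureProfile"))
  df <- data.frame(index = seq_along(profile@k), q = profile@q,
                   K = profile@k)
  .writeNumericCSV(df, path)
}
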