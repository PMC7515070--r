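#' @import methods
#' @importFrom stats sd var setNames
NULL

CONDITION_LEVELS <- c("healthy", "chf", "unknown")
NYHA_LEVELS <- c("none", "I", "II", "III", "III-IV", "IV")
SEGMENT_LEVELS <- c("h24", "asleep6", "awake6")
SKEW_LABELS <- c("sharply_left", "left", "symmetric", "right", "sharply_right")

#' Tachogram: an ordered RR-interval series with subject metadata
#'
#' A `Tachogram` holds the beat-to-beat RR intervals (seconds) of one
#' recording, the implied cumulative time axis, subject metadata
#' (identifier, health condition, NYHA class) and optional behavioural-state
#' windows (asleep/awake) given as time intervals on the cumulative axis.
#'
#' @slot subjectId character(1), subject identifier.
#' @slot condition character(1), one of `"healthy"`, `"chf"`, `"unknown"`.
#' @slot nyha character(1), one of `"none"`, `"I"`, `"II"`, `"III"`,
#'   `"III-IV"`, `"IV"`.
#' @slot rr numeric, RR intervals in seconds; all finite and positive.
#' @slot t numeric, cumulative time: `t[1] = 0`, `t[i] = t[i-1] + rr[i-1]`.
#' @slot stateWindows data.frame with columns `label` (`"asleep"`/`"awake"`),
#'   `start`, `end` (seconds on the cumulative axis); non-overlapping and
#'   contained in `[0, t[last] + rr[last]]`.
#' @slot segment character(1), which portion of the recording this object
#'   represents: `"h24"` (full), `"asleep6"` or `"awake6"`.
#'
#' @seealso [readRR()], [extractSegment()], [toMeasure()]
#' @export
setClass("Tachogram",
  representation(
    subjectId = "character",
    condition = "character",
    nyha = "character",
    rr = "numeric",
    t = "numeric",
    stateWindows = "data.frame",
    segment = "character"
  ),
  prototype(
    subjectId = "unknown",
    condition = "unknown",
    nyha = "none",
    stateWindows = data.frame(
      label = character(), start = numeric(), end = numeric(),
      stringsAsFactors = FALSE
    ),
    segment = "h24"
  )
)

setValidity("Tachogram", function(object) {
  msgs <- character()
  if (length(object@rr) > 0 && !all(is.finite(object@rr) & object@rr > 0)) {
    msgs <- c(msgs, "all RR intervals must be finite and > 0")
  }
  if (length(object@t) != length(object@rr)) {
    msgs <- c(msgs, "t and rr must have equal length")
  }
  if (length(object@t) > 1 && any(diff(object@t) <= 0)) {
    msgs <- c(msgs, "t must be strictly increasing")
  }
  if (!object@condition %in% CONDITION_LEVELS) {
    msgs <- c(msgs, sprintf("condition must be one of: %s",
                            paste(CONDITION_LEVELS, collapse = ", ")))
  }
  if (!object@nyha %in% NYHA_LEVELS) {
    msgs <- c(msgs, sprintf("nyha must be one of: %s",
                            paste(NYHA_LEVELS, collapse = ", ")))
  }
  if (!object@segment %in% SEGMENT_LEVELS) {
    msgs <- c(msgs, sprintf("segment must be one of: %s",
                            paste(SEGMENT_LEVELS, collapse = ", ")))
  }
  sw <- object@stateWindows
  if (nrow(sw) > 0) {
    if (!all(c("label", "start", "end") %in% names(sw))) {
      msgs <- c(msgs, "stateWindows needs columns label, start, end")
    } else {
      if (!all(sw$label %in% c("asleep", "awake"))) {
        msgs <- c(msgs, "state window labels must be 'asleep' or 'awake'")
      }
      if (any(sw$end <= sw$start)) {
        msgs <- c(msgs, "state windows must have end > start")
      }
      tot <- if (length(object@t)) {
        object@t[length(object@t)] + object@rr[length(object@rr)]
      } else 0
      if (any(sw$start < 0) || any(sw$end > tot + 1e-9)) {
        msgs <- c(msgs, "state windows must lie within the recording span")
      }
      o <- order(sw$start)
      if (nrow(sw) > 1 && any(sw$start[o][-1] < sw$end[o][-nrow(sw)] - 1e-9)) {
        msgs <- c(msgs, "state windows must not overlap")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' BoxMeasure: a normalised singular measure on a base-b support
#'
#' The RR series normalised to total mass one on a support of exactly
#' `base^m` points, so that it partitions exactly into `base^n` boxes at
#' every level `n <= m`.
#'
#' @slot p numeric of length `base^m`, non-negative, summing to 1.
#' @slot base integer(1), branching base b >= 2 (2 for dyadic).
#' @slot m integer(1), number of partition levels.
#' @slot sourceId character(1), identifier of the originating series.
#' @export
setClass("BoxMeasure",
  representation(p = "numeric", base = "integer", m = "integer",
                 sourceId = "character"),
  prototype(base = 2L, m = 0L, sourceId = "measure")
)

setValidity("BoxMeasure", function(object) {
  msgs <- character()
  if (length(object@base) != 1 || object@base < 2) {
    msgs <- c(msgs, "base must be a single integer >= 2")
  }
  if (length(object@p) != object@base^object@m) {
    msgs <- c(msgs, "length(p) must equal base^m")
  }
  if (any(object@p < 0) || any(!is.finite(object@p))) {
    msgs <- c(msgs, "p must be finite and non-negative")
  }
  if (abs(sum(object@p) - 1) > 1e-12) {
    msgs <- c(msgs, "p must sum to 1 within 1e-12")
  }
  if (length(msgs)) msgs else TRUE
})

#' MultifractalSpectrum: the (q, alpha, f) points with fit diagnostics
#'
#' One row per q value of the estimation grid: the singularity strength
#' `alpha(q)` and dimension `f(q)` obtained as least-squares slopes of the
#' scaling sums versus `log L`, with the R-squared and slope standard error
#' of each regression.
#'
#' @slot points data.frame with columns `q`, `alpha`, `f`, `r2_alpha`,
#'   `r2_f`, `stderr_alpha`, `stderr_f`, ordered by increasing q.
#' @slot base integer(1), partition base of the measure.
#' @slot levels integer, partition levels n used in the fits.
#' @slot sourceId character(1).
#' @export
setClass("MultifractalSpectrum",
  representation(points = "data.frame", base = "integer",
                 levels = "integer", sourceId = "character"),
  prototype(base = 2L, levels = integer(), sourceId = "spectrum")
)

setValidity("MultifractalSpectrum", function(object) {
  msgs <- character()
  need <- c("q", "alpha", "f", "r2_alpha", "r2_f", "stderr_alpha", "stderr_f")
  if (!all(need %in% names(object@points))) {
    msgs <- c(msgs, sprintf("points needs columns: %s",
                            paste(need, collapse = ", ")))
  } else {
    if (is.unsorted(object@points$q, strictly = TRUE)) {
      msgs <- c(msgs, "points must be strictly ordered by q")
    }
    if (!all(is.finite(object@points$alpha)) ||
        !all(is.finite(object@points$f))) {
      msgs <- c(msgs, "alpha and f must be finite")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ShapeMetrics: per-subject scalar shape statistics of one spectrum
#'
#' Width and asymmetry of the singularity spectrum plus the curvature
#' maximum: `deltaAlpha = alphaMax - alphaMin` measures the degree of
#' multifractality; `r = deltaRight / deltaLeft` quantifies the skew of the
#' spectrum about its maximum at `alpha0`; `kMax` is the maximum of the
#' curvature profile near q = 0 (infinite for a degenerate, point-like
#' spectrum).
#'
#' @slot alphaMin numeric(1), alpha at the right end of the q grid (q max).
#' @slot alphaMax numeric(1), alpha at the left end of the q grid (q min).
#' @slot alpha0 numeric(1), alpha at the f-maximising grid point.
#' @slot deltaAlpha numeric(1), spectrum width.
#' @slot deltaRight,deltaLeft numeric(1), right/left half-widths about alpha0.
#' @slot r numeric(1), symmetry ratio deltaRight/deltaLeft (Inf if the
#'   left half-width is numerically zero).
#' @slot skewLabel character(1), one of `"sharply_left"`, `"left"`,
#'   `"symmetric"`, `"right"`, `"sharply_right"`.
#' @slot kMax numeric(1), maximum curvature of the profile.
#' @slot kArgmaxQ numeric(1), q at which the curvature peaks.
#' @slot degenerate logical(1), TRUE for a near-monofractal spectrum.
#' @export
setClass("ShapeMetrics",
  representation(
    alphaMin = "numeric", alphaMax = "numeric", alpha0 = "numeric",
    deltaAlpha = "numeric", deltaRight = "numeric", deltaLeft = "numeric",
    r = "numeric", skewLabel = "character", kMax = "numeric",
    kArgmaxQ = "numeric", degenerate = "logical"
  ),
  prototype(kMax = NA_real_, kArgmaxQ = NA_real_, degenerate = FALSE,
            skewLabel = "symmetric")
)

#' CurvatureProfile: the pointwise curvature of one spectrum
#'
#' Curvature `K = |f''| / (1 + f'^2)^(3/2)` of the (alpha, f) curve,
#' estimated by finite differences at the interior grid points: a spectrum
#' with `n` points yields `n - 1` first-derivative and `n - 2` curvature
#' values (199 under the default 201-point grid). The centre entry
#' corresponds to q = 0.
#'
#' @slot k numeric, curvature values (non-negative).
#' @slot q numeric, q values aligned with `k` (interior grid points).
#' @slot centerIndex integer(1), 1-based index with `q[centerIndex]` closest
#'   to 0 (100 under defaults).
#' @slot degenerate logical(1), TRUE when the spectrum was too narrow to
#'   differentiate (near-monofractal); `k` is then empty.
#' @slot sourceId character(1).
#' @export
setClass("CurvatureProfile",
  representation(k = "numeric", q = "numeric", centerIndex = "integer",
                 degenerate = "logical", sourceId = "character"),
  prototype(degenerate = FALSE, sourceId = "profile")
)

setValidity("CurvatureProfile", function(object) {
  msgs <- character()
  if (length(object@k) != length(object@q)) {
    msgs <- c(msgs, "k and q must have equal length")
  }
  if (!object@degenerate && length(object@k) && any(object@k < -1e-12)) {
    msgs <- c(msgs, "curvature must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' SubjectRecord: one analysed subject-segment
#'
#' Bundles the labels of one analysed series (subject, condition, NYHA
#' class, segment) with its `ShapeMetrics` and `CurvatureProfile`.
#'
#' @slot subjectId character(1).
#' @slot condition character(1).
#' @slot nyha character(1).
#' @slot segment character(1), `"h24"`, `"asleep6"` or `"awake6"`.
#' @slot metrics a [ShapeMetrics-class] object.
#' @slot profile a [CurvatureProfile-class] object.
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", condition = "character",
                 nyha = "character", segment = "character",
                 metrics = "ShapeMetrics", profile = "CurvatureProfile"),
  prototype(condition = "unknown", nyha = "none", segment = "h24")
)

#' GroupSummary: cross-subject aggregates of shape statistics
#'
#' Skew counts and per-class mean symmetry ratios, the pointwise mean
#' curvature profile with its dispersion, and the maximum value of the
#' average curvature (mvac) with its location on the q axis.
#'
#' @slot groupLabel character(1).
#' @slot n integer(1), number of subjects.
#' @slot rightCount,leftCount,symmetricCount integer(1), subjects with
#'   r > 1, r < 1 and r == 1.
#' @slot rMeanRight,rSdRight,rMeanLeft,rSdLeft numeric(1), mean and sd of r
#'   within each skew class (NA when the class is empty).
#' @slot meanProfile numeric, pointwise mean curvature across subjects.
#' @slot profileSd,profileSem numeric, pointwise dispersion.
#' @slot q numeric, q axis of the profiles.
#' @slot mvac numeric(1), maximum of `meanProfile`.
#' @slot mvacErr numeric(1), dispersion at the argmax (sem by default).
#' @slot mvacErrType character(1), `"sem"` or `"sd"`.
#' @slot mvacArgmaxQ numeric(1).
#' @slot kMaxValues numeric, per-subject curvature maxima (inputs to group
#'   significance tests).
#' @export
setClass("GroupSummary",
  representation(
    groupLabel = "character", n = "integer",
    rightCount = "integer", leftCount = "integer", symmetricCount = "integer",
    rMeanRight = "numeric", rSdRight = "numeric",
    rMeanLeft = "numeric", rSdLeft = "numeric",
    meanProfile = "numeric", profileSd = "numeric", profileSem = "numeric",
    q = "numeric", mvac = "numeric", mvacErr = "numeric",
    mvacErrType = "character", mvacArgmaxQ = "numeric",
    kMaxValues = "numeric"
  ),
  prototype(mvacErrType = "sem")
)

## ---- accessors ----

#' @describeIn Tachogram-class RR intervals in seconds
#' @param object,x an object of the documented class
#' @export
setGeneric("rrIntervals", function(object) standardGeneric("rrIntervals"))
#' @export
setMethod("rrIntervals", "Tachogram", function(object) object@rr)

#' @describeIn Tachogram-class cumulative time axis (seconds)
#' @export
setGeneric("cumulativeTime", function(object) standardGeneric("cumulativeTime"))
#' @export
setMethod("cumulativeTime", "Tachogram", function(object) object@t)

#' @describeIn Tachogram-class subject identifier
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @export
setMethod("subjectId", "Tachogram", function(object) object@subjectId)
#' @export
setMethod("subjectId", "SubjectRecord", function(object) object@subjectId)

#' @describeIn Tachogram-class health condition label
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
#' @export
setMethod("condition", "Tachogram", function(object) object@condition)
#' @export
setMethod("condition", "SubjectRecord", function(object) object@condition)

#' @describeIn Tachogram-class NYHA class label
#' @export
setGeneric("nyhaClass", function(object) standardGeneric("nyhaClass"))
#' @export
setMethod("nyhaClass", "Tachogram", function(object) object@nyha)
#' @export
setMethod("nyhaClass", "SubjectRecord", function(object) object@nyha)

#' @describeIn Tachogram-class behavioural-state windows
#' @export
setGeneric("stateWindows", function(object) standardGeneric("stateWindows"))
#' @export
setMethod("stateWindows", "Tachogram", function(object) object@stateWindows)

#' @describeIn BoxMeasure-class the normalised box masses
#' @export
setGeneric("boxMasses", function(object) standardGeneric("boxMasses"))
#' @export
setMethod("boxMasses", "BoxMeasure", function(object) object@p)

#' @describeIn BoxMeasure-class partition base b
#' @export
setGeneric("measureBase", function(object) standardGeneric("measureBase"))
#' @export
setMethod("measureBase", "BoxMeasure", function(object) object@base)
#' @export
setMethod("measureBase", "MultifractalSpectrum", function(object) object@base)

#' @describeIn BoxMeasure-class number of partition levels m
#' @export
setGeneric("measureLevels", function(object) standardGeneric("measureLevels"))
#' @export
setMethod("measureLevels", "BoxMeasure", function(object) object@m)

#' @describeIn MultifractalSpectrum-class the per-q table of spectrum points
#' @export
setGeneric("spectrumPoints", function(object) standardGeneric("spectrumPoints"))
#' @export
setMethod("spectrumPoints", "MultifractalSpectrum",
          function(object) object@points)

#' @describeIn MultifractalSpectrum-class q values of the grid
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))
#' @export
setMethod("qValues", "MultifractalSpectrum", function(object) object@points$q)
#' @export
setMethod("qValues", "CurvatureProfile", function(object) object@q)

#' @describeIn MultifractalSpectrum-class singularity strengths alpha(q)
#' @export
setGeneric("alphaValues", function(object) standardGeneric("alphaValues"))
#' @export
setMethod("alphaValues", "MultifractalSpectrum",
          function(object) object@points$alpha)

#' @describeIn MultifractalSpectrum-class dimensions f(q)
#' @export
setGeneric("fValues", function(object) standardGeneric("fValues"))
#' @export
setMethod("fValues", "MultifractalSpectrum", function(object) object@points$f)

#' @describeIn CurvatureProfile-class curvature values
#' @export
setGeneric("curvatureValues", function(object) standardGeneric("curvatureValues"))
#' @export
setMethod("curvatureValues", "CurvatureProfile", function(object) object@k)

#' @describeIn CurvatureProfile-class index of the q = 0 entry (1-based)
#' @export
setGeneric("centerIndex", function(object) standardGeneric("centerIndex"))
#' @export
setMethod("centerIndex", "CurvatureProfile", function(object) object@centerIndex)

#' @describeIn SubjectRecord-class the subject's shape metrics
#' @export
setGeneric("shapeMetrics", function(object) standardGeneric("shapeMetrics"))
#' @export
setMethod("shapeMetrics", "SubjectRecord", function(object) object@metrics)

#' @describeIn SubjectRecord-class the subject's curvature profile
#' @export
setGeneric("curvatureProfileOf",
           function(object) standardGeneric("curvatureProfileOf"))
#' @export
setMethod("curvatureProfileOf", "SubjectRecord", function(object) object@profile)

#' @describeIn GroupSummary-class maximum value of the average curvature
#' @export
setGeneric("mvac", function(object) standardGeneric("mvac"))
#' @export
setMethod("mvac", "GroupSummary", function(object) object@mvac)

## ---- coercions ----

#' @export
#' @method as.data.frame ShapeMetrics
as.data.frame.ShapeMetrics <- function(x, ...) {
  data.frame(
    alpha_min = x@alphaMin, alpha_max = x@alphaMax, alpha_0 = x@alpha0,
    delta_alpha = x@deltaAlpha, delta_right = x@deltaRight,
    delta_left = x@deltaLeft, r = x@r, skew_label = x@skewLabel,
    k_max = x@kMax, k_argmax_q = x@kArgmaxQ, degenerate = x@degenerate,
    stringsAsFactors = FALSE
  )
}

setMethod("as.data.frame", "ShapeMetrics",
          function(x, ...) as.data.frame.ShapeMetrics(x, ...))

## ---- show methods ----

setMethod("show", "Tachogram", function(object) {
  n <- length(object@rr)
  span <- if (n) object@t[n] + object@rr[n] else 0
  cat(sprintf("Tachogram '%s' (%s, NYHA %s, segment %s)\n",
              object@subjectId, object@condition, object@nyha,
              object@segment))
  cat(sprintf("  %d beats spanning %.1f s (mean RR %.3f s)\n",
              n, span, if (n) mean(object@rr) else NA_real_))
  if (nrow(object@stateWindows)) {
    cat(sprintf("  %d state window(s): %s\n", nrow(object@stateWindows),
                paste(sprintf("%s[%.0f,%.0f]", object@stateWindows$label,
                              object@stateWindows$start,
                              object@stateWindows$end), collapse = " ")))
  }
})

setMethod("show", "BoxMeasure", function(object) {
  cat(sprintf("BoxMeasure '%s': %d = %d^%d boxes, total mass %.6f\n",
              object@sourceId, length(object@p), object@base, object@m,
              sum(object@p)))
})

setMethod("show", "MultifractalSpectrum", function(object) {
  p <- object@points
  cat(sprintf("MultifractalSpectrum '%s': %d points, q in [%g, %g]\n",
              object@sourceId, nrow(p), min(p$q), max(p$q)))
  cat(sprintf("  alpha in [%.4f, %.4f], max f = %.4f, levels n = %s (base %d)\n",
              min(p$alpha), max(p$alpha), max(p$f),
              paste(range(object@levels), collapse = ".."), object@base))
})

setMethod("show", "ShapeMetrics", function(object) {
  cat(sprintf(
    "ShapeMetrics: delta_alpha %.4f (right %.4f, left %.4f), r %.3f (%s)\n",
    object@deltaAlpha, object@deltaRight, object@deltaLeft, object@r,
    object@skewLabel))
  cat(sprintf("  k_max %.4g at q = %.2f%s\n", object@kMax, object@kArgmaxQ,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "CurvatureProfile", function(object) {
  if (object@degenerate) {
    cat("CurvatureProfile: degenerate (near-monofractal spectrum)\n")
  } else {
    cat(sprintf(
      "CurvatureProfile '%s': %d points, centre (q=0) at index %d, max K %.4g\n",
      object@sourceId, length(object@k), object@centerIndex, max(object@k)))
  }
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord '%s' (%s, NYHA %s, %s): r %.3f, k_max %.4g\n",
              object@subjectId, object@condition, object@nyha, object@segment,
              object@metrics@r, object@metrics@kMax))
})

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("GroupSummary '%s': n = %d (right %d / left %d / symmetric %d)\n",
              object@groupLabel, object@n, object@rightCount,
              object@leftCount, object@symmetricCount))
  cat(sprintf("  mvac %.4g +/- %.3g (%s) at q = %.2f\n",
              object@mvac, object@mvacErr, object@mvacErrType,
              object@mvacArgmaxQ))
})
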