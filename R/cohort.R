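## Surrogate RR cohorts with known multifractal structure, and the
## per-subject analysis pipeline that turns a tachogram into a
## SubjectRecord.

# Base weight set of the healthy-like surrogate: a broad, right-skewed
# base-3 cascade (analytic delta_alpha ~ 0.73, r ~ 1.4, vertex K ~ 10).
HEALTHY_WEIGHTS <- c(0.45, 0.35, 0.20)
# Fraction of the distance toward uniform weights covered at severity 1.
SEVERITY_PULL <- 0.85
# Per-subject log-normal weight jitter: sd 0.1 at severity 0 shrinking to
# 0.05 at severity 1 (near-uniform weights are more sensitive).
JITTER_SD <- function(severity) 0.1 - 0.05 * severity

#' NYHA class to surrogate severity mapping
#'
#' A monotone map used when simulating CHF cohorts stratified by NYHA
#' class: more severe classes get narrower, spikier spectra.
#'
#' @return named numeric vector over classes I, II, III, III-IV, IV.
#' @export
nyhaSeverity <- function() {
  c("I" = 0.25, "II" = 0.5, "III" = 0.7, "III-IV" = 0.85, "IV" = 0.95)
}

# Cascade weights of a surrogate subject (before jitter).
.profileWeights <- function(profile, severity) {
  if (profile == "healthy_like") severity <- 0
  lam <- SEVERITY_PULL * severity
  (1 - lam) * HEALTHY_WEIGHTS + lam * rep(1 / 3, 3)
}

#' Generate one RR-like surrogate tachogram
#'
#' Builds a randomised base-3 multiplicative cascade and rescales it to
#' RR-like values (mean 0.8 s). `healthy_like` uses a broad, asymmetric
#' weight set whose analytic spectrum is right-skewed with low vertex
#' curvature; `chf_like` pulls the weights toward uniform by
#' `0.85 * severity`, narrowing the spectrum and inflating the vertex
#' curvature (severity 0 reproduces the healthy-like parameterisation
#' exactly). Each subject's weights are additionally jittered
#' (log-normal, seeded) so cohorts have realistic between-subject spread,
#' and synthetic asleep/awake windows covering the two halves of the
#' recording are attached. The rescaling is a pure multiplication, so the
#' normalised measure -- and hence the spectrum -- is exactly that of the
#' underlying cascade.
#'
#' @param profile `"healthy_like"` or `"chf_like"`.
#' @param severity numeric in [0, 1]; ignored for `healthy_like`.
#' @param levels cascade depth m (series length `3^m`; default 8).
#' @param seed integer seed; the construction is bit-reproducible.
#' @param subjectId,nyha labels attached to the tachogram.
#' @return A [Tachogram-class] with condition set from the profile.
#' @export
makeRRSurrogate <- function(profile = c("healthy_like", "chf_like"),
                            severity = 0.7, levels = 8, seed = 1,
                            subjectId = NULL, nyha = "none") {
  profile <- match.arg(profile)
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  sev <- if (profile == "healthy_like") 0 else severity
  baseW <- .profileWeights(profile, severity)
  sig <- JITTER_SD(sev)
  rr <- withLocalSeed(seed, {
    w <- baseW * exp(stats::rnorm(3, 0, sig))
    w <- w / sum(w)
    meas <- makeCascade(w, levels = levels, randomize = TRUE)
    p <- boxMasses(meas)
    p / mean(p) * 0.8                       # pure rescaling: mean RR 0.8 s
  })
  total <- sum(rr)
  if (is.null(subjectId)) {
    subjectId <- sprintf("%s_s%d", sub("_like$", "", profile), seed)
  }
  newTachogram(
    rr, subjectId = subjectId,
    condition = if (profile == "healthy_like") "healthy" else "chf",
    nyha = nyha,
    stateWindows = data.frame(
      label = c("asleep", "awake"),
      start = c(0, total / 2), end = c(total / 2, total),
      stringsAsFactors = FALSE)
  )
}

#' Analyse one tachogram end to end
#'
#' Normalises the series into a box measure, estimates the multifractal
#' spectrum, reduces it to shape metrics and the curvature profile, and
#' bundles everything into a [SubjectRecord-class].
#'
#' @param tg a [Tachogram-class].
#' @param base partition base (2 for dyadic analysis of real recordings;
#'   3 recovers surrogate cascades exactly).
#' @param qgrid moment-order grid (default [makeQGrid()]).
#' @param levels partition levels for the scaling fits (default all
#'   informative levels).
#' @param mode derivative mode for the curvature, see
#'   [spectrumDerivatives()].
#' @param windowHalfwidthQ window for the curvature maximum.
#' @return A [SubjectRecord-class].
#' @export
analyzeTachogram <- function(tg, base = 2L, qgrid = makeQGrid(),
                             levels = NULL,
                             mode = c("paper_uniform", "nonuniform"),
                             windowHalfwidthQ = 10) {
  mode <- match.arg(mode)
  meas <- toMeasure(tg, base = base)
  sp <- computeSpectrum(meas, qgrid = qgrid, levels = levels)
  metrics <- computeShapeMetrics(sp, mode = mode,
                                 windowHalfwidthQ = windowHalfwidthQ)
  prof <- curvatureProfile(sp, mode = mode)
  newSubjectRecord(metrics, prof, subjectId = tg@subjectId,
                   condition = tg@condition, nyha = tg@nyha,
                   segment = tg@segment)
}

#' Simulate a labelled surrogate cohort in memory
#'
#' @param n subjects per call.
#' @param profile,severity,levels surrogate parameters, see
#'   [makeRRSurrogate()].
#' @param seed integer; subject i uses a seed derived deterministically
#'   from it.
#' @param nyha optional vector of NYHA labels (recycled).
#' @return list of [Tachogram-class] objects.
#' @export
simulateCohort <- function(n, profile = c("healthy_like", "chf_like"),
                           severity = 0.7, levels = 8, seed = 1,
                           nyha = "none") {
  profile <- match.arg(profile)
  nyha <- rep_len(nyha, n)
  lapply(seq_len(n), function(i) {
    makeRRSurrogate(profile, severity = severity, levels = levels,
                    seed = (seed + 104729L * i) %% .Machine$integer.max,
                    subjectId = sprintf("%s_%03d", sub("_like$", "", profile), i),
                    nyha = nyha[i])
  })
}

#' Write a surrogate cohort to disk
#'
#' Writes one RR file and sidecar per subject plus a manifest CSV
#' (`path,subject_id,condition,nyha,segment`) suitable for the `group`
#' command.
#'
#' @inheritParams simulateCohort
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(dir, n, profile = c("healthy_like", "chf_like"),
                        severity = 0.7, levels = 8, seed = 1,
                        nyha = "none") {
  profile <- match.arg(profile)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tgs <- simulateCohort(n, profile, severity, levels, seed, nyha)
  rows <- lapply(tgs, function(tg) {
    f <- file.path(dir, paste0(tg@subjectId, ".rr"))
    writeRR(tg, f, sidecar = file.path(dir, paste0(tg@subjectId, ".meta")))
    # manifest paths are relative to the manifest itself, so cohorts are
    # relocatable and byte-identical across output directories
    data.frame(path = basename(f), subject_id = tg@subjectId,
               condition = tg@condition,
               nyha = tg@nyha, segment = tg@segment, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  invisible(manifest)
}
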