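## Reading, validating and segmenting RR tachograms, and turning them into
## normalised singular measures on a base-b support.

#' Construct a Tachogram from RR intervals
#'
#' @param rr numeric, RR intervals in seconds (positive, finite).
#' @param subjectId,condition,nyha subject metadata.
#' @param stateWindows data.frame(label, start, end) of asleep/awake
#'   windows in seconds on the cumulative-time axis, or NULL.
#' @param segment which portion of a recording this is: `"h24"`,
#'   `"asleep6"` or `"awake6"`.
#' @return A [Tachogram-class].
#' @export
newTachogram <- function(rr, subjectId = "unknown", condition = "unknown",
                         nyha = "none", stateWindows = NULL,
                         segment = "h24") {
  rr <- as.numeric(rr)
  if (length(rr) == 0) stop("no samples")
  t <- c(0, cumsum(rr[-length(rr)]))
  if (is.null(stateWindows)) {
    stateWindows <- data.frame(label = character(), start = numeric(),
                               end = numeric(), stringsAsFactors = FALSE)
  }
  new("Tachogram", subjectId = subjectId, condition = condition,
      nyha = nyha, rr = rr, t = t, stateWindows = stateWindows,
      segment = segment)
}

#' Read an RR tachogram from a plain-text file
#'
#' Accepts one value per line (the RR interval) or two whitespace-separated
#' values (cumulative time, RR interval); lines starting with `#` and blank
#' lines are skipped. Values are converted to seconds: with
#' `units = "auto"` the series is taken to be in milliseconds when the
#' median raw value exceeds 10 (a physiological RR interval never reaches
#' 10 s).
#'
#' A sidecar key-value file can supply metadata: keys `subject_id`,
#' `condition`, `nyha`, and state windows as `asleep=start:end` /
#' `awake=start:end` lines (seconds; repeatable).
#'
#' @param path RR file path.
#' @param units `"auto"`, `"s"` or `"ms"`.
#' @param sidecar optional path of the metadata file (see [readSidecar()]).
#' @return A [Tachogram-class] with `rr` in seconds.
#' @export
readRR <- function(path, units = c("auto", "s", "ms"), sidecar = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", lines)
  keep <- grepl("\\S", raw)
  if (!any(keep)) stop("no samples")
  lineNo <- which(keep)
  toks <- strsplit(trimws(raw[keep]), "[,[:space:]]+")
  nf <- lengths(toks)
  if (any(nf > 2)) {
    stop("lines with more than 2 fields: ",
         paste(lineNo[nf > 2], collapse = ", "))
  }
  rr <- vapply(toks, function(x) suppressWarnings(as.numeric(x[length(x)])),
               numeric(1))
  if (any(is.na(rr))) {
    stop("non-numeric RR values on lines: ",
         paste(lineNo[is.na(rr)], collapse = ", "))
  }
  bad <- !is.finite(rr) | rr <= 0
  if (any(bad)) {
    stop("non-positive RR values on lines: ",
         paste(lineNo[bad], collapse = ", "))
  }
  if (units == "auto") units <- if (stats::median(rr) > 10) "ms" else "s"
  if (units == "ms") rr <- rr / 1000
  meta <- if (!is.null(sidecar)) readSidecar(sidecar) else NULL
  newTachogram(
    rr,
    subjectId = if (!is.null(meta)) meta$subjectId else
      sub("\\.[^.]*$", "", basename(path)),
    condition = if (!is.null(meta)) meta$condition else "unknown",
    nyha = if (!is.null(meta)) meta$nyha else "none",
    stateWindows = if (!is.null(meta)) meta$stateWindows else NULL
  )
}

#' Read a tachogram sidecar metadata file
#'
#' Plain `key=value` lines (`#` comments allowed): `subject_id`,
#' `condition` (healthy/chf/unknown), `nyha` (none/I/II/III/III-IV/IV), and
#' repeatable state-window lines `asleep=start:end`, `awake=start:end`
#' with times in seconds.
#'
#' @param path sidecar file path.
#' @return list with elements `subjectId`, `condition`, `nyha`,
#'   `stateWindows`.
#' @export
readSidecar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  meta <- list(subjectId = "unknown", condition = "unknown", nyha = "none")
  win <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k == "subject_id") meta$subjectId <- v
    else if (k == "condition") meta$condition <- v
    else if (k == "nyha") meta$nyha <- v
    else if (k %in% c("asleep", "awake")) {
      se <- as.numeric(strsplit(v, ":", fixed = TRUE)[[1]])
      if (length(se) != 2 || any(is.na(se))) {
        stop("bad state window '", v, "' (expected start:end seconds)")
      }
      win[[length(win) + 1]] <- data.frame(label = k, start = se[1],
                                           end = se[2],
                                           stringsAsFactors = FALSE)
    } else stop("unknown sidecar key: ", k)
  }
  meta$stateWindows <- if (length(win)) do.call(rbind, win) else
    data.frame(label = character(), start = numeric(), end = numeric(),
               stringsAsFactors = FALSE)
  meta
}

#' Write a tachogram as a plain-text RR file (plus optional sidecar)
#'
#' @param tg a [Tachogram-class].
#' @param path output RR file (one interval per line, seconds).
#' @param sidecar optional path for the metadata sidecar.
#' @return `path`, invisibly.
#' @export
writeRR <- function(tg, path, sidecar = NULL) {
  stopifnot(is(tg, "Tachogram"))
  writeLines(formatC(tg@rr, format = "g", digits = 10), path)
  if (!is.null(sidecar)) {
    sw <- tg@stateWindows
    lines <- c(
      paste0("subject_id=", tg@subjectId),
      paste0("condition=", tg@condition),
      paste0("nyha=", tg@nyha),
      if (nrow(sw)) sprintf("%s=%.6f:%.6f", sw$label, sw$start, sw$end)
    )
    writeLines(lines, sidecar)
  }
  invisible(path)
}

#' Extract a fixed-duration behavioural-state segment
#'
#' Returns the sub-tachogram of the first contiguous run of RR intervals
#' whose cumulative duration covers `durationS` inside the first state
#' window of the requested label that is long enough; windows are tried in
#' temporal order. Subject metadata is preserved and the segment label is
#' set. Recordings in which no continuous period of the requested length
#' exists are rejected, mirroring the exclusion of subjects without 6
#' continuous hours asleep or awake.
#'
#' @param tg a [Tachogram-class] with state windows.
#' @param label `"asleep"` or `"awake"`.
#' @param durationS segment duration in seconds (default 21600 = 6 h).
#' @return A [Tachogram-class] whose summed RR lies in
#'   `[durationS, durationS + max(rr))`.
#' @export
extractSegment <- function(tg, label = c("asleep", "awake"),
                           durationS = 21600) {
  stopifnot(is(tg, "Tachogram"))
  label <- match.arg(label)
  if (durationS <= 0) stop("durationS must be positive")
  sw <- tg@stateWindows
  sw <- sw[sw$label == label, , drop = FALSE]
  sw <- sw[order(sw$start), , drop = FALSE]
  ends <- tg@t + tg@rr                      # interval i spans [t[i], ends[i]]
  for (j in seq_len(nrow(sw))) {
    if (sw$end[j] - sw$start[j] < durationS) next
    inWin <- which(tg@t >= sw$start[j] - 1e-9 & ends <= sw$end[j] + 1e-9)
    if (length(inWin) == 0) next
    cum <- cumsum(tg@rr[inWin])
    k <- which(cum >= durationS)[1]
    if (is.na(k)) next
    idx <- inWin[seq_len(k)]
    return(newTachogram(tg@rr[idx], subjectId = tg@subjectId,
                        condition = tg@condition, nyha = tg@nyha,
                        segment = if (label == "asleep") "asleep6" else "awake6"))
  }
  stop("no continuous period of ", durationS, " s labelled '", label, "'")
}

#' Optional beat-level artifact filter
#'
#' Drops RR intervals outside `rrRange` seconds or differing from their
#' predecessor by more than `maxJump` (relative). Off by default in the
#' pipeline: the reference analysis applied no ectopy filtering.
#'
#' @param tg a [Tachogram-class].
#' @param rrRange length-2 numeric, plausible RR range in seconds.
#' @param maxJump maximum allowed relative jump between successive beats.
#' @return A filtered [Tachogram-class] (time axis rebuilt).
#' @export
artifactFilter <- function(tg, rrRange = c(0.2, 4.0), maxJump = 0.2) {
  stopifnot(is(tg, "Tachogram"))
  rr <- tg@rr
  keep <- rr >= rrRange[1] & rr <= rrRange[2]
  if (length(rr) > 1) {
    jump <- c(FALSE, abs(diff(rr)) / rr[-length(rr)] > maxJump)
    keep <- keep & !jump
  }
  if (!any(keep)) stop("artifact filter removed every beat")
  newTachogram(rr[keep], subjectId = tg@subjectId, condition = tg@condition,
               nyha = tg@nyha, segment = tg@segment)
}

#' Normalise a tachogram into a singular box measure
#'
#' Truncates the series to its largest leading block of length `base^m`
#' (padding would inject artificial singularities) and divides by the block
#' sum, so the measure partitions exactly into `base^n` boxes at every
#' level. The result is invariant to rescaling all RR values by a positive
#' constant.
#'
#' @param tg a [Tachogram-class] with at least `base^3` samples (three
#'   partition levels).
#' @param base integer(1), partition base (default 2, dyadic).
#' @return A [BoxMeasure-class] of length `base^m`.
#' @export
toMeasure <- function(tg, base = 2L) {
  stopifnot(is(tg, "Tachogram"))
  base <- as.integer(base)
  if (base < 2) stop("base must be >= 2")
  nRR <- length(tg@rr)
  if (nRR < base^3) {
    stop("series too short: ", nRR, " samples, need at least base^3 = ",
         base^3)
  }
  m <- floor(log(nRR) / log(base) + 1e-9)
  nUse <- base^m
  p <- tg@rr[seq_len(nUse)]
  p <- p / sum(p)
  new("BoxMeasure", p = p, base = base, m = as.integer(m),
      sourceId = tg@subjectId)
}
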