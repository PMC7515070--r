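## Cross-subject aggregation: skew counts and mean symmetry ratios, mean
## curvature profiles with the maximum of the average curvature (mvac),
## Welch/permutation significance tests, NYHA stratification, and the
## three-criterion health assessment.

#' Bundle one analysed subject-segment into a record
#'
#' @param metrics a [ShapeMetrics-class].
#' @param profile a [CurvatureProfile-class].
#' @param subjectId,condition,nyha,segment labels.
#' @return A [SubjectRecord-class].
#' @export
newSubjectRecord <- function(metrics, profile, subjectId = "unknown",
                             condition = "unknown", nyha = "none",
                             segment = "h24") {
  new("SubjectRecord", subjectId = subjectId, condition = condition,
      nyha = nyha, segment = segment, metrics = metrics, profile = profile)
}

# Per-subject symmetry ratios from records or a bare numeric vector.
.rValues <- function(x) {
  if (is.numeric(x)) return(x)
  vapply(x, function(rec) rec@metrics@r, numeric(1))
}

#' Skew counts and per-class mean symmetry ratios
#'
#' Subjects with r > 1 count as right-skewed, r < 1 as left-skewed and
#' r == 1 as symmetric (a measure-zero class in practice); within the
#' right and left classes the mean and sd of r are reported.
#'
#' @param x list of [SubjectRecord-class] objects, or a numeric vector of
#'   per-subject symmetry ratios.
#' @return list with `n`, `rightCount`, `leftCount`, `symmetricCount`,
#'   `rightPct`, `rMeanRight`, `rSdRight`, `rMeanLeft`, `rSdLeft`.
#' @examples
#' summarizeSymmetry(c(2, 3, 0.5))  # 2 right (mean 2.5), 1 left (0.5)
#' @export
summarizeSymmetry <- function(x) {
  r <- .rValues(x)
  if (length(r) < 1) stop("need at least one subject")
  right <- r[r > 1]
  left <- r[r < 1]
  list(
    n = length(r),
    rightCount = sum(r > 1),
    leftCount = sum(r < 1),
    symmetricCount = sum(r == 1),
    rightPct = 100 * sum(r > 1) / length(r),
    rMeanRight = if (length(right)) mean(right) else NA_real_,
    rSdRight = if (length(right) > 1) stats::sd(right) else NA_real_,
    rMeanLeft = if (length(left)) mean(left) else NA_real_,
    rSdLeft = if (length(left) > 1) stats::sd(left) else NA_real_
  )
}

#' Average curvature profile of a group
#'
#' Pointwise mean of the subjects' curvature profiles (which must share
#' length and q alignment), with pointwise sd and sem, and the maximum
#' value of the average curvature (mvac) read off the mean profile.
#' The dispersion attached to mvac is the pointwise sem at the argmax by
#' default (`errType = "sd"` switches to the sd); the error-bar semantics
#' are recorded in the result.
#'
#' @param records list of [SubjectRecord-class] objects.
#' @param groupLabel character(1) label for the summary.
#' @param errType `"sem"` (default) or `"sd"`.
#' @return A [GroupSummary-class].
#' @export
averageProfile <- function(records, groupLabel = "group", errType = c("sem", "sd")) {
  errType <- match.arg(errType)
  stopifnot(length(records) > 0)
  profs <- lapply(records, function(rec) rec@profile)
  if (any(vapply(profs, function(p) p@degenerate, logical(1)))) {
    stop("cannot average degenerate curvature profiles")
  }
  lens <- vapply(profs, function(p) length(p@k), integer(1))
  if (length(unique(lens)) != 1) {
    stop("profiles have mixed lengths: ", paste(unique(lens), collapse = ", "))
  }
  qs <- vapply(profs, function(p) p@q, numeric(lens[1]))
  if (max(abs(qs - qs[, 1])) > 1e-9) stop("profiles have mismatched q axes")
  K <- vapply(profs, function(p) p@k, numeric(lens[1]))   # points x subjects
  nSub <- length(profs)
  meanK <- rowMeans(K)
  sdK <- if (nSub > 1) apply(K, 1, stats::sd) else rep(0, lens[1])
  semK <- sdK / sqrt(nSub)
  iMax <- which(meanK == max(meanK))
  iMax <- iMax[which.min(abs(qs[iMax, 1]))]
  rsum <- summarizeSymmetry(records)
  kmaxes <- vapply(records, function(rec) rec@metrics@kMax, numeric(1))
  new("GroupSummary",
      groupLabel = groupLabel, n = as.integer(nSub),
      rightCount = as.integer(rsum$rightCount),
      leftCount = as.integer(rsum$leftCount),
      symmetricCount = as.integer(rsum$symmetricCount),
      rMeanRight = rsum$rMeanRight, rSdRight = rsum$rSdRight,
      rMeanLeft = rsum$rMeanLeft, rSdLeft = rsum$rSdLeft,
      meanProfile = meanK, profileSd = sdK, profileSem = semK,
      q = qs[, 1], mvac = max(meanK),
      mvacErr = if (errType == "sem") semK[iMax] else sdK[iMax],
      mvacErrType = errType, mvacArgmaxQ = qs[iMax, 1],
      kMaxValues = kmaxes)
}

#' Welch's two-sided unequal-variance t-test
#'
#' The group-comparison test of the pipeline, applied to per-subject
#' scalars (curvature maxima or symmetry ratios). When both groups have
#' zero variance the test is defined by its limit: p = 1 for equal means,
#' p = 0 otherwise.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param alphaLevel significance level (default 0.05).
#' @return list with `t`, `p`, `significant`, `alphaLevel`.
#' @export
welchTest <- function(a, b, alphaLevel = 0.05) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf, p = if (eq) 1 else 0,
                significant = !eq, alphaLevel = alphaLevel))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alphaLevel, alphaLevel = alphaLevel)
}

#' Two-sided permutation test on the difference of means
#'
#' A resampling alternative to [welchTest()] for small groups (e.g. sparse
#' NYHA classes): the group labels are permuted `nPerm` times and the
#' two-sided p-value is the fraction of permuted |mean difference| values
#' at least as large as the observed one (with the +1 continuity
#' correction).
#'
#' @inheritParams welchTest
#' @param nPerm number of label permutations (default 10000).
#' @param seed optional integer seed (local RNG state).
#' @return list with `stat` (observed mean difference), `p`,
#'   `significant`, `alphaLevel`.
#' @export
permutationTest <- function(a, b, alphaLevel = 0.05, nPerm = 10000,
                            seed = NULL) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a)
  run <- function() {
    exceed <- 0L
    for (i in seq_len(nPerm)) {
      idx <- sample.int(length(pool), na)
      d <- mean(pool[idx]) - mean(pool[-idx])
      if (abs(d) >= abs(obs) - 1e-15) exceed <- exceed + 1L
    }
    (exceed + 1) / (nPerm + 1)
  }
  p <- if (!is.null(seed)) withLocalSeed(seed, run()) else run()
  list(stat = obs, p = p, significant = p < alphaLevel,
       alphaLevel = alphaLevel)
}

#' Stratify records by NYHA class
#'
#' Groups the records into the NYHA classes present (ordering I, II, III,
#' III-IV, IV), summarises each with [averageProfile()], and runs the
#' group test on per-subject curvature maxima for each pair of adjacent
#' classes (I vs II, II vs III, ...). Empty classes are omitted with a
#' warning; classes with a single subject are summarised but excluded from
#' testing.
#'
#' @param records list of [SubjectRecord-class] objects with NYHA labels.
#' @param alphaLevel significance level for the pairwise tests.
#' @param testType `"welch"` (default) or `"permutation"`.
#' @param seed seed for the permutation test.
#' @return list with `summaries` (named list of [GroupSummary-class]) and
#'   `tests` (data.frame of adjacent-pair comparisons).
#' @export
stratifyByNyha <- function(records, alphaLevel = 0.05,
                           testType = c("welch", "permutation"),
                           seed = NULL) {
  testType <- match.arg(testType)
  classes <- NYHA_LEVELS[-1]                 # none excluded
  nyha <- vapply(records, function(rec) rec@nyha, character(1))
  if (all(nyha == "none")) stop("records carry no NYHA labels")
  present <- classes[classes %in% nyha]
  missing <- setdiff(unique(nyha[nyha != "none"]), present)
  summaries <- list()
  for (cl in present) {
    recs <- records[nyha == cl]
    if (length(recs) == 0) next
    summaries[[cl]] <- averageProfile(recs, groupLabel = paste0("NYHA ", cl))
  }
  empty <- setdiff(classes, present)
  if (length(empty)) {
    warning("empty NYHA class(es) omitted: ", paste(empty, collapse = ", "))
  }
  tests <- NULL
  if (length(present) > 1) {
    rows <- list()
    for (i in seq_len(length(present) - 1)) {
      g1 <- present[i]; g2 <- present[i + 1]
      a <- summaries[[g1]]@kMaxValues
      b <- summaries[[g2]]@kMaxValues
      if (length(a) < 2 || length(b) < 2) next
      tt <- if (testType == "welch") welchTest(a, b, alphaLevel)
            else permutationTest(a, b, alphaLevel, seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        group1 = g1, group2 = g2,
        stat = if (testType == "welch") tt$t else tt$stat,
        p = tt$p, significant = tt$significant, stringsAsFactors = FALSE)
    }
    if (length(rows)) tests <- do.call(rbind, rows)
  }
  list(summaries = summaries, tests = tests)
}

#' Three-criterion health assessment of one subject
#'
#' A subject's spectrum is scored against three criteria: (a) the spectrum
#' is wide (`deltaAlpha >= deltaAlphaRef`), (b) it is loaded to the right
#' (`r > 1`), and (c) the curvature around the maximum is small
#' (`kMax <= kRef`). At least two criteria decide the combined label:
#' healthy-like when two or more hold, CHF-like when two or more fail,
#' indeterminate when a criterion cannot be evaluated. The curvature
#' criterion deliberately rescues slightly left-skewed spectra of healthy
#' subjects. Reference thresholds are mandatory and cohort-derived
#' (e.g. midpoints between group means); no clinical defaults are shipped.
#'
#' @param metrics a [ShapeMetrics-class].
#' @param reference named list or vector with `deltaAlphaRef` and `kRef`.
#' @return list with the three booleans (`wide`, `right`, `smallK`),
#'   `score` (criteria met out of 3) and `label`
#'   (healthy_like/chf_like/indeterminate).
#' @export
assessSubject <- function(metrics, reference) {
  stopifnot(is(metrics, "ShapeMetrics"))
  reference <- as.list(reference)
  if (is.null(reference$deltaAlphaRef) || is.null(reference$kRef)) {
    stop("reference must provide deltaAlphaRef and kRef")
  }
  wide <- metrics@deltaAlpha >= reference$deltaAlphaRef
  right <- is.finite(metrics@r) && metrics@r > 1
  smallK <- is.finite(metrics@kMax) && metrics@kMax <= reference$kRef
  crits <- c(wide = wide, right = right, smallK = smallK)
  nTrue <- sum(crits, na.rm = TRUE)
  nFalse <- sum(!crits, na.rm = TRUE)
  label <- if (nTrue >= 2) "healthy_like"
           else if (nFalse >= 2) "chf_like"
           else "indeterminate"
  list(wide = wide, right = right, smallK = smallK,
       score = nTrue, label = label)
}

#' Serialise group summaries and tests to JSON
#'
#' @param summaries named list of [GroupSummary-class] objects.
#' @param tests optional data.frame of pairwise tests (`group1`, `group2`,
#'   `stat`/`t`, `p`, `significant`).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeGroupJSON <- function(summaries, tests = NULL, path) {
  grp <- lapply(summaries, function(g) {
    list(
      label = g@groupLabel, n = g@n,
      right_count = g@rightCount, left_count = g@leftCount,
      symmetric_count = g@symmetricCount,
      r_mean_right = g@rMeanRight, r_sd_right = g@rSdRight,
      r_mean_left = g@rMeanLeft, r_sd_left = g@rSdLeft,
      mvac = g@mvac, mvac_err = g@mvacErr, mvac_err_type = g@mvacErrType,
      mvac_argmax_q = g@mvacArgmaxQ
    )
  })
  out <- list(groups = grp)
  if (!is.null(tests)) out$tests <- tests
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a group's mean curvature profile to CSV
#'
#' Columns `index,q,mean_K,sd,sem` (199 rows under the default grid).
#'
#' @param summary a [GroupSummary-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMeanProfileCSV <- function(summary, path) {
  stopifnot(is(summary, "GroupSummary"))
  df <- data.frame(index = seq_along(summary@meanProfile), q = summary@q,
                   mean_K = summary@meanProfile, sd = summary@profileSd,
                   sem = summary@profileSem)
  .writeNumericCSV(df, path)
}
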