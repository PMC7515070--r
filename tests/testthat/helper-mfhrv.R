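# Shared test utilities: fixtures are built in code, no files shipped.

# Wrap an arbitrary (x, y) curve as a MultifractalSpectrum so the
# derivative/curvature reductions can be exercised on known geometry.
specFromXY <- function(x, y, q = seq(-10, 10, length.out = length(x))) {
  new("MultifractalSpectrum",
      points = data.frame(q = q, alpha = x, f = y,
                          r2_alpha = 1, r2_f = 1,
                          stderr_alpha = 0, stderr_f = 0),
      base = 2L, levels = integer(), sourceId = "xy")
}

# A curvature profile built directly from values (for argmax tests).
profileFromK <- function(k, q) {
  new("CurvatureProfile", k = k, q = q,
      centerIndex = as.integer(which.min(abs(q))), degenerate = FALSE,
      sourceId = "direct")
}

# Closed-form cascade spectrum at a single q (independent re-derivation,
# kept deliberately separate from analyticSpectrum()).
cascadeAlphaF <- function(weights, q, base = length(weights)) {
  pw <- weights^q
  mu <- pw / sum(pw)
  c(alpha = -sum(mu * log(weights)) / log(base),
    f = -sum(mu * log(mu)) / log(base))
}

# Write RR values to a temp file, return the path.
writeTempRR <- function(lines) {
  f <- tempfile(fileext = ".rr")
  writeLines(lines, f)
  f
}
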