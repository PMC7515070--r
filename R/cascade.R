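## Multiplicative cascades with closed-form singularity spectra.
## These are the estimator oracle: for a base-b cascade with weights
## (p_1..p_b) the partition sums are exactly log-linear in the box size, so
## the scaling fits recover the analytic alpha(q), f(q) to machine precision.

#' Build a multiplicative cascade measure
#'
#' Starting from unit mass on one cell, each of `levels` refinement steps
#' splits every cell's mass among `base` children in proportion to
#' `weights`. With `randomize = FALSE` the weights are applied in a fixed
#' order (deterministic cascade); with `randomize = TRUE` the assignment of
#' weights to children is shuffled independently at every node, which
#' randomises the arrangement of mass while leaving every partition sum --
#' and hence the multifractal spectrum -- unchanged.
#'
#' @param weights numeric of length `base`, positive, summing to 1.
#' @param levels integer(1), number of refinement levels m; the output has
#'   `base^m` cells (guarded to at most 2^22).
#' @param base integer(1), branching base b >= 2. Defaults to
#'   `length(weights)`.
#' @param randomize logical(1), shuffle the weight-to-child assignment per
#'   node.
#' @param seed optional integer; when given, the shuffling is seeded locally
#'   so the cascade is reproducible without touching the global RNG stream.
#' @param sourceId character(1) label carried into the measure.
#' @return A [BoxMeasure-class] of length `base^levels`.
#' @examples
#' makeCascade(c(0.6, 0.4), levels = 2)  # masses 0.36 0.24 0.24 0.16
#' @export
makeCascade <- function(weights, levels, base = length(weights),
                        randomize = FALSE, seed = NULL,
                        sourceId = "cascade") {
  base <- as.integer(base)
  levels <- as.integer(levels)
  if (base < 2) stop("base must be >= 2")
  if (length(weights) != base) stop("need exactly `base` weights")
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite")
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("weights must sum to 1 (got ", format(sum(weights), digits = 12), ")")
  }
  if (base^levels > 2^22) stop("base^levels exceeds the 2^22 memory guard")

  build <- function() {
    p <- 1
    for (lev in seq_len(levels)) {
      k <- length(p)            # nodes at this level
      if (randomize) {
        # per-node random permutation, vectorised: rank runif within node
        u <- stats::runif(k * base)
        grp <- rep(seq_len(k), each = base)
        widx <- integer(k * base)
        widx[order(grp, u)] <- rep(seq_len(base), k)
        w <- weights[widx]
      } else {
        w <- rep(weights, times = k)
      }
      p <- rep(p, each = base) * w
    }
    p
  }
  p <- if (randomize && !is.null(seed)) {
    withLocalSeed(seed, build())
  } else {
    build()
  }
  # renormalise away accumulated rounding so the validity contract holds
  p <- p / sum(p)
  new("BoxMeasure", p = p, base = base, m = levels, sourceId = sourceId)
}

# Evaluate an expression under a local RNG state.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Closed-form multifractal spectrum of a multiplicative cascade
#'
#' For a fully supported base-b cascade with weights `p_i`, the singularity
#' spectrum has the exact parametric form (natural logs)
#' \deqn{\tilde\mu_i(q) = p_i^q / \sum_j p_j^q,\quad
#'       \alpha(q) = \sum_i \tilde\mu_i \ln(1/p_i) / \ln b,\quad
#'       f(q) = \sum_i \tilde\mu_i \ln(1/\tilde\mu_i) / \ln b.}
#' The result is returned as a [MultifractalSpectrum-class] (perfect-fit
#' diagnostics) so the shape and curvature reductions apply to it directly;
#' it is the independent oracle for the scaling-fit estimator.
#'
#' @param weights numeric, positive cascade weights summing to 1.
#' @param qgrid numeric vector of q values, e.g. [makeQGrid()].
#' @param base integer(1), branching base; defaults to `length(weights)`.
#' @return A [MultifractalSpectrum-class] with exact `alpha` and `f`.
#' @examples
#' sp <- analyticSpectrum(c(0.6, 0.4))
#' range(alphaValues(sp))
#' @export
analyticSpectrum <- function(weights, qgrid = makeQGrid(),
                             base = length(weights)) {
  base <- as.integer(base)
  if (length(weights) != base) stop("need exactly `base` weights")
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("weights must be positive and sum to 1")
  }
  lw <- log(weights)
  ab <- vapply(qgrid, function(q) {
    s <- q * lw
    s <- s - max(s)                      # stable for |q| large
    mu <- exp(s) / sum(exp(s))
    alpha <- -sum(mu * lw) / log(base)
    f <- -sum(mu * log(mu)) / log(base)
    c(alpha, f)
  }, numeric(2))
  pts <- data.frame(
    q = qgrid, alpha = ab[1, ], f = ab[2, ],
    r2_alpha = 1, r2_f = 1, stderr_alpha = 0, stderr_f = 0
  )
  new("MultifractalSpectrum", points = pts, base = base,
      levels = integer(), sourceId = "analytic")
}
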