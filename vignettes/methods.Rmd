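---
title: "Multifractal spectrum shape analysis of RR tachograms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifractal spectrum shape analysis of RR tachograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfhrv)
```

## The model

A tachogram is the ordered sequence of RR intervals of one recording.
Normalised by its total, it defines a singular measure $P(x)$ on its index
support; `toMeasure()` truncates the series to its largest leading block of
$b^m$ samples (base $b = 2$ by default) so that the support partitions
exactly into $b^n$ boxes at every level $n \le m$. Truncation, not padding,
is used: padding would inject artificial singularities at the seam, whereas
dropping a trailing remainder leaves the measure's scaling intact. The
measure is invariant under rescaling all RR values by a positive constant,
so seconds vs milliseconds (and the surrogate generator's RR scaling)
cannot affect any downstream statistic.

The direct (Chhabra–Jensen) estimator warps the box masses $P_i(L)$ at box
size $L = b^{-n}$ into the normalised family
$\mu_i(q, L) = P_i^q / \sum_j P_j^q$ and reads the spectrum off two
ordinary least-squares scaling fits,

$$f(q) = \text{slope of } \sum_i \mu_i \log \mu_i \text{ vs } \log L,
\qquad
\alpha(q) = \text{slope of } \sum_i \mu_i \log P_i \text{ vs } \log L,$$

one pair per moment order $q$, each $q$ fitted independently (no
continuation or smoothing across $q$). The method yields $f(\alpha)$
directly, without a Legendre transform of $\tau(q)$; Legendre-based,
MF-DFA and wavelet-leader estimators are deliberately out of scope.

**Assumptions.** The estimator presumes approximate log-log linearity of
the scaling sums over the fitted levels; per-$q$ $R^2$ and slope standard
errors are stored in every `MultifractalSpectrum` so departures are
visible rather than silent. On deterministic cascades the sums are exactly
log-linear and the estimator reproduces the closed-form spectrum to
machine precision; on empirical series the fits are genuine regressions.

## Shape statistics

With $\alpha$ non-increasing in $q$, the grid endpoints give
$\alpha_{max} = \alpha(q_{min})$ and $\alpha_{min} = \alpha(q_{max})$;
$\alpha_0$ is $\alpha$ at the $f$-maximising grid point, with ties broken
toward $q = 0$ (the theoretical maximiser). The width
$\Delta\alpha = \alpha_{max} - \alpha_{min}$, the half-widths
$\Delta\alpha_{right} = \alpha_{max} - \alpha_0$ and
$\Delta\alpha_{left} = \alpha_0 - \alpha_{min}$, and the symmetry ratio
$r = \Delta\alpha_{right} / \Delta\alpha_{left}$ follow directly. When
$\Delta\alpha_{left}$ is numerically zero (a near-monofractal, point-like
spectrum) $r$ is reported as `Inf` with a warning rather than as an
unstable quotient.

The curvature $K = |f''| / (1 + f'^2)^{3/2}$ is evaluated along the
$(\alpha, f)$ curve by finite differences. A 201-point spectrum yields 200
first-derivative and 199 curvature values; the centre entry corresponds to
$q = 0$. Two derivative modes are provided because the $\alpha$ abscissae
are not uniformly spaced while the classical three-point second-difference
formula presumes a uniform step:

- `paper_uniform` (default): successive difference quotients for $f'$, and
  the three-point second difference with the local mean spacing
  $h = (\alpha_{i+1} - \alpha_{i-1})/2$ as the step — the uniform-grid
  construction applied to the slightly non-uniform abscissae;
- `nonuniform`: the exact three-point formulas for unequal spacing.

Both modes agree to well under 1% on smooth geometry (sampled circles
recover $K = 1/\rho$; parabola vertices recover $K = 2c$), and either may
be selected throughout the pipeline. Whether the reference construction
differenced with respect to $\alpha$ or to the point index is not
documented anywhere authoritative; both interpretations are available and
the default mimics the uniform-step construction. Consecutive points
closer than $10^{-9}$ in $\alpha$ are merged (with $f$ and $q$ averaged)
before differentiation, since duplicate abscissae — which empirical
near-monofractal series can produce — would otherwise dominate $K$ through
division blow-ups. If fewer than three points survive merging the profile
is flagged degenerate and `k_max` is `Inf`: a point-like spectrum has,
in the limit, infinite vertex curvature.

`maxCurvature()` restricts the maximum to $|q| \le$ `windowHalfwidthQ`
(default 10, i.e. the whole default profile) because $K$ decays to zero
away from the spectrum maximum anyway; ties break toward the smallest
$|q|$.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| q grid | $[-10, 10]$, step 0.1 | — | 201 points; 0 and 1 on the grid; matches the reference analysis |
| base $b$ | 2 | — | dyadic partition of real recordings; 3 for base-3 surrogates |
| levels $n$ | $1 \dots m-1$ | — | every informative scale: $\ge b$ boxes and $\ge b$ samples per box; overridable when a scaling subrange is wanted |
| segment duration | 21600 | s | 6 h behavioural-state segments |
| unit inference | median > 10 → ms | — | physiological RR never exceeds 10 s |
| skew thresholds | 0.5 / 0.95 / 1.05 / 2.0 | — | $r \ll 1$ ("sharply left") below 0.5 since 0.4 is described as sharply left-biased while 2.5 is merely right-skewed; the symmetric band is ±5% |
| curvature window | $|q| \le 10$ | — | $K \approx 0$ far from the vertex; config allows $|q| \le 1$ |
| artifact filter | off | s | RR outside [0.2, 4] s or >20% jumps can be dropped, but the reference pipeline applied no ectopy filtering, so the default reproduces it |
| significance level | 0.05 | — | used by every group test |

The scale range for the fits is the one genuinely open choice: the
reference analysis never states which box sizes enter the regressions.
Using all informative levels is the neutral default and matches the
"decreasing box sizes" description; the CLI exposes `--levels` for
subrange fits, and the stored $R^2$ values show when a subrange would have
been advisable.

## Statistics

Group summaries count subjects with $r > 1$ (right-skewed), $r < 1$
(left-skewed) and $r = 1$ (its own measure-zero bin, excluded from the
right/left means), average the curvature profiles pointwise, and read the
maximum of the average curvature (mvac) off the mean profile. Because the
dispersion semantics behind published "±" values are not stated, both sd
and sem are computed per point; sem is attached to mvac by default and the
choice is recorded in the output (`mvac_err_type`).

Two-group comparisons use Welch's two-sided unequal-variance $t$-test on
per-subject curvature maxima — the only per-subject scalar consistent with
group "±" reporting; variances differ strongly between health groups,
hence Welch rather than the pooled test. A seeded permutation test
(10,000 resamples) is available for small NYHA classes. The degenerate
zero-variance case is defined by its limit ($p = 1$ for equal means, else
$p = 0$). NYHA stratification summarises the classes present (I, II, III,
III-IV, IV), tests adjacent pairs, and omits empty classes with a warning.

The three-criterion assessment labels a subject healthy-like when at least
two of (a) $\Delta\alpha \ge$ `deltaAlphaRef`, (b) $r > 1$, (c)
$k_{max} \le$ `kRef` hold, CHF-like when at least two fail. The reference
thresholds are deliberately mandatory — they are cohort-derived midpoints
between group means, and no universal clinical constants exist to ship as
defaults.

## The surrogate generator

`makeCascade()` builds deterministic or randomised multiplicative
cascades. Shuffling the weight-to-child assignment per node randomises the
arrangement of mass but provably leaves every partition sum — and hence
the whole spectrum — unchanged, so randomised cascades share the closed
form evaluated by `analyticSpectrum()`:
$\alpha(q) = \sum_i \tilde\mu_i \ln(1/p_i)/\ln b$,
$f(q) = \sum_i \tilde\mu_i \ln(1/\tilde\mu_i)/\ln b$ with
$\tilde\mu_i = p_i^q / \sum_j p_j^q$. This oracle equivalence — estimator
versus closed form — is the central validation property of the package.

`makeRRSurrogate()` emulates the two empirical regimes:

- **healthy-like**: base-3 weights $(0.45, 0.35, 0.20)$, chosen from the
  analytic oracle (before any estimator-level testing) so that the
  spectrum is broad ($\Delta\alpha \approx 0.73$), right-skewed
  ($r \approx 1.36$; about 90% of jittered subjects have $r > 1$) and has
  low vertex curvature ($K \approx 10$);
- **chf-like**: the same weights pulled toward uniform by
  $0.85 \times$ severity, which narrows the spectrum and inflates the
  vertex curvature (severity 0.7, the default, gives $K \approx 80$);
  severity 0 reproduces the healthy-like parameterisation exactly.

Per-subject variability comes from log-normal weight jitter (sd 0.1 at
severity 0, shrinking to 0.05 at severity 1), seeded per subject. The
measure is rescaled multiplicatively to mean RR 0.8 s. A pure rescaling is
used rather than an affine map with an offset: only pure rescaling leaves
the renormalised measure — and therefore the spectrum — exactly invariant;
an offset would mix a uniform background into the measure and reshape it.
Synthetic asleep/awake windows covering the two recording halves are
attached so segmentation code paths are exercisable. The NYHA map
(`nyhaSeverity()`: I 0.25, II 0.5, III 0.7, III-IV 0.85, IV 0.95) is a
monotone convenience for stratified simulations.

**What the surrogates do not emulate.** Cascades are stationary,
noise-free and exactly scale-invariant; real tachograms carry ectopy,
non-stationarity across behavioural states, finite scaling ranges and
measurement noise, and their spectra are estimated, not exact. Passing
surrogate tests therefore demonstrates estimator and statistics
correctness under known multifractal structure — not clinical performance
on real recordings, which additionally depends on data quality and segment
selection. Matching the published group tables numerically is explicitly
not a surrogate goal; the surrogates only occupy the right qualitative
regimes (broad/right/low-K versus narrow/high-K).

## Numerical choices

- All powers $P_i^q$ are taken in log space with a columnwise max shift,
  so $|q| = 10$ on box masses of order $10^{-6}$ neither overflows nor
  underflows; zero-mass boxes are excluded ($0 \log 0 \to 0$), though
  RR-derived measures have none.
- Natural logs are used in the sums and in $\log L$; slopes are
  base-invariant, so this is purely cosmetic and recorded for
  reproducibility.
- The OLS slopes, $R^2$ and slope standard errors are computed by the
  closed-form textbook formulas, vectorised across the 201 moment orders,
  and are verified against `lm()` in the test suite.
- CSV exports round to 6 significant digits for cross-platform byte
  stability; identical inputs, configuration and seed give byte-identical
  outputs.
- Seeded operations (cascade shuffling, surrogate jitter, permutation
  tests) run under a local RNG state, so library calls never perturb a
  caller's random stream.

## Problem sizes

The validation suite estimates spectra from depth-16 binomial cascades
(65,536 samples; worst-case error against the closed form below 0.02 and
in practice at machine precision), depth-9 trinomial cascades for the
asymmetric-spectrum checks, and depth-8 base-3 surrogates (6,561 beats,
about 1.5 h of simulated recording) for cohort-level simulations: 100
replications of 20-vs-20 cohorts for the discrimination check and 2,000
null replications for the Welch type-I calibration. These sizes make the
full validation run in a few minutes on one core while leaving the
estimator's asymptotic regime clearly visible; real 24 h tachograms
(about $10^5$ beats, $m = 16$ dyadic levels) run through the identical
code path.

## Known limitations

- `extractSegment()` anchors a segment at the first qualifying prefix of
  the first long-enough window; where a 6 h segment was anchored inside
  longer behavioural periods in the reference analysis is undocumented,
  and a different anchoring convention would select different beats.
- Sleep/awake identification is taken from explicit state windows
  (sidecar or flags); no sleep staging is inferred from the signal.
- WFDB binary and annotation parsing is out of scope; recordings must be
  exported to plain-text RR files first.
- The estimator fits all informative dyadic scales by default; series
  with a genuinely restricted scaling range require a `--levels` subrange,
  which the stored diagnostics help identify but do not choose
  automatically.
- Spectra of short or heavily artifacted series can be non-concave or
  non-monotone in $\alpha$; the shape reductions handle these
  defensively (merging, degeneracy flags) but the resulting statistics
  should be interpreted alongside the fit diagnostics.
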