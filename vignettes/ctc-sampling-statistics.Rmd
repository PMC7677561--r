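---
title: "Temporal sampling statistics for rare CTC detection streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal sampling statistics for rare CTC detection streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcstream)
```

## The problem

Circulating tumor cells (CTCs) are rare — often below one cell per ml of
blood — and their abundance is the basis of liquid-biopsy enumeration.
Continuous in vivo cytometry counts individual CTCs as timestamped detection
events while optically sampling blood at a known volumetric rate
(about 50 ul of peripheral blood per minute in the mouse). Because the
instrument samples volume at a constant rate, any scan-time interval is
*equivalent to a drawn blood sample*: with the defaults, a 24 s interval
corresponds to 20 ul, or roughly 1% of a 2 ml mouse peripheral blood volume
(PBV); 2, 4 and 8 min correspond to 5%, 10% and 20%. This package analyses
such detection streams to answer two questions:

1. How reliable is CTC enumeration from a blood sample of a given size, and
   how does that reliability depend on when the sample is drawn?
2. Are the detection counts consistent with a *stationary, well-mixed*
   (homogeneous Poisson) model, or do mean CTC numbers change on the
   timescale of minutes to hours?

The core modelling assumption, carried by `scan_config()`,
`interval_to_volume()` and `rate_to_concentration()`, is that the event
count in a scan-time interval equals the count a drawn sample of the
corresponding volume would contain. No dilution or mixing correction is
applied — this is the stated equivalence model, not an approximation the
package tries to improve. Percent-of-PBV labels are display-only: ul is the
canonical unit, and no calculation depends on the assumed 2 ml PBV.

## Statistics computed

**Window counts.** `count_in_windows()` tallies events in half-open windows
`[t, t + w)` laid on a start grid. Sliding mode advances by a configurable
stride (default 1 s, a practical stand-in for "all possible intervals" at
instrument resolution); nonoverlapping mode tiles the scan. An event exactly
on a boundary belongs to the next window, which makes the nonoverlapping
tally conserve the total count; trailing partial windows are discarded
because an equivalent blood sample has a fixed volume.

**Deviation from the scan mean (DFSM).** For window count $C_i$ and scan
mean $\lambda$ (mean count per window over the whole scan),

$$\mathrm{DFSM}_i = \frac{|C_i - \lambda|}{\lambda} \times 100\%.$$

`dfsm()` computes the per-window values and the fraction of windows at or
below given thresholds (25% and 50% by default — thresholds at which an
enumeration error starts to move samples across prognostic cut-points). The
Poisson reference is available in closed form: `poisson_dfsm_fraction()`
enumerates the integers inside $[\lambda(1 \pm \mathrm{thr}/100)]$ and sums
the Poisson pmf; `poisson_dfsm_fraction_mc()` is the simulation route, and
the two are cross-checked in the test suite.

**Variance-versus-mean (overdispersion) analysis.** For an ideal Poisson
stream the variance of window counts equals the mean. `variance_mean_point()`
computes the sample mean and the $n-1$ sample variance per scan and window
size; `zero_intercept_fit()` fits variance against mean through the origin
($\hat\beta = \sum m_i v_i / \sum m_i^2$). Slope 1 is the equidispersion
signature; slopes above 1 indicate a changing underlying rate.

*Finite-scan overlap bias.* Overlapping sliding windows share the scan mean,
so their sample variance is biased low: for identically distributed,
correlated observations $E[s^2] = \sigma^2 (1 - \bar\rho)$, with $\bar\rho$
the mean correlation over distinct window pairs. For counts of a homogeneous
Poisson process that correlation is exactly the fractional window overlap
$\max(0, 1 - d\,\mathrm{stride}/w)$ at lag $d$, so $\bar\rho$ follows from
window geometry alone; at an 8-min window in a 35-min scan the bias factor
is about 0.73 — far from negligible. `variance_mean_point(debias_overlap =
TRUE)` divides by `overlap_debias_factor()` to remove it. The correction is
exact under the Poisson null; under overdispersion the true correlations
reach beyond the window overlap, so the corrected variance still
*underestimates*, making slope-above-1 detection conservative. For
nonoverlapping windows the factor is identically 1. On long streams the raw
sliding variance converges to the nonoverlapping variance, a property the
test suite checks explicitly.

**24-h variability.** `maxmin_rate_ratio()` summarises between-scan
variability of a `diurnal_session` as the maximum/minimum scan rate ratio
(zero minima yield a flagged `Inf`, or a configurable floor).
`split_scan_ratio()` is the within-scan analogue: first versus last 15 min,
separated by 5 min. `ks_two_sample()` compares groups of such ratios with a
two-sided two-sample Kolmogorov-Smirnov test; the p-value is asymptotic
(what standard tools report at these sample sizes), and with tied discrete
data it is conservative.

**Sampling strategies.** A `strategy_spec()` describes `n` samples of `w`
seconds each, drawn at least 6 h apart (configurable). For every draw the
estimate is the mean count across its samples; its DFSM is computed against
the session's 24-h reference — the pooled event count over all scans divided
by pooled scanned time, scaled to a window of the same length.
`strategy_accuracy()` returns the fraction of draws within a DFSM threshold,
and `paired_strategy_comparison()` contrasts two strategies of equal total
volume (e.g. four 1% samples versus one contiguous 4% sample) on the same
session. Samples must lie wholly inside a scan (a contiguous 80% PBV sample
is 32 min, which fits a 50-min scan).

## Synthetic event streams

All generators produce events by exponential inter-arrival sampling at a
piecewise-constant rate (no thinning is needed) and are bit-reproducible
under a seed; batteries derive per-stream seeds with the documented affine
rule `child_seed()`.

* `simulate_homogeneous_poisson()` — the stationary, well-mixed null; also
  the statistical model of a well-mixed microsphere suspension.
* `simulate_changepoint_poisson()` — rate $\lambda_1$ then
  $\lambda_2 = 2\lambda_1$ from mid-scan, the minimal "mean changed during
  the scan" alternative. Pooled window counts form a 50/50 mixture of
  Poissons with variance $\bar\mu + (\mu_2 - \mu_1)^2/4$, giving a
  variance-to-mean ratio of $1 + (\mu_2-\mu_1)^2 / (2(\mu_1+\mu_2))$.
* `simulate_merged_poisson()` — the sum of two concurrent streams; by
  superposition this is Poisson at the summed rate, so multiple simultaneous
  stationary sources cannot explain overdispersion.
* `simulate_switching_shedding()` — a two-state Markov-modulated Poisson
  process (exponential dwells, stationary start), the kinetic
  high/low-shedding hypothesis; overdispersed when dwells are long relative
  to the window.
* `simulate_diurnal_session()` — four 50-min scans 6 h apart, each
  homogeneous at `base_rate * multiplier`.

`generate_fixture_suite()` writes the standard battery: 54 homogeneous,
54 change-point and 54 merged 35-min streams with rates log-spaced over
0.6–19.6 events/min, plus 14 diurnal sessions (alternating 7am/7pm starts),
with a JSON manifest of every spec and realised count.

Two generator laws are genuinely open choices, fixed once here:

* The 54-stream rate grid is log-spaced across 0.6–19.6 events/min, the
  detection-rate range typical of an abundant-CTC (disseminated myeloma
  xenograft) setting; individual per-stream rates are an open choice, so the
  grid reproduces the envelope rather than any specific scan.
* Session multipliers are log-uniform on [1, 150]; the law of the real
  diurnal variation is unknown, and these bounds make realised max/min
  session ratios span roughly 2–150, the order of day-scale variability seen
  in vivo in xenograft models. With four draws
  from this law the median realised ratio is of order 20.

What the generators deliberately do **not** emulate: optical peak detection
and its false-alarm/miss rates, probe repositioning and operator effects,
arterial/venous discrimination, CTC clusters, and mechanistic clearance
kinetics (the switching model is a phenomenological hypothesis, not a
half-life ODE). Passing tests therefore validate the *statistical machinery*
and its behaviour under known point-process models — not any claim about a
particular animal dataset.

## Numerical and design choices

* **Sliding stride** defaults to 1 s; results stabilise as the stride
  shrinks and the supplementary convergence property (sliding variance to
  nonoverlapping variance on long streams) is under test.
* **Variance divisor** is $n-1$; with the overlap debias factor this makes
  the sliding estimator unbiased under the Poisson null.
* **DFSM thresholds are inclusive** (`<=`), matching "equal to or less
  than"; the Poisson band enumeration pads its floor/ceiling by `1e-9` to
  keep exact integer boundaries (e.g. $\lambda = 4$, count 6, threshold 50)
  on the inside.
* **Ratio of rates with a zero minimum** returns `Inf` rather than failing
  silently; analyses that pool ratios filter non-finite values and report
  how many were dropped.
* **Battery sizes.** Per-scan variance estimates at the 8-min window carry
  only ~4 independent windows' worth of information, so single-suite slope
  estimates are noisy there. Analyses that need a stable slope (the
  equidispersion recovery check) pool ten replicate 54-stream suites; the
  qualitative contrasts (change-point slope above 1, cohort ordering) hold
  already at one suite.
* **Strategy draw enumeration** is exhaustive on a non-overlapping offset
  grid where feasible; for multi-sample fine-grid cases the space is
  combinatorially large, so seeded random draws are used (scan combination
  uniform, one offset per scan, offsets sorted in chronological scan order,
  violating draws rejected). The estimator is the unweighted mean of
  per-sample counts rescaled to a common window — the natural choice when
  samples have equal volume; other normalisations would be defensible too.
* **24-h reference mean** is pooled events over pooled scanned time, not the
  mean of scan means; with equal-duration scans the two coincide.
* **KS p-values** are asymptotic; exact small-sample p-values are out of
  scope at the group sizes involved (6–18).

## A worked contrast

```{r contrast}
rates <- exp(seq(log(0.6), log(19.6), length.out = 12))
point_at <- function(sim) {
  do.call(rbind, lapply(seq_along(rates), function(i) {
    s <- sim(rates[i], child_seed(42, i))
    variance_mean_point(count_in_windows(s, interval_spec(120)),
                        debias_overlap = TRUE)
  }))
}
homog <- point_at(function(r, sd) simulate_homogeneous_poisson(r, 2100, sd))
change <- point_at(function(r, sd)
  simulate_changepoint_poisson(r, 2 * r, 1050, 2100, sd))
c(homogeneous = zero_intercept_fit(homog),
  changepoint = zero_intercept_fit(change))
```

The homogeneous suite sits near slope 1 while a rate doubling at mid-scan
drives the slope well above 1 — the package's central diagnostic, here at
2-min windows on a 12-stream battery.

## Known limitations

* The equivalence of a scan interval and a drawn blood sample is assumed,
  not tested; systematic detection-efficiency differences between the two
  would shift absolute concentrations but not the dispersion diagnostics.
* DFSM is undefined for empty scans (`lambda = 0`); such scans are excluded
  by the inclusion rules rather than imputed.
* The DFSM reference within a 35-min scan is the scan's own mean, so DFSM
  measures *precision* relative to that scan, not accuracy against the
  animal's longer-term burden; the session analyses use the 24-h mean for
  exactly that reason.
* Random-mode strategy draws sample a documented, slightly non-uniform law
  over feasible placements; exhaustive mode is available where the grid is
  small.
* The asymptotic KS p-value with heavily tied counts is conservative;
  comparisons near the significance boundary should be read accordingly.
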