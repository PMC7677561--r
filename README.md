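# ctcstream

Temporal sampling statistics for rare circulating-tumor-cell (CTC)
detection streams.

## What problem this solves

Continuous in vivo cytometry counts rare CTCs as timestamped detection
events while optically sampling blood at a known volumetric rate (~50 ul of
peripheral blood per minute in the mouse). Any scan-time interval is then
*equivalent to a drawn blood sample*: 24 s ≈ 20 ul ≈ 1% of a 2 ml mouse
peripheral blood volume (PBV); 2, 4 and 8 min ≈ 5%, 10% and 20%. For anyone
designing liquid-biopsy sampling schemes — or asking whether CTC numbers are
even stationary on the timescale of a blood draw — this package provides the
statistical machinery:

* interval ↔ volume ↔ concentration conversions (`scan_config()`,
  `interval_to_volume()`, `rate_to_concentration()`);
* sliding / non-overlapping window counting with detection fractions and
  count histograms against Poisson references;
* the **deviation from the scan mean**, for window count *Cᵢ* and scan mean
  *λ*:

  DFSMᵢ = |Cᵢ − λ| / λ × 100%

  with closed-form Poisson reference fractions;
* **overdispersion analysis**: per-scan variance-versus-mean points and a
  zero-intercept least-squares slope (slope 1 = Poisson equidispersion,
  slope > 1 = changing mean), including an exact correction for the
  finite-scan bias of overlapping sliding windows;
* 24-h variability metrics (max/min scan-rate ratios, first-vs-last segment
  ratios, two-sample KS comparisons);
* **sampling-strategy evaluation**: does averaging several small, temporally
  spread samples beat one contiguous sample of equal total volume?
* seeded generators for homogeneous, change-point (rate doubling at
  mid-scan), merged (superposed), Markov-modulated Poisson streams and
  diurnal four-scan sessions, so the whole chain is testable in silico.

## Worked example

Simulate the standard in-silico battery (54 homogeneous, 54 change-point and
54 merged 35-min streams over 0.6–19.6 events/min, plus 14 diurnal
sessions), analyse it, and render the report:

```r
library(ctcstream)
cfg <- run_config("run", master_seed = 1)
pipeline_simulate(cfg)
pipeline_analyze(cfg)
cat(pipeline_report(file.path("run", "results", "summary.json")), sep = "\n")
```

Selected lines of the printed report (master seed 1):

```
-- Zero-intercept variance-mean slopes --
  homogeneous      24 s: slope 0.996 (n = 54)
  changepoint      24 s: slope 2.002 (n = 54)
  changepoint     480 s: slope 22.347 (n = 54)
  merged           24 s: slope 1.004 (n = 54)

-- Diurnal sessions: max/min scan-rate ratios --
  n = 14, median ratio 19.42, range 4.20-120.04

-- Spread-vs-contiguous paired wins --
  four 1% beats 4% in 100% of sessions
  four 20% beats 80% in 100% of sessions
```

Reading these: the homogeneous and merged cohorts sit on the Poisson 1:1
variance-mean line (slopes ≈ 1) — merged streams are themselves Poisson by
superposition, so concurrent stationary sources cannot masquerade as
overdispersion. A mere rate doubling at mid-scan drives slopes of 2–22
(growing with window size), the signature of a changing mean. Simulated
diurnal sessions vary by an order of magnitude or more across a day, and on
such sessions four spread 1%-PBV samples estimate the 24-h mean within 25%
far more often than one contiguous 4% sample of identical total volume.

Single functions work on single scans too:

```r
s <- simulate_changepoint_poisson(4, 8, 1050, 2100, seed = 7)
ic <- count_in_windows(s, interval_spec(120))          # sliding 2-min windows
dfsm(ic)$threshold_fractions                           # fraction within 25%/50%
poisson_dfsm_fraction(scan_mean(ic), 25)               # Poisson reference
variance_mean_point(ic, debias_overlap = TRUE)         # overdispersion point
```

A thin command-line wrapper over the same pipeline lives at
`inst/cli/ctcstream-cli.R` (subcommands `simulate`, `analyze`, `report`,
YAML config).

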