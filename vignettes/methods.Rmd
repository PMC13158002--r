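---
title: "gBOLD-CSF coupling: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gBOLD-CSF coupling: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physiological model and the metric

During low-frequency global brain activity, changes in cerebral blood
volume displace cerebrospinal fluid: when the global BOLD (gBOLD)
signal falls, blood volume shrinks and CSF flows *into* the imaging
volume, which raises the signal of CSF voxels at the bottom
acquisition slice (an inflow effect).  The working model is therefore

> CSF(t) ≈ −d gBOLD/dt (t − δ) + noise,

with a short hemodynamic delay δ.  Two consequences define the
package's outputs:

1. the lagged cross-correlation between gBOLD and CSF has a negative
   peak at a positive lag near **+4 s** (with our lag convention
   `r(k) = cor(g[t+k], c[t])`, negative lag = gBOLD leads), and a
   positive peak at negative lag;
2. the cross-correlation between −d(gBOLD)/dt and CSF peaks near
   **−2 s**.

The per-subject *coupling strength* is `r(+4 s)`; weaker (less
negative) values are read as reduced brain–CSF synchronization, a
proxy for impaired glymphatic function.

For a narrowband gBOLD process centred at `f0`, the noise-free curve is
sinusoidal in the lag: the negative peak sits at `1/(4 f0) − δ`.  The
generator default `f0 = 1/24` Hz with `δ = 2` s puts it at +4 s and the
derivative peak at −δ = −2 s, the lag structure the analysis is
designed to recover.

## Pipeline parameters

| parameter | default | unit | why |
|---|---|---|---|
| `n_discard` | 10 | volumes | discard non-equilibrium scans |
| `trans_limit_mm`, `rot_limit_deg` | 1.5 / 1.5 | mm, deg | motion exclusion; *strictly greater* fails, so a value exactly at 1.5 passes ("bigger than" rule); configurable |
| band-pass | 0.01–0.1 | Hz | isolates the low-frequency band carrying the coupling |
| filter order | 4 (Butterworth) | — | conventional; applied forward–backward (zero phase) |
| `fwhm_mm` | 4 | mm | spatial smoothing of the gBOLD branch only |
| detrend degree | 2 | — | constant + linear + quadratic drift removal |
| `slice_index` | 1 | — | bottom slice = CSF inflow reference |
| `max_lag_s` / `metric_lag_s` | 10 / +4 | s | lag window and the headline lag |
| permutation `n_iter` | 10 000 | — | subject-shuffling null |
| `alpha`, m | 0.05, 5 | — | Bonferroni threshold α/m = 0.01 |

Zero-phase filtering matters because the analysis quantifies lags: any
group delay would shift the peak locations.  The two printed band
edges are treated as a band-*pass* (not a pure low-pass), since a band
with two edges is a band definition.

### Branch order

The gBOLD branch runs discard → detrend → band-pass → smooth → mask
average → z-score; the CSF branch is identical but with no smoothing
(smoothing would dilute the single-slice inflow signal across slices)
and no motion regression.  The temporal operators nearly commute in the
long-series limit, and the suite verifies this at n = 4000 samples
(< 2% RMS).  At scan length (230 samples) the polynomial fit of a
band-passed finite sample is *not* negligible (10–30% RMS), which is
why the order is fixed rather than left to chance: detrending first
removes drift before it can interact with the filter's edge response.

### Motion QC

Maxima are taken over per-volume absolute parameters (displacement
relative to the realignment reference), not frame-to-frame differences,
matching the "maximum translation/rotation" reading; framewise
displacement QC is deliberately not implemented.  Motion files are read
in the SPM/DPABI `rp_*.txt` dialect (rotations in radians) by default,
with a `dialect` flag for files already in degrees.

## Derivative estimators: one deliberate deviation

`negative_derivative()` is the forward difference
`-(x[i+1]-x[i])/dt`, which lives on the *midpoint* grid — its
timestamps are shifted by dt/2 (recorded in the series' `t0`).  At
TR = 2 s that half-sample shift is a full second.  If the derivative
coupling were computed by index-aligning the forward difference with
the CSF series, the curve's lag axis would be displaced by 1 s relative
to the raw gBOLD–CSF curve, and with the generator's exact model
(CSF = −g′ delayed 2 s) the derivative-curve maximum would sit midway
between the −2 s and −4 s grid points — an exact tie broken only by
sampling noise.  No generator delay can fix this: the raw-curve peak
and the derivative-curve peak conditions differ by exactly half a
sample.

`derivative_coupling()` therefore uses the *central* difference
`-(g[i+1]-g[i-1])/(2 dt)` internally.  The central difference is
phase-neutral (it estimates the derivative *on* the sampling grid), so
the derivative curve shares the raw curve's time base and the two
printed peak lags (+4 s and −2 s) are simultaneously recoverable.  For
narrowband signals the two estimators differ only by the half-sample
phase and a frequency-dependent gain, which cancels in the correlation.
The exported forward-difference operator keeps its documented contract
and is available for users who want the literal estimator.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` states the emulated study as defaults: 29 + 37
subjects; 240 volumes at TR 2 s (64 × 64 × 32 geometry scaled to a
16 × 16 × 8 desk grid, configurable back up); group mean couplings
−0.240 (clinical) / −0.111 (control) with SDs 0.200 / 0.225; a betel
quid dependence duration covariate (normal 15.3 ± 7.4 years, truncated
positive) correlated 0.4313 with coupling; dependence scores normal
8.8 ± 2.7 truncated > 4, daily dose 6.1 ± 7.2 truncated positive,
anxiety/depression scores integers 0–7; ~7% motion violators
(exceeding 1.5 mm / 1.5°, matching the 5-of-71 exclusion rate of the
emulated cohort).

Mechanics: gBOLD is white noise band-limited to `f0 ± bandwidth/2` in
the frequency domain (flat band, default width 0.02 Hz — narrow enough
that the autocorrelation envelope is nearly flat over ±10 s, so sampled
peak lags match the analytic ones).  The derivative and the delay are
applied spectrally (multiplication by `i 2 pi f` and a linear-phase
factor), so the model `CSF = −g′(t−δ)` holds exactly on the grid with
no estimator bias.  Per-subject expected couplings are drawn from the
group distributions truncated to (−0.95, 0.95); draws with |r| < 0.01
become *uncoupled* subjects (pure-noise CSF) rather than being clamped,
which keeps null cohorts (`target = 0, sd = 0`) exactly null.  The
noise SD realizing a target r uses the attenuation closed form
`r = r_ideal / sqrt(1 + sigma^2)`, where `r_ideal` (≈ −0.97 at the
defaults) is the noise-free metric-lag coupling estimated once by
long-series simulation under a fixed internal seed;
`calibrate_noise(refine = TRUE)` adds a bisection against simulated
estimates (tolerance 0.01).

Known gaps to real data, hence what a green test does *not* establish:
no hemodynamic response function, no cardiac/respiratory physiology, no
scanner drift beyond polynomial trends, no spatial autocorrelation of
voxel noise, no registration error.  The generator demonstrates that
the *analysis* recovers its stated world — not that the stated world is
physiologically complete.

Two quantitative notes a user should know:

* the *observed* per-subject coupling adds sampling noise
  (SE ≈ 0.08–0.09 at 230 volumes) to the drawn ideal coupling, so
  realized group SDs slightly exceed the configured 0.200/0.225, and
  the realized duration–coupling correlation is attenuated by a few
  hundredths relative to the configured 0.4313;
* single cohorts fluctuate: cohort-level group means scatter with
  SD ≈ 0.04 around their targets.  Recovery is therefore asserted over
  50 replicate cohorts (within 2 Monte-Carlo SEs), and the lag
  structure (+4 s / −2 s) is recovered in ≈ 97% of seeded 30-subject
  replicates — not in every seed.

## Statistical choices

* **Pooled t** (not Welch): re-computing the group contrast from the
  printed summaries gives ≈ −2.43 pooled vs ≈ −2.46 Welch against the
  printed −2.417, so pooled is the variant that reproduces the source.
* **Chi-square without continuity correction**: the printed sex-table
  p = 0.005 matches the uncorrected statistic (p = 0.0046), not the
  Yates-corrected one (0.011).
* **Mann-Whitney** for continuous demographics (the "two-sample
  nonparametric test" of record in SPSS workflows): exact enumeration
  of rank splits when n1+n2 ≤ 12, otherwise the tie-corrected normal
  approximation.
* **Bonferroni as a fixed threshold** (compare each uncorrected p
  against α/m, strictly), not p-multiplication — this mirrors the
  stated procedure and keeps `corrected_threshold * m = alpha` exact.
* **Adjusted model**: main-effects OLS of coupling on a 0/1 group
  indicator plus sex (0/1, reference configurable), age and education
  entered linearly; with an empty covariate set it reproduces the
  pooled t exactly (OLS/t equivalence, tested to 1e-9).
* **Permutation null**: derangements (no subject keeps its own CSF),
  since the null is defined by pairing signals "from various
  individuals"; plain permutations available by flag.  Two-sided p
  with +1 smoothing, `p = (#{|null| >= |obs|} + 1)/(n_iter + 1)`, so
  p = 0 is impossible.

## Numerical and degenerate-input conventions

* z-scoring uses the population SD (divisor N); irrelevant to Pearson
  values, stated for bit-reproducibility.
* Per-lag correlations are computed on each lag's own overlap segment;
  a zero-variance segment is an error, as is a series shorter than
  twice the lag window.
* Peak ties break toward the smallest |lag|, then toward negative lag.
* A metric lag off the lag grid (TR not dividing 4 s) is rounded to
  the nearest grid point with a warning.
* The boundary motion value exactly 1.5 mm/1.5° passes (strict
  inequality), and `bqds = 4` fails screening (strictly greater than 4
  required) while `hamd24 = 7` passes (not exceeding 7).
* Gaussian smoothing uses truncated (4σ) separable kernels with
  edge renormalization: constants are preserved everywhere and total
  intensity is conserved for interior-supported signals.
* NIfTI-1 I/O is a minimal built-in codec (348-byte header,
  uint8/int16/int32/float32/float64, `.nii`/`.nii.gz`), validated
  against an independent reference reader; orientation metadata beyond
  voxel size is ignored because the pipeline consumes
  already-registered volumes.  Whether the acquisition's bottom slice
  is stored first or last is scanner-dependent; `slice_axis` and
  `slice_index` are configurable rather than guessed.
* Config files are JSON (no YAML parser among the allowed
  dependencies); structure is identical to the documented fields.

## Open choices made here

* The motion maxima are interpreted relative to the realignment
  reference (not the mean image); recorded as a choice, not as the
  original authors' confirmed intent.
* The "grey-matter mask" is whatever the user supplies (an atlas union
  or a tissue-probability threshold both work); the synthetic study
  ships its own.
* The permutation statistic is the fixed +4 s lag value averaged over
  subjects (the searched-minimum variant is available as
  `metric_mode = "searched-minimum"`).
* Smoothing is placed after temporal filtering; the alternative order
  changes results negligibly since smoothing is purely spatial.

## Limitations

Voxelwise lag maps, frequency-domain coherence, hemodynamic
deconvolution, nuisance regression (motion/white-matter/global-signal
variants), slice-timing and realignment themselves, and FDR-style
multiplicity control are out of scope.  The coupling metric is a
cohort-level proxy; nothing here validates it against invasive
measures of glymphatic clearance.
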