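# csfcoupling

Quantifies the coupling between the **global blood-oxygen-level-dependent
(gBOLD) signal** and the **cerebrospinal-fluid (CSF) inflow signal** in
resting-state fMRI — a noninvasive proxy for glymphatic function — and
provides the cohort-level statistics used to compare it between a
clinical group and healthy controls.

## Who this is for

Neuroimaging researchers who have registered 4D rs-fMRI volumes, a
grey-matter mask, a CSF mask, and realignment-parameter files, and who
want the standard gBOLD–CSF coupling metric with quality control, a
permutation null, and group/correlation statistics — plus a fully
synthetic, seeded cohort generator for method validation when real
scans are unavailable.

## The metric

For each subject the pipeline extracts two z-scored series at the
repetition time TR:

* `g(t)` — the mean band-passed (0.01–0.1 Hz, zero-phase 4th-order
  Butterworth), detrended, spatially smoothed signal over grey matter;
* `c(t)` — the mean detrended, band-passed signal of CSF voxels in the
  bottom acquisition slice, where fresh-spin inflow makes intensity
  sensitive to CSF flow into the volume (no smoothing, to keep the
  inflow effect undiluted).

The coupling curve is the lagged Pearson correlation

```
r(k) = cor( g[t + k], c[t] ),   k = -10 s … +10 s in steps of TR,
```

each lag computed on its own overlap segment (so |r| ≤ 1 exactly).
**Negative lag means gBOLD leads CSF.** Physiologically the curve shows
a positive peak at negative lag and a negative peak near **+4 s**; the
value `r(+4 s)` is the per-subject *coupling strength* (more negative =
stronger coupling). A companion curve correlates `-dg/dt` with `c`,
peaking near **-2 s**, reflecting the model that CSF inflow tracks
decreases in cerebral blood volume. Significance of the cohort mean is
assessed against a null built by re-pairing gBOLD and CSF signals
across subjects (random derangements, 10 000 iterations).

Group contrasts use a pooled two-sample t (plus an OLS model adjusted
for sex, age, education); clinical associations use Pearson
correlations with a Bonferroni threshold α/m (0.05/5 = 0.01).

## Worked example

A synthetic cohort with the default stated world — 29 + 37 subjects,
240 volumes at TR 2 s, gBOLD band centred at 1/24 Hz, CSF = delayed
negative derivative of gBOLD plus calibrated noise, group mean
couplings −0.240 / −0.111:

```r
library(csfcoupling)

cohort <- generate_cohort(synthetic_config(seed = 1))
strength <- vapply(cohort$signals, function(p)
  as.numeric(coupling_strength(cross_correlation(p$gbold, p$csf))),
  numeric(1))

records <- cohort$records
records$coupling <- strength
records$qc_pass <- TRUE

group_ttest(records)
clinical_correlations(records)
permutation_null(lapply(cohort$signals, `[[`, "gbold"),
                 lapply(cohort$signals, `[[`, "csf"),
                 n_iter = 10000, seed = 1)
```

Output (seed 1):

```
BQD -0.222 +/- 0.186 (n=29) vs HC -0.069 +/- 0.200 (n=37)
pooled t = -3.167, df = 64, p = 0.0024
    variable       r  n p_uncorrected significant_after_correction
1       bqds -0.0435 29       0.82268                        FALSE
2   duration  0.5053 29       0.00517                         TRUE
3 daily_dose  0.0554 29       0.77520                        FALSE
4     hama14 -0.0216 29       0.91153                        FALSE
5     hamd24  0.2330 29       0.22387                        FALSE
permutation null: observed = -0.1360, p = 9.999e-05
mean curve neg peak r=-0.136 at +4 s; derivative peak r=0.140 at -2 s
```

Reading it: the BQD arm shows the more negative (stronger-magnitude)
+4 s correlation it was generated with; the pooled t detects the group
difference; the duration covariate correlates with coupling near its
configured value (0.4313); the true pairing is far outside the
subject-shuffled null (p ≈ 1/10001).  Single-cohort estimates
fluctuate — parameter recovery is verified over 50 replicate cohorts in
the acceptance suite.

## Full file-based pipeline

```r
cfg <- run_config("study", synthetic = synthetic_config(seed = 1))
run_all(cfg)   # simulate -> extract -> couple -> stats
```

writes NIfTI volumes/masks and rp-style motion files, per-subject
series TSVs, QC and exclusion logs (reason codes `motion`,
`csf_coverage`, `missing_files`), coupling curves/metrics, the
permutation-null summary, and a stats report (TSV + JSON + text).  A
CLI wrapper with subcommands `simulate | extract | couple | stats |
run-all` is in `inst/cli/csfcoupling.R`; JSON config files are read via
`read_run_config()`.

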