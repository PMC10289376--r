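# neurocurve

Quantitative morphometry of traced 3D neuron skeletons: discrete curvature
and radius estimation along neurite polylines, per-case and case–control
cohort statistics, and a fully synthetic validation cohort.

## The problem

Post-mortem brain tissue can be Golgi-stained, imaged at nanometre scale by
synchrotron nano-CT, and traced into Cartesian coordinate models — ordered
node chains with local radii, grouped into unbranched neurite segments. The
tortuosity of those neurites, measured as **curvature** κ (the reciprocal of
the local curve radius, µm⁻¹), is a structural parameter of interest in
aging and schizophrenia research: control cases show an age-declining
spread of neurite curvature, while disease cases show elevated, long-tailed
curvature distributions and thinner neurites, with case-level curvature
tracking hallucination severity.

`neurocurve` is for researchers who have such skeleton models (or want to
simulate them) and need the full quantitative chain:

1. **I/O** — a fixed-column PDB-dialect skeleton format and standard SWC
   (`read_pdb_skeleton()`, `read_swc()`, writers, strict validation).
2. **Geometry** — Menger curvature per consecutive resampled triplet,
   κ = 4A/(abc) = 1/circumradius, summarized per neurite by the
   arc-length-weighted mean (`trace_curvature_profile()`,
   `model_morphometry()`).
3. **Statistics** — case-level aggregation, two-sided Welch *t* comparisons
   between groups, Shapiro-Wilk checks, Pearson/OLS regressions against age
   and symptom scores, relative-frequency curvature histograms in 0.1 µm⁻¹
   bins (`run_cohort_analysis()`).
4. **Synthetic cohorts** — worm-like-chain neurites with exponentially
   decorrelating tangents; per-case curvature distributions are controlled
   through a closed form linking persistence length to expected Menger
   curvature, with ground truth recorded for recovery testing
   (`synthetic_cohort_spec()`, `generate_cohort()`).

## Worked example

The `analysis/` scripts run the whole study shape on a synthetic cohort:

```sh
Rscript analysis/01_simulate.R 1   # skeleton files + cohort metadata + truth
Rscript analysis/02_measure.R      # per-neurite morphometry (blind to metadata)
Rscript analysis/03_analyze.R      # cohort statistics + report bundle
```

which prints (seed 1):

```
Simulated 16 cases (32 skeleton models, 38.2 mm of neurite trace)
...
Measured 960 neurites across 32 datasets (0 excluded as too short)
Neurite curvature: median 0.375 um^-1, 95th percentile 1.204 um^-1
...
Group mean curvature: 0.580 (schizophrenia) vs 0.365 um^-1 (control), +59%
  Welch mean_curvature t =  +9.59, df = 13.22, p = 2.5e-07
  Welch sd_curvature   t =  +5.99, df = 12.05, p = 6.2e-05
  Welch mean_radius    t =  -5.72, df = 13.22, p = 6.6e-05
  sd_curvature_vs_age              r = -0.847, p = 0.0079 (n = 8)
  mean_curvature_vs_hallucination  r = +0.901, p = 1.9e-06 (n = 16)
  mean_curvature_vs_cpz            r = -0.234, p = 0.58 (n = 8)
Curvature tail mass beyond 0.8 um^-1: control 0.029, schizophrenia 0.296
```

Reading the output: the disease group's case-mean curvature is elevated
~60% over controls and its neurites are thinner (negative radius *t*); the
control-only regression recovers the negative age trend of curvature SD;
case curvature correlates with the hallucination score while the
antipsychotic-dose check stays null; and only disease cases place
appreciable curvature mass beyond 0.8 µm⁻¹. Every number is recomputed from
the generated skeleton files — stage 2 never sees the clinical metadata.

The same pieces work interactively:

```r
library(neurocurve)
co <- generate_cohort(synthetic_cohort_spec(seed = 1))
morph <- morphometry_table(lapply(co$models, model_morphometry, step = 1))
report <- run_cohort_analysis(morph, co$records)
report$comparisons       # Welch tests on case-level values
report$group_means       # case-mean and neurite-pooled conventions
```

Per-neurite curvature tables exported from a spreadsheet (long `case_id,
curvature` or one column per case) can be ingested directly with
`read_curvature_table()` and aggregated with `aggregate_curvature_table()`.

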