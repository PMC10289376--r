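---
title: "Neurite curvature morphometry: models, estimators and synthetic validation"
author: "neurocurve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neurite curvature morphometry: models, estimators and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocurve)
```

## The scientific problem

Golgi-stained neurons imaged by synchrotron nano-CT can be traced into 3D
coordinate models: ordered chains of nodes with a local radius, grouped into
unbranched neurite segments. The tortuosity of those neurites — quantified
as *curvature*, the reciprocal of the local curve radius, in µm⁻¹ — differs
between individuals, declines in spread with age in non-psychiatric
controls, and is elevated in schizophrenia, where per-case distributions
grow long tails and neurites are thinner. `neurocurve` implements the
complete quantitative side of such a study: skeleton file I/O, discrete
curvature and radius estimation per neurite, per-case and per-group
statistics, and a synthetic cohort generator with known ground truth so the
whole pipeline is testable without access to post-mortem trace data.

## Skeleton representation and file formats

A `skeleton_model` is a set of `neurite_trace` objects: ordered, pairwise
non-coincident 3D nodes (µm) with positive radii, labelled as neurite, soma
or other. Branching is represented by starting a new trace, duplicating the
branch node, so every trace is an independent polyline — curvature is a
per-unbranched-neurite quantity (one summary value per trace).

Two formats are supported:

* a fixed-column **PDB dialect**: one chain per trace, `TER` separated (so
  models with more than 62 traces remain representable), residue name
  encoding the constituent kind (`NEU`/`SOM`/`OTH`), node order in the
  residue number, coordinates interpreted directly as µm, and the node
  radius in the occupancy column at two decimals. The mapping the original
  tracing tool uses inside its PDB output is not published; this dialect is
  a documented, round-trippable choice, and `dialect_options` allows
  remapping (e.g. radius from the B-factor column). Writing refuses values
  that do not fit the fixed columns rather than truncating.
* standard 7-column **SWC**, split into unbranched traces at roots, branch
  points, and type-code changes. Node ids are renumbered on read because
  duplicated branch nodes cannot keep the original ids unique model-wide.

Validation (`validate_model()`) reports *all* violations — short traces,
coincident consecutive nodes, nonpositive radii, duplicate ids — rather
than stopping at the first, because traced models are hand-made artifacts
whose defects cluster.

## Curvature estimation

The estimator is **Menger curvature**: for three consecutive points the
curvature of their circumscribed circle, κ = 4A/(abc). This is the direct
discrete realization of "reciprocal of the curve radius"; collinear triplets
give exactly zero. Traces are first resampled to uniform arc-length spacing
(`step`, default 1 µm) with endpoints preserved, because raw tracing nodes
are irregularly spaced and Menger curvature on irregular triplets is
dominated by the local sampling pattern rather than the curve. The default
of 1 µm was chosen once: nano-CT voxel pitch is sub-µm, so 1 µm smooths
node-placement jitter while still resolving tortuosity on the 0–2 µm⁻¹
scale of interest. Halving the step perturbs smooth-fixture curvature by
well under 1% (tested on circle and helix fixtures with closed-form
curvature 1/R and a/(a²+b²)).

Per-neurite summaries: the **arc-length-weighted mean** of point curvatures
is the primary summary (one dot per neurite in the study's bee-swarm
plots); median and maximum are selectable alternatives, since the original
definition of the per-neurite value is not published. No curvature is
evaluated at the two terminal nodes (no one-sided estimates). The
per-neurite radius is the arc-length-weighted mean node radius. Traces
shorter than one triplet at the chosen step are flagged excluded and
counted, never silently dropped.

Estimator guarantees covered by tests: equality with an independent
least-squares circumcenter solve to 1e-8 relative on random triplets; scale
covariance (κ → κ/s, lengths → s·L when coordinates and step scale by s);
rigid-motion invariance to 1e-9.

## Cohort statistics

The **unit of analysis is the case**: neurites are pooled across a case's
datasets (dataset "S8A" → case "S8"), each case is reduced to summary
statistics (mean, sample SD, median, max of neurite curvature; mean radius;
total length), and groups are compared on case-level values with the
two-sided Welch *t*-test (n = 8 vs 8, Welch–Satterthwaite df). A guard test
verifies that inflating one case's neurite count does not change its weight.
Two "group mean" conventions exist — mean of case means versus pooling all
neurites — and both are reported, the case-mean version as primary.

Shapiro-Wilk checks of the per-case curvature SDs justify the *t*-test on
deviations, mirroring the source analysis. Regressions are ordinary least
squares with Pearson's r and a two-sided *t*-distributed p (n−2 df): the
age regression of curvature SD is fitted on controls only by default (the
aging trend is a control phenomenon from which disease cases deviate; an
all-cases variant is a flag), the hallucination-score regression uses all
16 cases by default (controls enter at score 0; a disease-only variant is a
flag), and the chlorpromazine-equivalent-dose regression is reported as a
null check without inference emphasis. No multiple-testing correction is
applied; the report states the number of tests performed.

Histograms use right-open 0.1 µm⁻¹ bins from zero with frequencies relative
to the case's included neurites, plus the tail mass at ≥ 0.8 µm⁻¹ — the
threshold beyond which control distributions are essentially empty, making
tail mass a one-number summary of the long-tail phenotype. Degenerate
inputs fail loudly: zero-variance groups raise an error rather than
returning infinite statistics, because in this workflow they indicate a
misconfigured simulation, not data.

## The synthetic cohort generator

Real trace data for such studies are not publicly deposited, so the
generator is a first-class module that emulates the statistical structure
the analysis assumes, with recorded ground truth.

**Geometry.** Neurites are worm-like chains: unit tangents perform a random
walk on the sphere with von Mises–Fisher (vMF) deflections whose
concentration is set so tangent autocorrelation decays as exp(−s/Lp) with
persistence length Lp. For uniform segment length h the Menger curvature of
a consecutive triplet is exactly 2·sin(θ/2)/h, giving a closed form for the
expected point curvature as a function of the vMF concentration (upper
bound 4/(3h) for fully decorrelated tangents). The generator inverts this
closed form: each neurite receives a target mean curvature, mapped to its
persistence length, so per-case curvature distributions are controlled
directly and recorded as truth. Expected mean curvature is strictly
decreasing in persistence length (tested on a grid, and against Monte
Carlo).

**Cohort structure** (defaults chosen once as the emulated study
conditions; all configurable in `synthetic_cohort_spec()`):

* 8 cases per group, 60 neurites per case split over 2 datasets, trace
  lengths lognormal around 40 µm (cv 0.25), step 1 µm. 60 neurites per case
  keeps replicate simulation studies tractable while every group-level
  effect remains decisively detectable; the parameter-recovery test runs at
  200 neurites per case.
* Controls: case mean curvature lognormal around 0.36 µm⁻¹ (between-case
  log-sd 0.06); within-case neurite SD declines linearly with age
  (0.24 µm⁻¹ at age 45, −0.003 µm⁻¹ per year, ages 42–81), reproducing the
  age-compression of the curvature distribution.
* Disease cases: case mean elevated ×1.6 (between-case log-sd 0.08);
  per-neurite targets are a two-component mixture — bulk at the control
  level plus a 30% short-persistence tail component — producing long-tailed
  distributions without moving the bulk mode. Radii thinned ×0.85 from the
  control 0.30 µm.
* Symptom model: hallucination score affine in the case's generating mean
  curvature plus Gaussian noise (sd 2.5), truncated at zero; controls are
  exactly zero. Dose is drawn independently of curvature — a built-in null.
* Targets are clipped into the estimator's feasible range (0, 4/(3·step));
  the clipped gamma draws are mean-adjusted so the realized case mean equals
  the declared one — without this the declared ×1.6 contrast would be
  biased low.

The between-case dispersions and clinical noise scales were dimensioned so
that the declared effects are recovered at the study's size with the
strength the emulated figures show: across replicate cohorts the recovered
group ratio is 1.60 ± 0.08, the control age regression gives r ≈ −0.8, and
the score regression r ≈ 0.8.

**Reproducibility.** One global seed expands into per-case substreams
(deterministic hash of seed, group and case index), so a case's data are
identical regardless of how many cases are generated, and
simulate→measure→analyze is byte-deterministic end to end.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: tracing errors and node-placement jitter, branch
topology (every synthetic neurite is unbranched), spatially structured
tissue context (somata are token blobs used only to test kind filtering),
non-stationary curvature along a neurite, the radius–curvature coupling
within neurites, and realistic per-case neurite counts. Results on
synthetic cohorts validate the *pipeline*, not the biology.

## Simulation sizes and numerical choices

Property and calibration tests use sizes chosen to make their conclusions
statistically decisive: 1000 random triplets for the geometry oracle,
500 zero-effect cohorts (reduced size: 10 neurites per case, 15 µm traces —
null p-value uniformity does not depend on cohort size) for the
Kolmogorov–Smirnov calibration check, 200 default-size cohorts for effect
and age-trend recovery, and 200 neurites per case for per-case parameter
recovery within three Monte-Carlo standard errors. The acceptance script
runs one full default cohort end to end through the on-disk pipeline.

Numerical details worth knowing: curvature targets live in
(0.02, 0.98·4/3) µm⁻¹ and the vMF concentration is interpolated on a
1200-point monotone grid over log-concentration (relative error ~1e-4);
resampling snaps the final node to the exact trace end when the residual is
below 1e-9 of the length; histogram binning snaps values within 1e-9 of a
bin edge into the upper (right-open) bin to keep decimal boundaries exact
in floating point.

## Known limitations

* The PDB dialect is a documented assumption, not a published
  specification; files from other tracing tools may need `dialect_options`
  or conversion through SWC.
* Per-neurite curvature workbooks are ingested from plain-text exports
  (CSV/TSV, long or column-per-case layout); spreadsheet binaries must be
  exported first.
* The per-neurite summary hides within-neurite curvature structure; the
  full point-curvature profiles are available per trace for finer analyses.
* Group comparisons assume two groups named `schizophrenia`/`control`; the
  statistics themselves are generic, but the report layout is
  study-shaped.
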