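#!/usr/bin/env Rscript

# Stage 2: measure per-neurite morphometry.
#
# Reads every skeleton model under results/cohort/models/ and computes the
# per-neurite structural parameters (Menger curvature along the resampled
# trace, arc-length-weighted radius, trace length). This stage sees only
# geometry - the cohort metadata is never read here, mirroring the blinded
# model-building firewall of the original workflow.
#
# Usage: Rscript analysis/02_measure.R

suppressPackageStartupMessages(library(neurocurve))

morph <- pipeline_measure("results/cohort/models", "results/morphometry.csv",
                          step = 1)
inc <- !morph$excluded_flag
cat(sprintf("Measured %d neurites across %d datasets (%d excluded as too short)\n",
            sum(inc), length(unique(morph$dataset_id)), sum(!inc)))
cat(sprintf("Neurite curvature: median %.3f um^-1, 95th percentile %.3f um^-1\n",
            stats::median(morph[["neurite_curvature_um-1"]][inc]),
            stats::quantile(morph[["neurite_curvature_um-1"]][inc], 0.95)))
cat(sprintf("Neurite radius:    median %.3f um\n",
            stats::median(morph[["neurite_radius_um"]][inc])))
cat("Output: results/morphometry.csv (+ _excluded.csv sidecar)\n")
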