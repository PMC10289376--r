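#!/usr/bin/env Rscript

# Stage 3: cohort statistics.
#
# Joins the per-neurite morphometry with the cohort metadata and reproduces
# the study-level analyses: per-case aggregation, Welch group comparisons
# of curvature / curvature SD / radius, the control-only age regression of
# curvature SD, the hallucination-score regression, the antipsychotic-dose
# null check, and per-case 0.1 um^-1 curvature histograms.
#
# Usage: Rscript analysis/03_analyze.R

suppressPackageStartupMessages(library(neurocurve))

report <- pipeline_analyze("results/morphometry.csv",
                           "results/cohort/cohort.csv",
                           "results/report")

gm <- report$group_means
scz <- gm$case_mean[gm$group == "schizophrenia"]
ctl <- gm$case_mean[gm$group == "control"]
cmp <- report$comparisons

cat(sprintf("Group mean curvature: %.3f (schizophrenia) vs %.3f um^-1 (control), %+.0f%%\n",
            scz, ctl, 100 * (scz / ctl - 1)))
for (i in seq_len(nrow(cmp)))
  cat(sprintf("  Welch %-14s t = %+6.2f, df = %5.2f, p = %.2g\n",
              cmp$parameter[i], cmp$t[i], cmp$df[i], cmp$p[i]))
reg <- report$regressions
for (i in seq_len(nrow(reg)))
  cat(sprintf("  %-32s r = %+.3f, p = %.2g (n = %d)\n",
              reg$analysis[i], reg$pearson_r[i], reg$p[i], reg$n[i]))
tails <- vapply(report$histograms, `[[`, 0, "tail_mass")
cat(sprintf("Curvature tail mass beyond 0.8 um^-1: control %.3f, schizophrenia %.3f\n",
            mean(tails[startsWith(names(tails), "N")]),
            mean(tails[startsWith(names(tails), "S")])))
cat("Outputs: results/report/{case_table,comparisons,regressions,normality,histograms}.csv, summary.json\n")
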