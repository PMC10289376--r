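#' Run the full cohort analysis
#'
#' Reproduces the study-level statistics from a per-neurite morphometry
#' table and the cohort records:
#' \itemize{
#'   \item per-case aggregation (neurites pooled across a case's datasets);
#'   \item two-sided Welch comparisons between groups for mean curvature,
#'     SD of curvature, and mean radius (case-level unit of analysis);
#'   \item Shapiro-Wilk normality checks of the per-case curvature SDs,
#'     per group;
#'   \item regressions: SD of curvature on age (controls only by default,
#'     the control aging trend), mean curvature on hallucination score
#'     (all cases by default), and mean curvature on
#'     chlorpromazine-equivalent dose (cases with a recorded dose;
#'     reported as a null check without inference emphasis);
#'   \item per-case relative-frequency curvature histograms (0.1 um^-1
#'     bins) with tail mass beyond 0.8 um^-1;
#'   \item group mean curvature under both pooling conventions.
#' }
#' No multiple-testing correction is applied; the number of tests performed
#' is reported alongside. The analysis is deterministic.
#'
#' @param morph_df Per-neurite data frame ([morphometry_table()] layout).
#' @param records Cohort records ([read_cohort()] layout).
#' @param age_regression_population `"control"` (default) or `"all"`.
#' @param score_regression_population `"all"` (default) or `"schizophrenia"`.
#' @param bin_width Histogram bin width (1/um), default 0.1.
#' @param tail_threshold Histogram tail threshold (1/um), default 0.8.
#' @return An object of class `cohort_report`.
#' @export
run_cohort_analysis <- function(morph_df, records,
                                age_regression_population = c("control", "all"),
                                score_regression_population = c("all", "schizophrenia"),
                                bin_width = 0.1, tail_threshold = 0.8) {
  age_regression_population <- match.arg(age_regression_population)
  score_regression_population <- match.arg(score_regression_population)
  validate_cohort(records)
  cases_present <- unique(case_of_dataset(morph_df$dataset_id))
  missing <- setdiff(cases_present, records$case_id)
  if (length(missing))
    stop("no cohort record for case(s): ", paste(missing, collapse = ", "))

  case_table <- aggregate_cases(morph_df)
  comparisons <- do.call(rbind, lapply(
    c("mean_curvature", "sd_curvature", "mean_radius"),
    function(p) group_compare(case_table, records, p)))

  merged <- merge(case_table, records, by = "case_id")
  normality <- do.call(rbind, lapply(split(merged, merged$group), function(g) {
    sw <- normality_check(g$sd_curvature)
    data.frame(group = g$group[1L], parameter = "sd_curvature",
               W = sw$W, p = sw$p, n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(normality) <- NULL

  age_cases <- if (age_regression_population == "control")
    case_table[case_table$case_id %in% records$case_id[records$group == "control"], ]
  else case_table
  reg_age <- correlate(age_cases, records, "age", "sd_curvature")

  score_cases <- if (score_regression_population == "all") case_table
  else case_table[case_table$case_id %in%
                  records$case_id[records$group == "schizophrenia"], ]
  reg_score <- correlate(score_cases, records,
                         "hallucination_score", "mean_curvature")
  # flipped orientation is also informative downstream; r and p are symmetric

  dosed <- records$case_id[!is.na(records$cpz_dose)]
  reg_cpz <- if (length(dosed) >= 3L)
    correlate(case_table[case_table$case_id %in% dosed, ], records,
              "cpz_dose", "mean_curvature")
  else NULL
  regressions <- rbind(
    cbind(analysis = "sd_curvature_vs_age", reg_age),
    cbind(analysis = "mean_curvature_vs_hallucination", reg_score),
    if (!is.null(reg_cpz)) cbind(analysis = "mean_curvature_vs_cpz", reg_cpz))

  case_ids <- sort(unique(case_of_dataset(morph_df$dataset_id)))
  histograms <- lapply(case_ids, function(cid) {
    rows <- case_of_dataset(morph_df$dataset_id) == cid
    curvature_histogram(morph_df[rows, , drop = FALSE], bin_width = bin_width,
                        tail_threshold = tail_threshold, case_id = cid)
  })
  names(histograms) <- case_ids

  structure(list(
    case_table = case_table,
    comparisons = comparisons,
    normality = normality,
    regressions = regressions,
    histograms = histograms,
    group_means = group_mean_curvature(case_table, records,
                                       values = morph_long_values(morph_df)),
    n_tests = nrow(comparisons) + nrow(regressions),
    options = list(age_regression_population = age_regression_population,
                   score_regression_population = score_regression_population,
                   bin_width = bin_width, tail_threshold = tail_threshold)),
    class = "cohort_report")
}

morph_long_values <- function(morph_df) {
  inc <- !morph_df$excluded_flag
  data.frame(case_id = case_of_dataset(morph_df$dataset_id)[inc],
             curvature = morph_df[["neurite_curvature_um-1"]][inc],
             stringsAsFactors = FALSE)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", nrow(x$case_table), "cases;",
      x$n_tests, "tests (no multiplicity correction)\n")
  cat("Group comparisons (Welch, two-sided):\n")
  print(x$comparisons, digits = 4)
  cat("Regressions:\n")
  print(x$regressions[, c("analysis", "pearson_r", "p", "slope", "n")],
        digits = 4)
  invisible(x)
}

#' Histograms of a report as one long data frame
#' @param report A `cohort_report`.
#' @return Data frame: case_id, bin_lo, bin_hi, relative_frequency.
#' @export
histogram_table <- function(report) {
  do.call(rbind, lapply(report$histograms, function(h) {
    nb <- length(h$relative_frequencies)
    data.frame(case_id = h$case_id,
               bin_lo = h$bin_edges[seq_len(nb)],
               bin_hi = h$bin_edges[seq_len(nb) + 1L],
               relative_frequency = h$relative_frequencies,
               stringsAsFactors = FALSE)
  }))
}

#' JSON-ready summary of a cohort report, keyed by figure
#'
#' Keys mirror the study's figures: `fig2b` (age regression of curvature
#' SD), `fig3a` (group comparison of mean curvature), `fig3b` (radius),
#' `fig4` (per-case tail mass of the curvature distributions), `fig5`
#' (hallucination-score regression), `s5` (chlorpromazine-dose null check),
#' plus the SD comparison and the dual-convention group means.
#'
#' @param report A `cohort_report`.
#' @return Nested list suitable for [jsonlite::write_json()].
#' @export
report_summary <- function(report) {
  cmp <- function(p) as.list(report$comparisons[report$comparisons$parameter == p,
                                                c("mean_schizophrenia",
                                                  "mean_control", "t", "df", "p")])
  reg <- function(a) {
    r <- report$regressions[report$regressions$analysis == a, ]
    if (!nrow(r)) return(NULL)
    as.list(r[, c("pearson_r", "p", "slope", "intercept", "n")])
  }
  list(
    fig2b = reg("sd_curvature_vs_age"),
    fig3a = cmp("mean_curvature"),
    fig3b = cmp("mean_radius"),
    sd_comparison = cmp("sd_curvature"),
    fig4 = lapply(report$histograms, function(h)
      list(tail_mass = h$tail_mass, n = h$n)),
    fig5 = reg("mean_curvature_vs_hallucination"),
    s5 = reg("mean_curvature_vs_cpz"),
    group_means = report$group_means,
    normality = report$normality,
    n_tests = report$n_tests)
}
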