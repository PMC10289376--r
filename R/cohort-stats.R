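#' Aggregate per-neurite morphometry into one case summary
#'
#' Pools the per-neurite summary values of all datasets belonging to one
#' case and computes the case-level statistics used by the group tests:
#' number of included neurites, mean / sample SD (n - 1 denominator) /
#' median / max / min of neurite curvature, mean neurite radius, total
#' trace length. Excluded (too-short) neurites do not contribute.
#'
#' @param profiles List of [trace_curvature_profile()] objects, a
#'   `morphometry` object, or a per-neurite data frame as produced by
#'   [morphometry_table()].
#' @param case_id Case label, e.g. `"S8"`.
#' @return A one-row data frame of class `case_morphometry`.
#' @export
aggregate_case <- function(profiles, case_id) {
  if (inherits(profiles, "morphometry")) profiles <- profiles$profiles
  if (is.data.frame(profiles)) {
    inc <- !profiles$excluded_flag
    curv <- profiles[["neurite_curvature_um-1"]][inc]
    rad <- profiles[["neurite_radius_um"]][inc]
    len <- profiles[["trace_length_um"]][inc]
  } else {
    inc <- !vapply(profiles, `[[`, TRUE, "excluded")
    curv <- vapply(profiles[inc], `[[`, 0, "neurite_curvature")
    rad <- vapply(profiles[inc], `[[`, 0, "neurite_radius")
    len <- vapply(profiles[inc], `[[`, 0, "trace_length")
  }
  case_aggregate_values(case_id, curv, rad, len)
}

case_aggregate_values <- function(case_id, curv, rad = NULL, len = NULL) {
  if (length(curv) < 2L)
    stop("case ", case_id, ": fewer than 2 included neurites (",
         length(curv), ")")
  out <- data.frame(
    case_id = case_id,
    n_neurites = length(curv),
    mean_curvature = mean(curv),
    sd_curvature = stats::sd(curv),
    median_curvature = stats::median(curv),
    max_curvature = max(curv),
    min_curvature = min(curv),
    mean_radius = if (length(rad)) mean(rad) else NA_real_,
    total_length = if (length(len)) sum(len) else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("case_morphometry", class(out))
  out
}

#' Aggregate a per-neurite table into the per-case table
#'
#' Dataset labels are mapped to cases with [case_of_dataset()] (dataset
#' "S8A" belongs to case "S8"), so a case's neurites are pooled across its
#' datasets before any statistic is computed.
#'
#' @param morph_df Per-neurite data frame ([morphometry_table()] layout).
#' @return Data frame with one row per case.
#' @export
aggregate_cases <- function(morph_df) {
  case <- case_of_dataset(morph_df$dataset_id)
  out <- do.call(rbind, lapply(split(morph_df, case), function(d)
    aggregate_case(d, case_id = case_of_dataset(d$dataset_id[1L]))))
  rownames(out) <- NULL
  out[order(out$case_id), , drop = FALSE]
}

#' Welch comparison of a case-level parameter between groups
#'
#' Two-sided Welch's t-test (unequal variances, Welch-Satterthwaite degrees
#' of freedom) on case-level values: the unit of analysis is the case, never
#' the neurite, so each case enters with weight one regardless of how many
#' neurites it contributes. The t statistic is oriented as
#' schizophrenia minus control.
#'
#' @param cases Per-case data frame ([aggregate_cases()] layout).
#' @param records Cohort records data frame ([read_cohort()] layout).
#' @param parameter Column of `cases` to compare (e.g. `"mean_curvature"`,
#'   `"sd_curvature"`, `"mean_radius"`).
#' @return A one-row data frame: parameter, group means, t, df, p,
#'   sidedness, group sizes.
#' @export
group_compare <- function(cases, records, parameter) {
  if (!parameter %in% names(cases))
    stop("parameter '", parameter, "' not present in case table")
  d <- merge(cases, records[, c("case_id", "group")], by = "case_id")
  if (anyNA(d[[parameter]]))
    stop("parameter '", parameter, "' missing for case(s) ",
         paste(d$case_id[is.na(d[[parameter]])], collapse = ", "))
  x <- d[[parameter]][d$group == "schizophrenia"]
  y <- d[[parameter]][d$group == "control"]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 cases (got ", length(x), " vs ",
         length(y), ")")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("degenerate variance: both groups are constant in '", parameter, "'")
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  data.frame(parameter = parameter,
             mean_schizophrenia = mean(x), mean_control = mean(y),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, sidedness = "two.sided",
             n_schizophrenia = length(x), n_control = length(y),
             stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality check of case-level values
#'
#' @param values Numeric vector, 3 to 5000 non-missing values.
#' @return List with `W` and `p`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (stats::sd(values) == 0) stop("zero variance: normality check undefined")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Pearson correlation and OLS regression between case-level fields
#'
#' Merges the per-case morphometry with the cohort records and regresses
#' `y_field` on `x_field`: Pearson's r with a two-sided p-value (t
#' distribution, n - 2 df) plus the ordinary least-squares slope and
#' intercept. Pairs with a missing value in either field are dropped.
#'
#' @param cases Per-case data frame (may be `NULL` if both fields are in
#'   `records`).
#' @param records Cohort records data frame (may be `NULL` likewise).
#' @param x_field Predictor column name.
#' @param y_field Response column name.
#' @return One-row data frame: predictor, response, pearson_r, p, slope,
#'   intercept, n.
#' @export
correlate <- function(cases, records, x_field, y_field) {
  d <- if (is.null(records)) cases
       else if (is.null(cases)) records
       else merge(cases, records, by = "case_id")
  for (f in c(x_field, y_field))
    if (!f %in% names(d)) stop("field '", f, "' not found")
  keep <- !is.na(d[[x_field]]) & !is.na(d[[y_field]])
  x <- d[[x_field]][keep]; y <- d[[y_field]][keep]
  if (length(x) < 3L)
    stop("need at least 3 paired observations (got ", length(x), ")")
  if (stats::sd(x) == 0) stop("zero variance in predictor '", x_field, "'")
  if (stats::sd(y) == 0) stop("zero variance in response '", y_field, "'")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  data.frame(predictor = x_field, response = y_field,
             pearson_r = unname(ct$estimate), p = ct$p.value,
             slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             n = length(x), stringsAsFactors = FALSE)
}

#' Relative-frequency histogram of neurite curvature
#'
#' Right-open bins of width `bin_width` starting at 0 (a value equal to an
#' edge falls in the upper bin); frequencies are relative to the number of
#' included neurites and sum to 1. Also reports the tail mass at or beyond
#' `tail_threshold` (control cases show almost no curvature beyond
#' 0.8 um^-1, so the tail mass separates long-tailed from compact
#' distributions).
#'
#' @param x Numeric vector of per-neurite curvatures, a `morphometry`
#'   object, or a per-neurite data frame ([morphometry_table()] layout).
#' @param bin_width Bin width in 1/micrometres (default 0.1).
#' @param tail_threshold Tail cut-off in 1/micrometres (default 0.8).
#' @param case_id Optional label attached to the result.
#' @return List of class `curvature_histogram`: `bin_edges` (length
#'   nbins + 1), `relative_frequencies`, `tail_mass`, `n`, `case_id`.
#' @export
curvature_histogram <- function(x, bin_width = 0.1, tail_threshold = 0.8,
                                case_id = NULL) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a positive number")
  if (inherits(x, "morphometry")) x <- as.data.frame(x)
  if (is.data.frame(x))
    x <- x[["neurite_curvature_um-1"]][!x$excluded_flag]
  x <- x[!is.na(x)]
  if (!length(x)) stop("no included neurites to histogram")
  if (any(x < 0)) stop("negative curvature value")
  idx <- floor(x / bin_width)
  # snap values within rounding error of the next edge into the upper bin
  bump <- ((idx + 1) * bin_width - x) <= bin_width * 1e-9
  idx[bump] <- idx[bump] + 1
  nb <- max(idx) + 1
  counts <- tabulate(idx + 1, nbins = nb)
  structure(list(bin_edges = (0:nb) * bin_width,
                 relative_frequencies = counts / length(x),
                 tail_mass = mean(x >= tail_threshold * (1 - 1e-12)),
                 tail_threshold = tail_threshold,
                 n = length(x), case_id = case_id),
            class = "curvature_histogram")
}

#' @export
print.curvature_histogram <- function(x, ...) {
  cat("<curvature_histogram>", if (!is.null(x$case_id)) x$case_id else "",
      "-", x$n, "neurites,", length(x$relative_frequencies), "bins of",
      x$bin_edges[2L], "um^-1, tail mass (>=", x$tail_threshold, ") =",
      format(x$tail_mass, digits = 4), "\n")
  invisible(x)
}
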