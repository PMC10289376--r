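# Pipeline stages mirror the organizational firewall of a blinded
# morphometry study: the measurement stage sees only skeleton files and
# never reads clinical metadata; case information enters at the analysis
# stage only.

#' Simulate a synthetic cohort to disk
#'
#' Writes one PDB-dialect skeleton file per dataset, the cohort metadata
#' CSV, the ground-truth table, and the generating spec.
#'
#' @param spec A [synthetic_cohort_spec()] (or a list of its arguments).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [generate_cohort()] result.
#' @export
pipeline_simulate <- function(spec, out_dir) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(synthetic_cohort_spec, spec)
  dir.create(file.path(out_dir, "models"), recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  for (m in cohort$models)
    write_pdb_skeleton(m, file.path(out_dir, "models",
                                    paste0(m$dataset_id, ".pdb")))
  write_cohort(cohort$records, file.path(out_dir, "cohort.csv"))
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(spec), file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Measure morphometry of every skeleton model in a directory
#'
#' Reads every `*.pdb` skeleton file, computes per-neurite curvature
#' profiles, and writes the tidy per-neurite table plus an exclusion
#' sidecar listing traces too short to analyze. By default any validation
#' error aborts the run; with `skip_invalid = TRUE` offending files are
#' dropped with a warning.
#'
#' @param models_dir Directory of `.pdb` skeleton files.
#' @param out_csv Output path of the per-neurite CSV.
#' @param step Resampling interval, micrometres.
#' @param summary Per-neurite curvature summary (`"mean"`, `"median"`,
#'   `"max"`).
#' @param skip_invalid Drop unreadable/invalid files instead of aborting?
#' @param dialect_options Passed to [read_pdb_skeleton()].
#' @return Invisibly, the per-neurite data frame.
#' @export
pipeline_measure <- function(models_dir, out_csv, step = 1, summary = "mean",
                             skip_invalid = FALSE, dialect_options = list()) {
  files <- sort(list.files(models_dir, pattern = "\\.pdb$", full.names = TRUE))
  if (!length(files)) stop("no .pdb skeleton files in ", models_dir)
  morphos <- list()
  for (f in files) {
    m <- tryCatch(model_morphometry(read_pdb_skeleton(f, dialect_options),
                                    step = step, summary = summary),
                  error = function(e) e)
    if (inherits(m, "error")) {
      if (skip_invalid) { warning("skipping ", f, ": ", conditionMessage(m)) ; next }
      stop("failed on ", f, ": ", conditionMessage(m))
    }
    morphos[[f]] <- m
  }
  if (!length(morphos)) stop("no valid skeleton files in ", models_dir)
  df <- morphometry_table(morphos)
  utils::write.csv(df, out_csv, row.names = FALSE, quote = FALSE)
  excl <- df[df$excluded_flag, c("dataset_id", "trace_id"), drop = FALSE]
  utils::write.csv(excl, sub("\\.csv$", "_excluded.csv", out_csv),
                   row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a per-neurite morphometry CSV
#' @param path CSV written by [pipeline_measure()].
#' @return Per-neurite data frame.
#' @export
read_morphometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("dataset_id", "trace_id", "trace_length_um",
            "neurite_curvature_um-1", "neurite_radius_um", "excluded_flag")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("morphometry table lacks column(s): ",
                         paste(miss, collapse = ", "))
  d$excluded_flag <- as.logical(d$excluded_flag)
  d
}

#' Analyze a measured cohort and write the report bundle
#'
#' Runs [run_cohort_analysis()] on a morphometry CSV and a cohort CSV and
#' writes the report directory: `case_table.csv`, `comparisons.csv`,
#' `regressions.csv`, `normality.csv`, `histograms.csv`, `summary.json`
#' (keyed by figure) and `MANIFEST.json` (package version, options, input
#' checksums).
#'
#' @param morphometry_csv Per-neurite CSV from [pipeline_measure()].
#' @param cohort_csv Cohort metadata CSV.
#' @param out_dir Report directory (created if needed).
#' @param ... Passed to [run_cohort_analysis()].
#' @return Invisibly, the `cohort_report`.
#' @export
pipeline_analyze <- function(morphometry_csv, cohort_csv, out_dir, ...) {
  morph <- read_morphometry(morphometry_csv)
  records <- read_cohort(cohort_csv)
  report <- run_cohort_analysis(morph, records, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                        row.names = FALSE, quote = FALSE)
  wr(report$case_table, "case_table.csv")
  wr(report$comparisons, "comparisons.csv")
  wr(report$regressions, "regressions.csv")
  wr(report$normality, "normality.csv")
  wr(histogram_table(report), "histograms.csv")
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- list(
    package = "neurocurve",
    version = as.character(utils::packageVersion("neurocurve")),
    options = report$options,
    inputs = list(
      morphometry_csv = unname(tools::md5sum(morphometry_csv)),
      cohort_csv = unname(tools::md5sum(cohort_csv))))
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE)
  invisible(report)
}
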