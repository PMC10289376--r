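#' Read cohort metadata records
#'
#' CSV with header `case_id,group,age,sex,hallucination_score,cpz_dose`.
#' `group` must be `schizophrenia` or `control`; control cases must carry a
#' hallucination score of exactly 0 (controls are assigned zero by
#' construction); `cpz_dose` (chlorpromazine-equivalent dose, mg/day) may be
#' empty.
#'
#' @param path CSV path.
#' @return Data frame of cohort records.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(d)
  d
}

validate_cohort <- function(d) {
  need <- c("case_id", "group", "age", "sex", "hallucination_score", "cpz_dose")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("cohort table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !d$group %in% c("schizophrenia", "control")
  if (any(bad)) stop("unknown group for case(s) ",
                     paste(d$case_id[bad], collapse = ", "))
  if (anyDuplicated(d$case_id))
    stop("duplicate case_id: ",
         paste(unique(d$case_id[duplicated(d$case_id)]), collapse = ", "))
  ctl <- d$group == "control"
  if (any(is.na(d$hallucination_score[ctl]) | d$hallucination_score[ctl] != 0))
    stop("control case(s) with nonzero hallucination score: ",
         paste(d$case_id[ctl & (is.na(d$hallucination_score) |
                                d$hallucination_score != 0)], collapse = ", "))
  invisible(d)
}

#' Write cohort metadata records
#' @param records Cohort data frame ([read_cohort()] layout).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(records, path) {
  validate_cohort(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-neurite curvature table (workbook export)
#'
#' Ingests per-neurite curvature values shaped like a supplementary
#' workbook exported to plain text, in either of two layouts, auto-detected:
#' \describe{
#'   \item{long}{columns `case_id` and `curvature` (or
#'     `neurite_curvature_um-1`), one row per neurite;}
#'   \item{wide}{one column per case (header = case label), columns of
#'     unequal length padded with empty cells.}
#' }
#' Files ending in `.tsv`/`.txt` are read tab-separated, otherwise
#' comma-separated.
#'
#' @param path Path to the exported table.
#' @return Long data frame with columns `case_id`, `curvature` (1/um).
#' @export
read_curvature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  curv_col <- intersect(c("curvature", "neurite_curvature_um-1"), names(d))
  if ("case_id" %in% names(d) && length(curv_col)) {
    out <- data.frame(case_id = as.character(d$case_id),
                      curvature = as.numeric(d[[curv_col[1L]]]),
                      stringsAsFactors = FALSE)
  } else {
    vals <- lapply(names(d), function(cn) {
      v <- suppressWarnings(as.numeric(d[[cn]]))
      v[!is.na(v)]
    })
    if (!any(lengths(vals)))
      stop("could not interpret ", path,
           " as a curvature table (no numeric case columns, ",
           "and no case_id/curvature columns)")
    out <- data.frame(
      case_id = rep(names(d), lengths(vals)),
      curvature = unlist(vals), stringsAsFactors = FALSE)
  }
  out <- out[!is.na(out$curvature), , drop = FALSE]
  if (any(out$curvature < 0)) stop("negative curvature value in ", path)
  rownames(out) <- NULL
  out
}

#' Aggregate a long curvature table per case
#'
#' @param curv_table Long data frame from [read_curvature_table()].
#' @return Per-case data frame (as [aggregate_cases()], radius and length
#'   columns are `NA` since the table carries curvature only).
#' @export
aggregate_curvature_table <- function(curv_table) {
  out <- do.call(rbind, lapply(split(curv_table, curv_table$case_id),
                               function(d) case_aggregate_values(d$case_id[1L],
                                                                 d$curvature)))
  rownames(out) <- NULL
  out[order(out$case_id), , drop = FALSE]
}

#' Group mean curvature under both pooling conventions
#'
#' A "group mean" can pool the per-case means (each case weighted equally;
#' the primary convention here) or pool every neurite of the group (cases
#' weighted by neurite count). Both are reported so the conventions can be
#' compared directly.
#'
#' @param case_table Per-case data frame with `mean_curvature`.
#' @param records Cohort records.
#' @param values Optional long per-neurite table (`case_id`, `curvature`)
#'   for the pooled convention; if omitted, the pooled mean is the
#'   neurite-count-weighted mean of case means.
#' @return Data frame: group, case_mean, pooled_mean, n_cases, n_neurites.
#' @export
group_mean_curvature <- function(case_table, records, values = NULL) {
  d <- merge(case_table, records[, c("case_id", "group")], by = "case_id")
  do.call(rbind, lapply(split(d, d$group), function(g) {
    pooled <- if (!is.null(values)) {
      mean(values$curvature[values$case_id %in% g$case_id])
    } else {
      stats::weighted.mean(g$mean_curvature, g$n_neurites)
    }
    data.frame(group = g$group[1L],
               case_mean = mean(g$mean_curvature),
               pooled_mean = pooled,
               n_cases = nrow(g), n_neurites = sum(g$n_neurites),
               stringsAsFactors = FALSE)
  }))
}
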