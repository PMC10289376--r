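#' Construct a neurite trace
#'
#' A trace is one unbranched polyline of skeleton nodes. Branching structures
#' are represented as several traces (a branch node is duplicated into each
#' child trace), so every trace can be analyzed as an independent curve.
#'
#' @param xyz Numeric matrix, one row per node, three columns (x, y, z) in
#'   micrometres.
#' @param radius Numeric vector of per-node radii (neurite half-thickness,
#'   micrometres). Recycled if length 1.
#' @param kind Constituent kind: `"neurite"`, `"soma"` or `"other"`. Only
#'   neurite-kind traces enter curvature analysis.
#' @param trace_id Identifier, unique within a model.
#' @param node_id Optional integer node identifiers (defaults to sequential).
#' @param validate Check trace invariants (at least two nodes, finite
#'   coordinates, positive radii, no coincident consecutive nodes)?
#' @return An object of class `neurite_trace`.
#' @export
neurite_trace <- function(xyz, radius, kind = "neurite", trace_id = "T1",
                          node_id = NULL, validate = TRUE) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("`xyz` must have three columns (x, y, z)")
  n <- nrow(xyz)
  radius <- rep_len(as.numeric(radius), n)
  if (is.null(node_id)) node_id <- seq_len(n)
  kind <- match.arg(kind, c("neurite", "soma", "other"))
  dimnames(xyz) <- NULL
  tr <- structure(
    list(xyz = xyz, radius = radius, kind = kind,
         trace_id = as.character(trace_id), node_id = as.integer(node_id)),
    class = "neurite_trace")
  if (validate) {
    v <- validate_trace(tr)
    if (length(v)) stop("invalid trace '", trace_id, "': ",
                        paste(v, collapse = "; "))
  }
  tr
}

#' Construct a skeleton model
#'
#' A skeleton model is one traced dataset: a set of neurite/soma traces with
#' a dataset label (e.g. `"S8A"`, dataset A of case S8).
#'
#' @param traces List of [neurite_trace()] objects.
#' @param dataset_id Non-empty dataset label.
#' @param validate Check model invariants?
#' @return An object of class `skeleton_model`.
#' @export
skeleton_model <- function(traces, dataset_id, validate = TRUE) {
  if (!is.character(dataset_id) || length(dataset_id) != 1L ||
      is.na(dataset_id) || !nzchar(dataset_id))
    stop("`dataset_id` must be a non-empty string")
  m <- structure(list(traces = traces, dataset_id = dataset_id),
                 class = "skeleton_model")
  if (validate) {
    v <- validate_model(m)
    if (length(v)) stop("invalid model '", dataset_id, "': ",
                        paste(v, collapse = "; "))
  }
  m
}

#' @export
print.skeleton_model <- function(x, ...) {
  kinds <- vapply(x$traces, `[[`, "", "kind")
  cat("<skeleton_model> dataset", x$dataset_id, "-", length(x$traces),
      "traces (", sum(kinds == "neurite"), "neurite /", sum(kinds == "soma"),
      "soma ),", format(total_trace_length(x), digits = 6),
      "um neurite length\n")
  invisible(x)
}

#' @export
print.neurite_trace <- function(x, ...) {
  cat("<neurite_trace>", x$trace_id, "-", x$kind, "-", nrow(x$xyz),
      "nodes,", format(polyline_length(x$xyz), digits = 6), "um\n")
  invisible(x)
}

#' Polyline length of a coordinate matrix
#'
#' @param xyz n x 3 coordinate matrix (micrometres).
#' @return Total length of the piecewise-linear path, micrometres.
#' @export
polyline_length <- function(xyz) {
  if (nrow(xyz) < 2L) return(0)
  sum(sqrt(rowSums((xyz[-1L, , drop = FALSE] -
                    xyz[-nrow(xyz), , drop = FALSE])^2)))
}

#' Total neurite trace length of a model
#'
#' Sum of polyline lengths over neurite-kind traces only (somata and other
#' constituents are excluded), micrometres.
#'
#' @param model A [skeleton_model()].
#' @return Numeric scalar, micrometres.
#' @export
total_trace_length <- function(model) {
  len <- 0
  for (tr in model$traces)
    if (tr$kind == "neurite") len <- len + polyline_length(tr$xyz)
  len
}

validate_trace <- function(tr) {
  out <- character(0)
  n <- nrow(tr$xyz)
  if (n < 2L)
    out <- c(out, sprintf("trace %s: fewer than 2 nodes", tr$trace_id))
  if (!all(is.finite(tr$xyz)))
    out <- c(out, sprintf("trace %s: non-finite coordinates", tr$trace_id))
  bad_r <- which(!is.finite(tr$radius) | tr$radius <= 0)
  if (length(bad_r))
    out <- c(out, sprintf("trace %s node %d: nonpositive radius",
                          tr$trace_id, tr$node_id[bad_r]))
  if (n >= 2L && all(is.finite(tr$xyz))) {
    d <- sqrt(rowSums((tr$xyz[-1L, , drop = FALSE] -
                       tr$xyz[-n, , drop = FALSE])^2))
    coin <- which(d == 0)
    if (length(coin))
      out <- c(out, sprintf("trace %s nodes %d/%d: coincident nodes",
                            tr$trace_id, tr$node_id[coin], tr$node_id[coin + 1L]))
  }
  out
}

#' Validate a skeleton model
#'
#' Reports every invariant breach rather than stopping at the first:
#' traces with fewer than two nodes, non-finite coordinates, nonpositive
#' radii, coincident consecutive nodes, duplicate node ids across the model,
#' duplicate trace ids. An empty return value means the model is analyzable.
#'
#' @param model A [skeleton_model()].
#' @return Character vector of violation messages (empty if none).
#' @export
validate_model <- function(model) {
  out <- character(0)
  for (tr in model$traces) out <- c(out, validate_trace(tr))
  ids <- unlist(lapply(model$traces, `[[`, "node_id"))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    out <- c(out, sprintf("duplicate node_id %d", dup))
  tids <- vapply(model$traces, `[[`, "", "trace_id")
  tdup <- unique(tids[duplicated(tids)])
  if (length(tdup))
    out <- c(out, sprintf("duplicate trace_id %s", tdup))
  out
}

#' Map dataset labels to case labels
#'
#' Dataset ids follow the `<case><letter>` scheme (dataset "S8A" belongs to
#' case "S8"); trailing capital letters are stripped. Ids without a trailing
#' letter are returned unchanged, so plain case ids pass through.
#'
#' @param dataset_id Character vector of dataset labels.
#' @return Character vector of case labels.
#' @export
case_of_dataset <- function(dataset_id) {
  sub("(?<=[0-9])[A-Z]+$", "", dataset_id, perl = TRUE)
}
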