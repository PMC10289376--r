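#' Menger curvature of three points
#'
#' The curvature of the unique circle through three points in 3D: the
#' reciprocal of the circumradius of the triangle they span,
#' \eqn{\kappa = 4A/(abc)} with A the triangle area and a, b, c the side
#' lengths. This is the discrete realization of curvature as the reciprocal
#' of the curve radius. Collinear (but distinct) points return exactly 0.
#'
#' @param p1,p2,p3 Numeric length-3 coordinates (micrometres).
#' @return Curvature in 1/micrometres.
#' @export
menger_curvature <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1; w <- p3 - p2
  a2 <- sum(w^2); b2 <- sum(v^2); c2 <- sum(u^2)
  if (a2 == 0 || b2 == 0 || c2 == 0)
    stop("coincident points: Menger curvature undefined")
  cx <- c(u[2L] * v[3L] - u[3L] * v[2L],
          u[3L] * v[1L] - u[1L] * v[3L],
          u[1L] * v[2L] - u[2L] * v[1L])
  4 * (0.5 * sqrt(sum(cx^2))) / sqrt(a2 * b2 * c2)
}

# curvature at every interior node of a polyline (vectorized over triplets)
menger_chain <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3L) return(numeric(0))
  p1 <- xyz[1:(n - 2L), , drop = FALSE]
  p2 <- xyz[2:(n - 1L), , drop = FALSE]
  p3 <- xyz[3:n, , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1; w <- p3 - p2
  a2 <- rowSums(w^2); b2 <- rowSums(v^2); c2 <- rowSums(u^2)
  if (any(a2 == 0 | b2 == 0 | c2 == 0))
    stop("coincident points in polyline: Menger curvature undefined")
  cr2 <- (u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L])^2 +
         (u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L])^2 +
         (u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])^2
  2 * sqrt(cr2) / sqrt(a2 * b2 * c2)
}

#' Resample a trace at uniform arc-length spacing
#'
#' Places nodes at arc-length positions 0, step, 2*step, ... along the
#' original piecewise-linear path and always keeps the original endpoint
#' (the final inter-node spacing may therefore be shorter than `step`).
#' Coordinates and radii are linearly interpolated along the path.
#'
#' @param trace A valid [neurite_trace()].
#' @param step Arc-length spacing, micrometres (> 0 and < trace length).
#' @return A resampled [neurite_trace()].
#' @export
resample_trace <- function(trace, step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("`step` must be a positive number")
  v <- validate_trace(trace)
  if (length(v)) stop("invalid trace: ", paste(v, collapse = "; "))
  n <- nrow(trace$xyz)
  d <- sqrt(rowSums((trace$xyz[-1L, , drop = FALSE] -
                     trace$xyz[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(d))
  len <- s[n]
  if (step >= len)
    stop("`step` (", step, ") must be smaller than the trace length (",
         format(len), ")")
  targets <- seq(0, len, by = step)
  if (len - targets[length(targets)] > 1e-9 * max(1, len))
    targets <- c(targets, len)
  else
    targets[length(targets)] <- len
  xyz <- vapply(1:3, function(j)
    stats::approx(s, trace$xyz[, j], xout = targets)$y, numeric(length(targets)))
  radius <- stats::approx(s, trace$radius, xout = targets)$y
  neurite_trace(matrix(xyz, ncol = 3L), radius, kind = trace$kind,
                trace_id = trace$trace_id, validate = FALSE)
}

#' Curvature profile of a single neurite trace
#'
#' Resamples the trace at `step`, evaluates the Menger curvature on every
#' consecutive node triplet (no one-sided estimates at the two terminal
#' nodes), and summarizes the trace with an arc-length-weighted mean point
#' curvature (the default; median and max are selectable), an
#' arc-length-weighted mean node radius, and the resampled trace length.
#' Traces too short to yield a single triplet at the requested step are
#' returned flagged as excluded rather than dropped.
#'
#' @param trace A valid [neurite_trace()].
#' @param step Resampling interval, micrometres (default 1).
#' @param summary Per-trace summary of point curvatures: `"mean"`
#'   (arc-length weighted), `"median"` or `"max"`.
#' @return An object of class `curvature_profile` with fields
#'   `arc_positions`, `point_curvatures`, `neurite_curvature`,
#'   `neurite_radius`, `trace_length`, `n_points`, `excluded`.
#' @export
trace_curvature_profile <- function(trace, step = 1, summary = c("mean", "median", "max")) {
  summary <- match.arg(summary)
  v <- validate_trace(trace)
  if (length(v)) stop("invalid trace: ", paste(v, collapse = "; "))
  len0 <- polyline_length(trace$xyz)
  if (len0 <= step) return(excluded_profile(trace, step, summary))
  rs <- resample_trace(trace, step)
  m <- nrow(rs$xyz)
  if (m < 3L) return(excluded_profile(trace, step, summary))

  d <- sqrt(rowSums((rs$xyz[-1L, , drop = FALSE] -
                     rs$xyz[-m, , drop = FALSE])^2))
  s <- c(0, cumsum(d))
  k <- menger_chain(rs$xyz)
  w_int <- (s[3:m] - s[1:(m - 2L)]) / 2   # interior arc-length weights
  kappa <- switch(summary,
                  mean = stats::weighted.mean(k, w_int),
                  median = stats::median(k),
                  max = max(k))
  w_all <- (c(d, 0) + c(0, d)) / 2        # trapezoid weights, all nodes
  structure(list(trace_id = trace$trace_id,
                 arc_positions = s[2:(m - 1L)],
                 point_curvatures = k,
                 neurite_curvature = kappa,
                 neurite_radius = stats::weighted.mean(rs$radius, w_all),
                 trace_length = s[m],
                 n_points = length(k),
                 step = step, summary = summary, excluded = FALSE),
            class = "curvature_profile")
}

excluded_profile <- function(trace, step, summary) {
  structure(list(trace_id = trace$trace_id,
                 arc_positions = numeric(0), point_curvatures = numeric(0),
                 neurite_curvature = NA_real_, neurite_radius = NA_real_,
                 trace_length = polyline_length(trace$xyz), n_points = 0L,
                 step = step, summary = summary, excluded = TRUE),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  if (x$excluded)
    cat("<curvature_profile>", x$trace_id, "- EXCLUDED (too short at step",
        x$step, "um)\n")
  else
    cat("<curvature_profile>", x$trace_id, "-", x$n_points, "points,",
        "curvature", format(x$neurite_curvature, digits = 4), "um^-1,",
        "radius", format(x$neurite_radius, digits = 4), "um,",
        "length", format(x$trace_length, digits = 6), "um\n")
  invisible(x)
}

#' Morphometry of every neurite trace in a model
#'
#' Computes a [trace_curvature_profile()] for each neurite-kind trace of the
#' model (somata and other constituents are excluded by kind); traces too
#' short for one curvature triplet are kept as excluded-flagged profiles.
#' Deterministic given (model, step, summary).
#'
#' @param model A valid [skeleton_model()].
#' @param step Resampling interval, micrometres (default 1).
#' @param summary Per-trace curvature summary, see [trace_curvature_profile()].
#' @return An object of class `morphometry`: list with `profiles` (all
#'   neurite traces, in model order), `excluded_ids`, `dataset_id`, `step`,
#'   `summary`. Use [as.data.frame()] for the tidy per-neurite table.
#' @export
model_morphometry <- function(model, step = 1, summary = c("mean", "median", "max")) {
  summary <- match.arg(summary)
  v <- validate_model(model)
  if (length(v)) stop("invalid model '", model$dataset_id, "': ",
                      paste(v, collapse = "; "))
  neur <- Filter(function(tr) tr$kind == "neurite", model$traces)
  if (!length(neur))
    stop("model '", model$dataset_id, "' contains no neurite traces")
  profiles <- lapply(neur, trace_curvature_profile, step = step, summary = summary)
  excluded <- vapply(profiles, `[[`, TRUE, "excluded")
  structure(list(profiles = profiles,
                 excluded_ids = vapply(profiles[excluded], `[[`, "", "trace_id"),
                 dataset_id = model$dataset_id, step = step, summary = summary),
            class = "morphometry")
}

#' @export
as.data.frame.morphometry <- function(x, ...) {
  df <- data.frame(
    dataset_id = x$dataset_id,
    trace_id = vapply(x$profiles, `[[`, "", "trace_id"),
    trace_length_um = vapply(x$profiles, `[[`, 0, "trace_length"),
    curvature = vapply(x$profiles, `[[`, 0, "neurite_curvature"),
    radius = vapply(x$profiles, `[[`, 0, "neurite_radius"),
    n_points = vapply(x$profiles, `[[`, 0L, "n_points"),
    excluded_flag = vapply(x$profiles, `[[`, TRUE, "excluded"),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "curvature"] <- "neurite_curvature_um-1"
  names(df)[names(df) == "radius"] <- "neurite_radius_um"
  df
}

#' Combine morphometry of several models into one per-neurite table
#'
#' @param morphos List of `morphometry` objects (or a single one).
#' @return Tidy data frame with columns `dataset_id`, `trace_id`,
#'   `trace_length_um`, `neurite_curvature_um-1`, `neurite_radius_um`,
#'   `n_points`, `excluded_flag`.
#' @export
morphometry_table <- function(morphos) {
  if (inherits(morphos, "morphometry")) morphos <- list(morphos)
  do.call(rbind, lapply(morphos, as.data.frame))
}
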