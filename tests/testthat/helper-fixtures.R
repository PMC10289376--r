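# Geometric fixtures and independent oracles shared across the suite.

straight_trace <- function(length_um = 10, n = 11, radius = 0.3, id = "LINE") {
  neurite_trace(cbind(seq(0, length_um, length.out = n), 0, 0),
                radius = radius, trace_id = id)
}

# regular polygon approximation of a circle in the xy plane
circle_trace <- function(R = 5, n = 2000, radius = 0.3, id = "CIRC") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  neurite_trace(cbind(R * cos(th), R * sin(th), 0), radius = radius,
                trace_id = id)
}

# helix (a*cos t, a*sin t, b*t); analytic curvature a / (a^2 + b^2)
helix_trace <- function(a = 1, b = 1, turns = 3, n_per_turn = 600,
                        radius = 0.3, id = "HLX") {
  t <- seq(0, 2 * pi * turns, length.out = turns * n_per_turn)
  neurite_trace(cbind(a * cos(t), a * sin(t), b * t), radius = radius,
                trace_id = id)
}

random_wlc_model <- function(seed, n_traces = 5, persistence = 10,
                             len = 30, id = "RND") {
  set.seed(seed)
  traces <- lapply(seq_len(n_traces), function(i)
    generate_neurite(persistence, len, step = 1,
                     trace_id = sprintf("T%03d", i)))
  nid <- 0L
  for (i in seq_along(traces)) {
    traces[[i]]$node_id <- nid + seq_len(nrow(traces[[i]]$xyz))
    nid <- nid + nrow(traces[[i]]$xyz)
  }
  skeleton_model(traces, dataset_id = id)
}

# independent circumradius: solve for the point equidistant from p1, p2, p3
# within their plane (3x3 linear system), then R = |c - p1|
circumcurvature_oracle <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  nrm <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  if (sqrt(sum(nrm^2)) < 1e-14 * max(sqrt(sum(u^2)), sqrt(sum(v^2)))) return(0)
  # center c satisfies 2(p2-p1).c = |p2|^2 - |p1|^2 (and likewise for p3),
  # constrained to the triangle plane
  A <- rbind(2 * u, 2 * v, nrm)
  b <- c(sum(p2^2) - sum(p1^2), sum(p3^2) - sum(p1^2), sum(nrm * p1))
  cc <- solve(A, b)
  1 / sqrt(sum((cc - p1)^2))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

pearson_oracle <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((length(x) - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), length(x) - 2))
}

# small cohort spec for fast end-to-end tests
tiny_spec <- function(seed = 1, ...) {
  synthetic_cohort_spec(n_cases_per_group = 4L, neurites_per_case = 10L,
                        datasets_per_case = 2L, trace_length_mean = 15,
                        seed = seed, ...)
}

# zero-effect spec: both groups generated with identical case-mean law
null_spec <- function(seed) {
  synthetic_cohort_spec(n_cases_per_group = 8L, neurites_per_case = 10L,
                        datasets_per_case = 1L, trace_length_mean = 15,
                        disease_curvature_mult = 1, tail_fraction = 0,
                        disease_radius_mult = 1,
                        disease_case_log_sd = 0.06,
                        age_range_disease = c(42, 81), seed = seed)
}

cohort_case_table <- function(co, step = 1) {
  aggregate_cases(morphometry_table(lapply(co$models, model_morphometry,
                                           step = step)))
}
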