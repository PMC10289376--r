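# Worm-like-chain (WLC) synthetic neurites.
#
# Tangent directions evolve as a random walk on the unit sphere: each step
# deflects the tangent by an angle drawn from a von Mises-Fisher (vMF)
# distribution about the previous tangent, with concentration chosen so the
# tangent autocorrelation decays as exp(-s / persistence_length). For a vMF
# deflection with concentration k and uniform segment length h, the Menger
# curvature of a consecutive node triplet is exactly 2*sin(theta/2)/h, which
# gives the closed-form expected point curvature used as generator ground
# truth:
#   E[kappa] = (2/h) * sqrt(pi/8) * P(Gamma(3/2) <= 2k) / (sqrt(k)(1-e^{-2k}))
# (limit 4/(3h) as k -> 0, i.e. uniformly random turns).

# mean cosine of a vMF deflection: A(k) = coth(k) - 1/k
vmf_mean_cos <- function(k) ifelse(k < 1e-6, k / 3, 1 / tanh(k) - 1 / k)

vmf_kappa_from_mean_cos <- function(a) {
  stopifnot(a > 0, a < 1)
  upper <- max(10, 4 / (1 - a))
  stats::uniroot(function(k) vmf_mean_cos(k) - a,
                 lower = 1e-8, upper = upper, tol = 1e-12)$root
}

# E[sin(theta/2)] under the vMF deflection distribution (dimensionless)
vmf_mean_half_sine <- function(k) {
  small <- k < 1e-8
  out <- numeric(length(k))
  out[small] <- 2 / 3
  kk <- k[!small]
  out[!small] <- sqrt(pi / 8) * stats::pgamma(2 * kk, shape = 1.5, rate = 1) /
    (sqrt(kk) * (1 - exp(-2 * kk)))
  out
}

#' Expected Menger point curvature of a worm-like chain
#'
#' Closed form for the expected per-point Menger curvature of a WLC sampled
#' at uniform arc step `step` with the given persistence length. Strictly
#' decreasing in the persistence length; upper bound 4/(3*step) (fully
#' decorrelated tangents).
#'
#' @param persistence_length Persistence length, micrometres (> 0).
#' @param step Segment length, micrometres.
#' @return Expected point curvature, 1/micrometres.
#' @export
expected_wlc_curvature <- function(persistence_length, step = 1) {
  stopifnot(persistence_length > 0, step > 0)
  a <- exp(-step / persistence_length)
  k <- vapply(a, vmf_kappa_from_mean_cos, 0)
  (2 / step) * vmf_mean_half_sine(k)
}

# inverse of expected_wlc_curvature via a cached monotone grid over log k
.wlc_cache <- new.env(parent = emptyenv())

wlc_kappa_conc_from_curvature <- function(target_curvature, step) {
  # target in units of E[sin(theta/2)] = target * step / 2, in (0, 2/3)
  s <- target_curvature * step / 2
  if (any(s <= 0) || any(s >= 2 / 3 - 1e-6))
    stop("target mean curvature must lie in (0, 4/(3*step)); got ",
         paste(format(target_curvature[s <= 0 | s >= 2 / 3 - 1e-6]),
               collapse = ", "))
  if (is.null(.wlc_cache$grid)) {
    lk <- seq(-14, 26, length.out = 1200)
    .wlc_cache$grid <- list(lk = lk, s = vmf_mean_half_sine(exp(lk)))
  }
  g <- .wlc_cache$grid
  # s is strictly decreasing in log k; linear interpolation on the fine grid
  exp(stats::approx(g$s, g$lk, xout = s, rule = 2)$y)
}

wlc_positions <- function(kappa_conc, n_seg, step) {
  t0 <- stats::rnorm(3)
  t0 <- t0 / sqrt(sum(t0^2))
  u <- stats::runif(n_seg)
  e2k <- exp(-2 * kappa_conc)
  w <- if (kappa_conc < 1e-8) 2 * u - 1
       else 1 + log(u + (1 - u) * e2k) / kappa_conc
  w <- pmin(1, pmax(-1, w))
  phi <- stats::runif(n_seg, 0, 2 * pi)
  tang <- matrix(0, n_seg, 3)
  tcur <- t0
  for (i in seq_len(n_seg)) {
    ref <- if (abs(tcur[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- c(tcur[2L] * ref[3L] - tcur[3L] * ref[2L],
            tcur[3L] * ref[1L] - tcur[1L] * ref[3L],
            tcur[1L] * ref[2L] - tcur[2L] * ref[1L])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(tcur[2L] * e1[3L] - tcur[3L] * e1[2L],
            tcur[3L] * e1[1L] - tcur[1L] * e1[3L],
            tcur[1L] * e1[2L] - tcur[2L] * e1[1L])
    st <- sqrt(max(0, 1 - w[i]^2))
    tcur <- w[i] * tcur + st * (cos(phi[i]) * e1 + sin(phi[i]) * e2)
    tcur <- tcur / sqrt(sum(tcur^2))
    tang[i, ] <- tcur
  }
  rbind(c(0, 0, 0), apply(tang * step, 2L, cumsum))
}

#' Generate one worm-like-chain neurite trace
#'
#' @param persistence_length Persistence length, micrometres (> 0).
#' @param total_length Target trace length, micrometres (>= 3 * step).
#' @param step Segment length, micrometres.
#' @param radius_mean Mean node radius, micrometres.
#' @param radius_cv Coefficient of variation of the lognormal per-node
#'   radius distribution.
#' @param trace_id Trace identifier.
#' @return A [neurite_trace()]. Uses the current RNG state; seed with
#'   [set.seed()] for reproducibility.
#' @export
generate_neurite <- function(persistence_length, total_length, step = 1,
                             radius_mean = 0.3, radius_cv = 0.1,
                             trace_id = "T1") {
  stopifnot(persistence_length > 0, step > 0, radius_mean > 0, radius_cv >= 0)
  if (total_length < 3 * step)
    stop("`total_length` must be at least 3 * step")
  a <- exp(-step / persistence_length)
  k <- vmf_kappa_from_mean_cos(a)
  wlc_neurite(k, n_seg = max(3L, as.integer(round(total_length / step))),
              step = step, radius_mean = radius_mean, radius_cv = radius_cv,
              trace_id = trace_id)
}

wlc_neurite <- function(kappa_conc, n_seg, step, radius_mean, radius_cv,
                        trace_id) {
  xyz <- wlc_positions(kappa_conc, n_seg, step)
  n <- n_seg + 1L
  radius <- if (radius_cv > 0) {
    sl <- sqrt(log(1 + radius_cv^2))
    stats::rlnorm(n, meanlog = log(radius_mean) - sl^2 / 2, sdlog = sl)
  } else rep(radius_mean, n)
  neurite_trace(xyz, radius, kind = "neurite", trace_id = trace_id,
                validate = FALSE)
}

#' Parameters of a synthetic cohort
#'
#' Defines the generating conditions of a synthetic case-control cohort:
#' per-neurite curvature targets are drawn per case and mapped to worm-like
#' chain persistence lengths, so the per-case distribution of neurite
#' curvature is controlled directly.
#' \itemize{
#'   \item Controls: case mean curvature around `control_mean_curvature`
#'     with lognormal between-case spread; the within-case SD of neurite
#'     curvature declines linearly with age (`sd_age_slope` per year around
#'     the reference age) so older controls have more compact distributions.
#'   \item Disease cases: case mean elevated by `disease_curvature_mult`;
#'     the per-neurite targets are a two-component mixture - a bulk
#'     component at the control level plus a minority short-persistence
#'     (high-curvature) component of weight `tail_fraction` - producing the
#'     long-tailed distributions without moving the bulk mode. Radii are
#'     thinned by `disease_radius_mult`.
#'   \item Hallucination score: affine in the case's target mean curvature
#'     plus noise, truncated at zero; controls are exactly 0. The
#'     chlorpromazine-equivalent dose is drawn independently of curvature
#'     (a built-in null).
#' }
#'
#' @param n_cases_per_group Cases per group (default 8).
#' @param neurites_per_case Neurites per case (default 60).
#' @param datasets_per_case Datasets each case's neurites are split over
#'   (default 2).
#' @param step Generator segment length = analysis resampling step,
#'   micrometres (default 1).
#' @param trace_length_mean,trace_length_cv Lognormal trace-length
#'   distribution, micrometres (default mean 40, cv 0.25).
#' @param control_mean_curvature Control-group case mean curvature target,
#'   1/um (default 0.36).
#' @param control_case_log_sd Between-case lognormal sd of control case
#'   means (default 0.06, i.e. about 0.022 1/um).
#' @param disease_curvature_mult Multiplicative elevation of disease case
#'   mean curvature (default 1.6).
#' @param disease_case_log_sd Between-case lognormal sd of disease case
#'   means (default 0.08).
#' @param tail_fraction Mixture weight of the high-curvature component in
#'   disease cases (default 0.3).
#' @param tail_sd Within-case SD of the tail component, 1/um (default 0.15).
#' @param bulk_sd Within-case SD of the disease bulk component, 1/um
#'   (default 0.15).
#' @param control_sd_ref Control within-case neurite-curvature SD at the
#'   reference age, 1/um (default 0.24).
#' @param sd_age_slope Change of that SD per year of age (default -0.003).
#' @param sd_age_ref Reference age, years (default 45).
#' @param age_range_control,age_range_disease Age ranges, years.
#' @param radius_mean Control mean node radius, micrometres (default 0.30).
#' @param radius_case_log_sd Between-case lognormal sd of radii (default 0.06).
#' @param radius_cv Within-trace node radius cv (default 0.1).
#' @param disease_radius_mult Multiplicative radius thinning in disease
#'   (default 0.85).
#' @param score_slope,score_offset,score_sd Hallucination-score model:
#'   score = max(0, score_slope * (case mean curvature - score_offset) +
#'   noise(sd = score_sd)).
#' @param cpz_meanlog,cpz_sdlog Lognormal chlorpromazine-equivalent dose
#'   (mg/day) for disease cases.
#' @param seed Integer seed; expands to per-case substreams so a case's
#'   data do not depend on how many other cases are generated.
#' @return A list of class `cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_cases_per_group = 8L,
                                  neurites_per_case = 60L,
                                  datasets_per_case = 2L,
                                  step = 1,
                                  trace_length_mean = 40,
                                  trace_length_cv = 0.25,
                                  control_mean_curvature = 0.36,
                                  control_case_log_sd = 0.06,
                                  disease_curvature_mult = 1.6,
                                  disease_case_log_sd = 0.08,
                                  tail_fraction = 0.3,
                                  tail_sd = 0.15,
                                  bulk_sd = 0.15,
                                  control_sd_ref = 0.24,
                                  sd_age_slope = -0.003,
                                  sd_age_ref = 45,
                                  age_range_control = c(42, 81),
                                  age_range_disease = c(35, 70),
                                  radius_mean = 0.30,
                                  radius_case_log_sd = 0.06,
                                  radius_cv = 0.1,
                                  disease_radius_mult = 0.85,
                                  score_slope = 15,
                                  score_offset = 0.25,
                                  score_sd = 2.5,
                                  cpz_meanlog = log(600),
                                  cpz_sdlog = 0.4,
                                  seed = 1L) {
  spec <- as.list(environment())
  pos <- c("neurites_per_case", "step", "trace_length_mean", "trace_length_cv",
           "control_mean_curvature", "control_case_log_sd",
           "disease_curvature_mult", "tail_sd", "bulk_sd", "control_sd_ref",
           "radius_mean", "radius_cv", "radius_mean", "disease_radius_mult")
  for (p in pos) if (!is.numeric(spec[[p]]) || spec[[p]] <= 0)
    stop("spec parameter `", p, "` must be positive")
  if (spec$n_cases_per_group < 1L) stop("need at least 1 case per group")
  if (spec$tail_fraction < 0 || spec$tail_fraction >= 1)
    stop("`tail_fraction` must be in [0, 1)")
  if (spec$neurites_per_case < 2L) stop("need at least 2 neurites per case")
  class(spec) <- "cohort_spec"
  spec
}

case_substream_seed <- function(seed, group_idx, case_idx) {
  as.integer((as.numeric(seed) * 1009 + group_idx * 7919 +
              case_idx * 104729) %% 2147483647)
}

# mean of a gamma(m_raw, s) variable clipped into [lo, hi]
clipped_gamma_mean <- function(m_raw, s, lo, hi) {
  a <- (m_raw / s)^2; r <- m_raw / s^2
  lo * stats::pgamma(lo, a, r) + hi * stats::pgamma(hi, a, r, lower.tail = FALSE) +
    m_raw * (stats::pgamma(hi, a + 1, r) - stats::pgamma(lo, a + 1, r))
}

# gamma draws clipped into [lo, hi], with the raw mean adjusted so the
# clipped mean equals `m` (curvature targets must stay inside the feasible
# range of the estimator; naive clipping would bias the declared effect)
rgamma_clipped <- function(n, m, s, lo, hi) {
  stopifnot(m > lo, m < hi)
  m_raw <- if (clipped_gamma_mean(m, s, lo, hi) > m - 1e-9) m else
    stats::uniroot(function(x) clipped_gamma_mean(x, s, lo, hi) - m,
                   lower = m, upper = hi * 5, tol = 1e-10)$root
  pmin(pmax(stats::rgamma(n, shape = (m_raw / s)^2, rate = m_raw / s^2), lo), hi)
}

# draw the per-neurite curvature targets of one case
case_curvature_targets <- function(spec, group, age, n) {
  cap <- 4 / (3 * spec$step) * 0.98
  lo <- 0.02 / spec$step
  if (group == "control") {
    mu <- spec$control_mean_curvature *
      exp(stats::rnorm(1, 0, spec$control_case_log_sd))
    sdv <- max(0.02, (spec$control_sd_ref +
                      spec$sd_age_slope * (age - spec$sd_age_ref)) *
                     exp(stats::rnorm(1, 0, 0.12)))
    targets <- rgamma_clipped(n, mu, sdv, lo, cap)
  } else {
    mu <- spec$control_mean_curvature * spec$disease_curvature_mult *
      exp(stats::rnorm(1, 0, spec$disease_case_log_sd))
    pi_t <- spec$tail_fraction
    if (pi_t > 0) {
      mu_b <- spec$control_mean_curvature * exp(stats::rnorm(1, 0, 0.05))
      mu_t <- min(max((mu - (1 - pi_t) * mu_b) / pi_t, mu_b + 0.1), cap * 0.92)
      mu_b <- (mu - pi_t * mu_t) / (1 - pi_t)  # re-balance if tail was clamped
      is_tail <- stats::runif(n) < pi_t
      targets <- ifelse(is_tail, rgamma_clipped(n, mu_t, spec$tail_sd, lo, cap),
                        rgamma_clipped(n, mu_b, spec$bulk_sd, lo, cap))
    } else {
      targets <- rgamma_clipped(n, mu, spec$bulk_sd, lo, cap)
    }
  }
  list(mu_target = mu, targets = targets)
}

#' Generate a synthetic case-control cohort
#'
#' One skeleton model per dataset (a case's neurites are split over
#' `datasets_per_case` datasets labelled `<case>A`, `<case>B`, ...; each
#' dataset also carries one soma-kind trace, which downstream analysis must
#' ignore), one cohort record per case, and a ground-truth table recording
#' each case's generating parameters and the realized mean/SD of its
#' per-neurite curvature targets - the quantities a correct pipeline should
#' recover. Identical spec and seed give an identical cohort, and each case
#' is generated on its own seed substream, so cohorts are reproducible under
#' changes of the case count.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return List with `models` (list of [skeleton_model()]), `records`
#'   (cohort data frame), `truth` (per-case data frame).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(synthetic_cohort_spec, spec)
  groups <- c("control", "schizophrenia")
  models <- list()
  records <- list()
  truth <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n_cases <- spec$n_cases_per_group
    rng <- if (g == "control") spec$age_range_control else spec$age_range_disease
    ages <- round(seq(rng[1L], rng[2L], length.out = n_cases))
    for (ci in seq_len(n_cases)) {
      set.seed(case_substream_seed(spec$seed, gi, ci))
      case_id <- sprintf("%s%d", if (g == "control") "N" else "S", ci)
      age <- ages[ci]
      tg <- case_curvature_targets(spec, g, age, spec$neurites_per_case)
      kcs <- wlc_kappa_conc_from_curvature(tg$targets, spec$step)
      rmean <- spec$radius_mean *
        (if (g == "control") 1 else spec$disease_radius_mult) *
        exp(stats::rnorm(1, 0, spec$radius_case_log_sd))
      sl <- sqrt(log(1 + spec$trace_length_cv^2))
      lens <- stats::rlnorm(spec$neurites_per_case,
                            log(spec$trace_length_mean) - sl^2 / 2, sl)
      n_segs <- pmax(4L, as.integer(round(lens / spec$step)))
      traces <- lapply(seq_len(spec$neurites_per_case), function(i)
        wlc_neurite(kcs[i], n_segs[i], spec$step, rmean, spec$radius_cv,
                    trace_id = sprintf("%s_T%04d", case_id, i)))
      # split neurites over datasets, one soma blob per dataset
      ds <- rep(seq_len(spec$datasets_per_case),
                length.out = spec$neurites_per_case)
      for (di in seq_len(spec$datasets_per_case)) {
        dtr <- traces[ds == di]
        theta <- seq(0, 2 * pi, length.out = 13L)[-13L]
        soma <- neurite_trace(
          cbind(5 * cos(theta), 5 * sin(theta), 0), radius = 4,
          kind = "soma", trace_id = sprintf("%s_SOMA%d", case_id, di),
          validate = FALSE)
        did <- sprintf("%s%s", case_id, LETTERS[di])
        all_tr <- c(dtr, list(soma))
        nid <- 0L
        for (ti in seq_along(all_tr)) {  # model-wide unique node ids
          n_tr <- nrow(all_tr[[ti]]$xyz)
          all_tr[[ti]]$node_id <- nid + seq_len(n_tr)
          nid <- nid + n_tr
        }
        models[[did]] <- skeleton_model(all_tr, dataset_id = did,
                                        validate = FALSE)
      }
      score <- if (g == "control") 0 else
        round(max(0, spec$score_slope * (tg$mu_target - spec$score_offset) +
                    stats::rnorm(1, 0, spec$score_sd)), 1)
      cpz <- if (g == "control") NA_real_ else
        round(stats::rlnorm(1, spec$cpz_meanlog, spec$cpz_sdlog))
      records[[case_id]] <- data.frame(
        case_id = case_id, group = g, age = age,
        sex = if (ci %% 2L) "M" else "F",
        hallucination_score = score, cpz_dose = cpz, stringsAsFactors = FALSE)
      truth[[case_id]] <- data.frame(
        case_id = case_id, group = g, age = age,
        target_case_mean = tg$mu_target,
        expected_mean_curvature = mean(tg$targets),
        expected_sd_curvature = stats::sd(tg$targets),
        median_persistence_length = stats::median(
          -spec$step / log(vmf_mean_cos(kcs))),
        radius_mean = rmean,
        n_neurites = spec$neurites_per_case, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, records)
  truth <- do.call(rbind, truth)
  rownames(records) <- rownames(truth) <- NULL
  list(models = models, records = records, truth = truth)
}
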