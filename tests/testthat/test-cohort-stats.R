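profile_stub <- function(k, radius = 0.3, len = 10) {
  structure(list(trace_id = "T", neurite_curvature = k,
                 neurite_radius = radius, trace_length = len,
                 excluded = FALSE), class = "curvature_profile")
}

toy_records <- function(n_per_group = 3) {
  data.frame(
    case_id = c(paste0("S", 1:n_per_group), paste0("N", 1:n_per_group)),
    group = rep(c("schizophrenia", "control"), each = n_per_group),
    age = 50, sex = "M",
    hallucination_score = rep(c(2, 0), each = n_per_group),
    cpz_dose = rep(c(500, NA), each = n_per_group),
    stringsAsFactors = FALSE)
}

test_that("case aggregation matches hand arithmetic", {
  ca <- aggregate_case(lapply(c(0.2, 0.4, 0.6), profile_stub), "S1")
  expect_equal(ca$mean_curvature, 0.4)
  expect_equal(ca$sd_curvature, 0.2)
  expect_equal(ca$median_curvature, 0.4)
  expect_equal(ca$max_curvature, 0.6)
  expect_equal(ca$n_neurites, 3L)

  same <- aggregate_case(lapply(rep(0.3, 5), profile_stub), "S2")
  expect_equal(same$sd_curvature, 0)

  expect_error(aggregate_case(list(profile_stub(0.3)), "S3"),
               "S3.*fewer than 2")
})

test_that("aggregated moments recover the generating gamma moments", {
  set.seed(99)
  x <- stats::rgamma(10000, shape = 4, rate = 10)   # mean 0.4, sd 0.2
  ca <- aggregate_case(lapply(x, profile_stub), "MC")
  expect_lte(abs(ca$mean_curvature - 0.4), 3 * 0.2 / sqrt(10000))
  expect_lte(abs(ca$sd_curvature - 0.2), 3 * 0.01)
})

test_that("aggregation pools a case's datasets associatively", {
  set.seed(4)
  k <- stats::runif(30, 0.1, 0.9)
  df <- data.frame(dataset_id = rep(c("S1A", "S1B", "S1C"), each = 10),
                   trace_id = sprintf("T%02d", 1:30),
                   trace_length_um = 10, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[["neurite_curvature_um-1"]] <- k
  df[["neurite_radius_um"]] <- 0.3
  df$n_points <- 8L
  df$excluded_flag <- FALSE
  pooled <- aggregate_cases(df)
  direct <- aggregate_case(lapply(k, profile_stub), "S1")
  expect_equal(pooled$mean_curvature, direct$mean_curvature)
  expect_equal(pooled$sd_curvature, direct$sd_curvature)
  expect_equal(pooled$n_neurites, 30L)
  expect_equal(pooled$case_id, "S1")
})

test_that("Welch comparison reproduces the hand-evaluated fixture", {
  cases <- data.frame(case_id = c("S1", "S2", "S3", "N1", "N2", "N3"),
                      mean_curvature = c(1, 2, 3, 2, 3, 4),
                      stringsAsFactors = FALSE)
  cmp <- group_compare(cases, toy_records(), "mean_curvature")
  expect_equal(cmp$t, -1 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(cmp$t, -1.2247, tolerance = 1e-4)
  expect_equal(cmp$df, 4, tolerance = 1e-10)
  expect_equal(cmp$p, 2 * stats::pt(-1 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(round(cmp$p, 3), 0.288)

  cases$mean_curvature <- rep(c(1, 2, 3), 2)
  same <- group_compare(cases, toy_records(), "mean_curvature")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  cases$mean_curvature <- rep(c(1, 2), each = 3)
  expect_error(group_compare(cases, toy_records(), "mean_curvature"),
               "degenerate variance")
})

test_that("Welch results agree with the textbook formula on random samples", {
  set.seed(17)
  for (i in 1:100) {
    nx <- sample(3:10, 1); ny <- sample(3:10, 1)
    x <- stats::rnorm(nx); y <- stats::rnorm(ny, sd = stats::runif(1, 0.5, 2))
    cases <- data.frame(case_id = c(paste0("S", 1:nx), paste0("N", 1:ny)),
                        v = c(x, y), stringsAsFactors = FALSE)
    recs <- data.frame(case_id = cases$case_id,
                       group = rep(c("schizophrenia", "control"), c(nx, ny)),
                       age = 50, sex = "M", hallucination_score = 0,
                       cpz_dose = NA, stringsAsFactors = FALSE)
    recs$hallucination_score[recs$group == "schizophrenia"] <- 1
    cmp <- group_compare(cases, recs, "v")
    o <- welch_oracle(x, y)
    expect_lte(abs(cmp$t - o$t), 1e-10)
    expect_lte(abs(cmp$df - o$df), 1e-10)
    expect_lte(abs(cmp$p - o$p), 1e-10)
  }
})

test_that("group tests weigh each case once regardless of neurite count", {
  set.seed(2)
  k <- stats::runif(40, 0.2, 0.8)
  base <- data.frame(dataset_id = rep(c("S1A", "S2A", "N1A", "N2A"), each = 10),
                     trace_id = sprintf("T%02d", 1:40), trace_length_um = 10,
                     stringsAsFactors = FALSE, check.names = FALSE)
  base[["neurite_curvature_um-1"]] <- k
  base[["neurite_radius_um"]] <- 0.3
  base$n_points <- 8L; base$excluded_flag <- FALSE
  recs <- toy_records(2)
  t1 <- group_compare(aggregate_cases(base), recs, "mean_curvature")$t
  # inflate case S1 by repeating its neurites five times
  inflated <- rbind(base, do.call(rbind, replicate(4, {
    d <- base[base$dataset_id == "S1A", ]; d$trace_id <- paste0(d$trace_id, "x")
    d
  }, simplify = FALSE)))
  t2 <- group_compare(aggregate_cases(inflated), recs, "mean_curvature")$t
  expect_equal(t2, t1)
})

test_that("normality check has approximately nominal level and detects bimodality", {
  set.seed(21)
  hits <- mean(vapply(1:200, function(i)
    normality_check(stats::rnorm(8))$p > 0.05, TRUE))
  expect_gte(hits, 0.9)
  bimodal <- c(stats::rnorm(25, -4, 0.3), stats::rnorm(25, 4, 0.3))
  expect_lt(normality_check(bimodal)$p, 0.05)
  expect_error(normality_check(rep(1, 8)), "zero variance")
  expect_error(normality_check(stats::rnorm(2)), "3 <= n")
})

test_that("correlation handles exact linear fixtures and degenerate input", {
  d <- data.frame(case_id = c("A", "B", "C"), x = c(1, 2, 3), y = c(2, 4, 6))
  r <- correlate(d, NULL, "x", "y")
  expect_equal(r$pearson_r, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)

  d2 <- data.frame(case_id = c("A", "B", "C", "D"),
                   x = c(0, 1, 2, 3), y = c(3, 2, 1, 0))
  expect_equal(correlate(d2, NULL, "x", "y")$pearson_r, -1)

  d2$z <- 1
  expect_error(correlate(d2, NULL, "z", "y"), "zero variance in predictor")
  expect_error(correlate(d2[1:2, ], NULL, "x", "y"), "at least 3")
})

test_that("Pearson r/p match the closed formula and behave under affine maps", {
  set.seed(31)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  d <- data.frame(case_id = letters[1:10], x = x, y = y)
  r <- correlate(d, NULL, "x", "y")
  o <- pearson_oracle(x, y)
  expect_equal(r$pearson_r, o$r, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-12)

  d$x2 <- 3 * x + 7; d$y2 <- -2 * y + 1
  expect_equal(correlate(d, NULL, "x2", "y")$pearson_r, o$r, tolerance = 1e-12)
  expect_equal(correlate(d, NULL, "x2", "y2")$pearson_r, -o$r, tolerance = 1e-12)
})

test_that("p-values are uniform under an independence permutation null", {
  set.seed(47)
  x <- 1:8
  y <- stats::rnorm(8)
  ps <- vapply(1:1000, function(i) {
    d <- data.frame(case_id = letters[1:8], x = x, y = sample(y))
    correlate(d, NULL, "x", "y")$p
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("curvature histograms follow the right-open binning convention", {
  h <- curvature_histogram(c(0.05, 0.15, 0.15, 0.25))
  expect_equal(h$relative_frequencies, c(0.25, 0.5, 0.25))
  expect_equal(h$bin_edges, c(0, 0.1, 0.2, 0.3))

  one <- curvature_histogram(rep(0.55, 7))
  expect_equal(sum(one$relative_frequencies > 0), 1)
  expect_equal(max(one$relative_frequencies), 1)

  # boundary values land in the upper (right-open) bin
  hb <- curvature_histogram(c(0.3, 0.31))
  expect_equal(which(hb$relative_frequencies > 0), 4)

  h2 <- curvature_histogram(seq(0.1, 0.79, by = 0.01))
  expect_equal(h2$tail_mass, 0)
  expect_gt(curvature_histogram(c(0.2, 0.85))$tail_mass, 0)

  expect_error(curvature_histogram(c(0.1, 0.2), bin_width = 0), "positive")
})

test_that("histogram frequencies sum to one and ignore input order", {
  set.seed(6)
  x <- stats::rgamma(500, 3, 8)
  h1 <- curvature_histogram(x)
  h2 <- curvature_histogram(sample(x))
  expect_equal(sum(h1$relative_frequencies), 1, tolerance = 1e-12)
  expect_identical(h1$relative_frequencies, h2$relative_frequencies)
})
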