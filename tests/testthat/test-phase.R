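asym_map <- function() {
  # peak at 0, trough at 10, next peak at 26 (10/16-h asymmetric halves)
  build_phase_map(anchor_set(c(0, 10, 26, 36, 52),
                             c("peak", "trough", "peak", "trough", "peak")))
}

test_that("phase maps pin peaks to 0, troughs to pi, linear in between", {
  map <- asym_map()
  expect_equal(phase_at_time(map, 0), 0)
  expect_equal(phase_at_time(map, 10), pi)
  expect_equal(phase_at_time(map, 26) %% (2 * pi), 0)
  expect_equal(phase_at_time(map, 5), pi / 2)            # midpoint peak->trough
  expect_equal(phase_at_time(map, 18), 1.5 * pi)         # 8/16 into trough->peak
  # round trip time -> phase -> time is the identity
  tq <- seq(0.5, 51.5, by = 0.7)
  expect_equal(time_at_phase(map, phase_at_time(map, tq, wrap = FALSE)), tq,
               tolerance = 1e-9)
  expect_error(build_phase_map(anchor_set(5, "peak")), "two alternating")
})

test_that("commitment projection computes phase and time since last peak", {
  map <- asym_map()
  at_trough <- commitment_phase(map, 10, "c")
  expect_equal(at_trough$commit_phase, pi)
  expect_equal(at_trough$time_since_last_peak, 10)
  mid <- commitment_phase(map, 31, "c")
  expect_equal(mid$commit_phase, pi / 2)
  expect_equal(mid$time_since_last_peak, 5)
  # outside the mapped interval: excluded, not an error
  expect_null(commitment_phase(map, 60, "c"))
  expect_null(commitment_phase(map, -1, "c"))
})

test_that("estimated commitment phases recover ground truth and gating", {
  cfg <- generator_config(n_cells = 250, condition = "rosi", seed = 21)
  pop <- generate_population(cfg)
  reporter <- lapply(population_traces(pop, "reporter"), smooth_moving_average)
  anchors <- lapply(reporter, detect_anchors)
  maps <- lapply(Filter(function(a) length(a$anchor_times) >= 2, anchors),
                 build_phase_map)
  pparg <- lapply(population_traces(pop, "pparg"), smooth_moving_average)
  term <- vapply(pparg, function(tr) tr$value[length(tr$value)], numeric(1))
  roc <- roc_threshold_scan(pparg, fate_labels(term, 1.1))
  rec <- assign_commitment_times(pparg, roc$optimal_threshold)
  hits <- 0L; n <- 0L; est <- numeric(0)
  for (i in seq_len(nrow(rec))) {
    id <- rec$cell_id[i]
    gt <- pop$ground_truth[[id]]
    if (is.null(maps[[id]]) || is.na(gt$true_commit_phase)) next
    row <- commitment_phase(maps[[id]], rec$commit_time[i], id)
    if (is.null(row)) next
    n <- n + 1L
    est <- c(est, row$commit_phase)
    if (circ_dist(row$commit_phase, gt$true_commit_phase) <= 0.15 * pi)
      hits <- hits + 1L
  }
  expect_gt(n, 50L)
  expect_gte(hits / n, 0.9)
  expect_gte(mean(est >= pi & est <= 2 * pi), 0.9)
})

test_that("Gaussian mixture fits recover component structure", {
  set.seed(3)
  one <- rnorm(2000, 50, 3)
  g1 <- fit_commitment_time_gmm(one)
  expect_equal(g1$k, 1L)
  expect_lt(abs(g1$means[1] - 50), 0.3)
  two <- c(rnorm(400, 30, 2), rnorm(400, 56, 2))
  g2 <- fit_commitment_time_gmm(two)
  expect_equal(g2$k, 2L)
  expect_equal(diff(g2$means), 26, tolerance = 1)
  expect_equal(sum(g2$weights), 1, tolerance = 1e-9)
  # degenerate input: one component with an sd floor
  gd <- fit_commitment_time_gmm(rep(12, 100))
  expect_equal(gd$k, 1L)
  expect_gt(gd$sds[1], 0)
  # deterministic: same input, same fit
  expect_identical(fit_commitment_time_gmm(two)$means, g2$means)
})

test_that("mixture components of gated populations are spaced by the period", {
  cfg <- generator_config(n_cells = 400, condition = "rosi", seed = 37,
                          frac_differentiating = 0.8)
  pop <- generate_population(cfg)
  tc <- vapply(pop$ground_truth, function(g) g$true_commit_time, numeric(1))
  g <- fit_commitment_time_gmm(tc[!is.na(tc)])
  expect_gte(g$k, 2L)
  expect_equal(mean(diff(g$means[1:min(3, g$k)])), cfg$reporter_period_mean,
               tolerance = 3)
})

test_that("one-term Fourier fits localize the phase preference", {
  set.seed(6)
  # uniform phases: negligible first harmonic
  fu <- suppressWarnings(fit_phase_fourier(runif(3000, 0, 2 * pi)))
  expect_lt(sqrt(fu$a1^2 + fu$b1^2), 3 / sqrt(3000) * fu$a0 * 2 * pi)
  # concentrated phases: implied peak at the concentration point
  fc <- suppressWarnings(fit_phase_fourier(rnorm(500, 1.5 * pi, 0.15)))
  expect_equal(fc$peak_phase, 1.5 * pi, tolerance = 0.1)
  # gated synthetic population: peak inside the gating window
  cfg <- generator_config(n_cells = 200, condition = "rosi", seed = 39)
  pop <- generate_population(cfg)
  ph <- vapply(pop$ground_truth, function(g) g$true_commit_phase, numeric(1))
  fg <- fit_phase_fourier(ph[!is.na(ph)])
  expect_gt(fg$peak_phase, pi)
  expect_lt(fg$peak_phase, 2 * pi)
  expect_error(fit_phase_fourier(rep(1, 100)), "one bin")
})

test_that("phase folding recovers built-in slope phase structure", {
  t <- seq(0, 96, 0.2)
  anc <- anchor_set(c(seq(5, 96, 13)),
                    rep(c("peak", "trough"), length.out = length(seq(5, 96, 13))))
  map <- build_phase_map(anc)
  mk_cell <- function(lag) {
    ph <- phase_at_time(map, t, wrap = FALSE)
    v <- cos((ph %% (2 * pi)) - lag)
    v[is.na(ph)] <- 0
    trace_series(t, v, "slope", "x")
  }
  maps <- list(a = map, b = map, c = map)
  tr0 <- list(a = mk_cell(0), b = mk_cell(0), c = mk_cell(0))
  pf0 <- phase_fold_slopes(tr0, maps, n_boot = 100, seed = 2)
  expect_equal(circ_dist(pf0$argmax_phase, 0), 0, tolerance = 2 * pi / 48 + 1e-9)
  tr14 <- list(a = mk_cell(1.4 * pi), b = mk_cell(1.4 * pi), c = mk_cell(1.4 * pi))
  pf14 <- phase_fold_slopes(tr14, maps, n_boot = 100, seed = 2)
  expect_equal(circ_dist(pf14$argmax_phase, 1.4 * pi), 0,
               tolerance = 2 * pi / 48 + 1e-9)
  # two channels with a built-in 0.4*pi lag differ by 0.4*pi at the argmax
  tr18 <- list(a = mk_cell(1.8 * pi), b = mk_cell(1.8 * pi), c = mk_cell(1.8 * pi))
  pf18 <- phase_fold_slopes(tr18, maps, n_boot = 100, seed = 2)
  expect_equal(circ_dist(pf18$argmax_phase, pf14$argmax_phase), 0.4 * pi,
               tolerance = 2 * 2 * pi / 48 + 1e-9)
  # CI bounds bracket the mean; scaling invariance of the argmax
  expect_true(all(pf14$ci_lower <= pf14$mean + 1e-9))
  expect_true(all(pf14$ci_upper >= pf14$mean - 1e-9))
  tr_sc <- lapply(tr14, function(x) retrace_test(x, 5 * x$value))
  expect_equal(phase_fold_slopes(tr_sc, maps, n_boot = 50, seed = 2)$argmax_phase,
               pf14$argmax_phase)
  expect_error(phase_fold_slopes(list(), list(), n_boot = 10), "no complete")
})

test_that("permutation cosinor test is calibrated and specific", {
  t <- seq(0, 44, by = 4)
  # pure cosine at the tested period: minimal attainable p
  p_cos <- rhythmicity_test(cos(2 * pi * t / 24), t, 24, n_perm = 500)$p_value
  expect_lte(p_cos, 1 / 501 + 1e-12)
  # type-I calibration on white noise
  set.seed(10)
  hits <- mean(replicate(200, {
    rhythmicity_test(rnorm(12), t, 24, n_perm = 99, seed = NULL)$p_value < 0.05
  }))
  expect_lt(abs(hits - 0.05), 0.035)
  # cosine at double the period is not called rhythmic at the tested period
  set.seed(11)
  spec <- mean(replicate(50, {
    y <- cos(2 * pi * t / 48 + runif(1, 0, 2 * pi)) + rnorm(12, 0, 0.1)
    rhythmicity_test(y, t, 24, n_perm = 199, seed = NULL)$p_value >= 0.05
  }))
  expect_gte(spec, 0.9)
  # constant input: p = 1
  expect_equal(rhythmicity_test(rep(2, 12), t, 24)$p_value, 1)
  expect_error(rhythmicity_test(1:4, 1:4, 24), "six time points")
})
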