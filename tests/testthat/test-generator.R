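test_that("generator config enforces its invariants", {
  expect_error(generator_config(duration = 96.1, dt = 0.2), "multiple")
  expect_error(generator_config(gating_window = c(0, 3 * pi)), "gating_window")
  expect_error(generator_config(pparg_low = 1.5), "pparg_low")
  expect_error(generator_config(lh846_period_factor = 1), "exceed 1")
  expect_silent(generator_config())
})

test_that("reporter traces honor the condition rules", {
  cfg0 <- generator_config(n_cells = 1, condition = "rosi",
                           measurement_noise_cv = 0)
  set.seed(3)
  r <- generate_reporter_trace(cfg0)
  # noise-free peak spacings all equal the drawn period
  pk <- r$anchors$anchor_times[r$anchors$anchor_kinds == "peak"]
  expect_equal(diff(pk), rep(r$period, length(pk) - 1L), tolerance = 1e-9)
  # dmi vs control at the same seed: first peak later by exactly 12 h
  set.seed(9)
  rc <- generate_reporter_trace(generator_config(n_cells = 1, condition = "rosi"))
  set.seed(9)
  rd <- generate_reporter_trace(generator_config(n_cells = 1, condition = "dmi"))
  expect_equal(rd$first_peak - rc$first_peak, 12)
  expect_equal(rd$period, rc$period)
  # lh846: all periods multiplied by the period factor
  set.seed(9)
  rl <- generate_reporter_trace(generator_config(n_cells = 1, condition = "lh846",
                                                 lh846_period_factor = 1.25))
  expect_equal(rl$period, rc$period * 1.25, tolerance = 1e-12)
  # bmal1_kd: flat trace, no anchors
  set.seed(9)
  rb <- generate_reporter_trace(generator_config(n_cells = 1,
                                                 condition = "bmal1_kd",
                                                 measurement_noise_cv = 0))
  expect_length(rb$anchors$anchor_times, 0L)
  expect_equal(diff(range(rb$trace$value)), 0)
})

test_that("pparg traces encode fate, switch timing and switch speed", {
  cfg0 <- generator_config(n_cells = 1, condition = "rosi",
                           measurement_noise_cv = 0)
  set.seed(5)
  rep_out <- generate_reporter_trace(cfg0)
  set.seed(6)
  und <- generate_pparg_trace(cfg0, rep_out$anchors, "undifferentiated")
  expect_lt(max(und$value), cfg0$pparg_threshold_true)
  dif <- generate_pparg_trace(cfg0, rep_out$anchors, "differentiated",
                              commit_time = 48)
  # first crossing of the true threshold at the commitment time
  i <- which(dif$value > cfg0$pparg_threshold_true)[1]
  expect_equal(dif$time[i], 48, tolerance = cfg0$dt + 1e-9)
  expect_equal(dif$value[length(dif$value)], cfg0$pparg_high, tolerance = 0.02)
  # 10-90% rise time of the switch component is ~4 h
  step <- dif$value - und$value * 0  # noise-free switch-dominated trace
  lo <- min(dif$value); hi <- max(dif$value)
  t10 <- dif$time[which(dif$value >= lo + 0.1 * (hi - lo))[1]]
  t90 <- dif$time[which(dif$value >= lo + 0.9 * (hi - lo))[1]]
  expect_equal(t90 - t10, 4, tolerance = 1.0)
  # invalid commitment times are rejected
  expect_error(generate_pparg_trace(cfg0, rep_out$anchors, "differentiated",
                                    commit_time = 120), "outside")
  expect_error(generate_pparg_trace(cfg0, rep_out$anchors, "differentiated"),
               "commit_time")
})

test_that("populations respect fate fractions, gating and reproducibility", {
  cfg <- generator_config(n_cells = 60, condition = "rosi", seed = 17)
  pop <- generate_population(cfg)
  expect_s3_class(pop, "cg_population")
  gt <- pop$ground_truth
  # differentiated <=> commitment time present; phases inside the window
  for (g in gt) {
    if (g$fate == "differentiated") {
      expect_false(is.na(g$true_commit_time))
      expect_gte(g$true_commit_phase, cfg$gating_window[1])
      expect_lte(g$true_commit_phase, cfg$gating_window[2])
    } else {
      expect_true(is.na(g$true_commit_time))
    }
  }
  # frac_differentiating = 0 gives no commitment records
  pop0 <- generate_population(generator_config(n_cells = 30,
                                               condition = "control",
                                               seed = 17))
  expect_true(all(vapply(pop0$ground_truth, function(g)
    g$fate == "undifferentiated", logical(1))))
  # bit-for-bit reproducibility and per-cell stream independence
  pop2 <- generate_population(cfg)
  expect_identical(pop$traces, pop2$traces)
  big <- generate_population(generator_config(n_cells = 65, condition = "rosi",
                                              seed = 17))
  small_df <- as.data.frame(pop$traces)
  big_df <- as.data.frame(big$traces)
  expect_identical(small_df[small_df$cell_id == "cell_0001", ],
                   big_df[big_df$cell_id == "cell_0001", ])
  # too-short duration errors
  expect_error(generate_population(generator_config(n_cells = 2, duration = 20,
                                                    dt = 0.2)),
               "full reporter cycle")
})

test_that("phase-time inversion and endpoint bimodality hold by construction", {
  cfg <- generator_config(n_cells = 80, condition = "rosi", seed = 23,
                          measurement_noise_cv = 0)
  pop <- generate_population(cfg)
  tab <- as.data.frame(pop$traces)
  ends <- list(differentiated = c(), undifferentiated = c())
  for (g in pop$ground_truth) {
    if (g$fate == "differentiated") {
      map <- build_phase_map(anchor_set(g$true_anchor_times,
                                        g$true_anchor_kinds))
      expect_equal(phase_at_time(map, g$true_commit_time) %% (2 * pi),
                   g$true_commit_phase %% (2 * pi), tolerance = 1e-9)
    }
    tr <- tab[tab$cell_id == g$cell_id & tab$channel == "pparg", ]
    ends[[g$fate]] <- c(ends[[g$fate]], tr$value[nrow(tr)])
  }
  expect_gt(min(ends$differentiated), max(ends$undifferentiated))
})

test_that("division frequency matches the configured probability", {
  cfg <- generator_config(n_cells = 1000, condition = "rosi", seed = 29,
                          division_prob = 0.05)
  pop <- generate_population(cfg)
  ndiv <- sum(vapply(pop$ground_truth, function(g)
    length(g$division_times) > 0L, logical(1)))
  ci <- qnorm(c(0.025, 0.975), 0.05, sqrt(0.05 * 0.95 / 1000))
  expect_gte(ndiv / 1000, ci[1])
  expect_lte(ndiv / 1000, ci[2])
  # at most one division, within the first 24 h
  for (g in pop$ground_truth) {
    expect_lte(length(g$division_times), 1L)
    if (length(g$division_times)) expect_lte(g$division_times, 24)
  }
})
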