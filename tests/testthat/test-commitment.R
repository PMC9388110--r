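test_that("ground-truth cutoff implements the strict <3% rule", {
  # brute-force oracle over all order statistics
  brute <- function(x, f) {
    s <- sort(unique(x))
    s[which(vapply(s, function(c) mean(x > c) < f, logical(1)))[1]]
  }
  expect_equal(ground_truth_cutoff(1:100), brute(1:100, 0.03))
  expect_equal(ground_truth_cutoff(1:100), 98)   # 97th leaves exactly 3%: move up
  expect_equal(mean((1:100) > ground_truth_cutoff(1:100)), 0.02)
  # identical controls: cutoff equals the common value, none above
  expect_equal(ground_truth_cutoff(rep(5.5, 60)), 5.5)
  # property: strict bound holds on random inputs
  set.seed(13)
  for (i in 1:20) {
    x <- rlnorm(50 + i * 7)
    expect_lt(mean(x > ground_truth_cutoff(x)), 0.03)
    expect_equal(ground_truth_cutoff(x), brute(x, 0.03))
  }
  expect_error(ground_truth_cutoff(numeric(0)), "no control")
})

test_that("ROC scan separates disjoint classes and matches the rank oracle", {
  t <- seq(0, 48, 0.2)
  mk <- function(peak) trace_series(t, peak * exp(-(t - 24)^2 / 50), "pparg")
  set.seed(5)
  hi <- lapply(runif(30, 2, 3), mk)
  lo <- lapply(runif(40, 0.5, 1), mk)
  traces <- c(hi, lo)
  names(traces) <- paste0("c", seq_along(traces))
  labels <- fate_labels(setNames(c(rep(2.5, 30), rep(0.7, 40)),
                                 names(traces)), 1.5)
  roc <- roc_threshold_scan(traces, labels)
  expect_equal(roc$auc, 1.0)
  stat <- vapply(traces, function(tr) max(tr$value), numeric(1))
  # perfect separation: threshold sits in the gap between the class maxima
  # (ties at the corner break toward the lower threshold)
  expect_gte(roc$optimal_threshold, max(stat[labels$label == "undifferentiated"]))
  expect_lt(roc$optimal_threshold, min(stat[labels$label == "differentiated"]))
  expect_true(all(diff(roc$tpr) <= 1e-12) && all(diff(roc$fpr) <= 1e-12))
  # AUC equals the Mann-Whitney oracle on noisy overlapping classes
  set.seed(8)
  ov <- lapply(rlnorm(120, 0, 0.5), mk)
  names(ov) <- paste0("v", seq_along(ov))
  lab2 <- fate_labels(setNames(rep(c(2, 0.5), 60), names(ov)), 1)
  roc2 <- roc_threshold_scan(ov, lab2)
  stat <- vapply(ov, function(tr) max(tr$value), numeric(1))
  expect_equal(roc2$auc,
               mw_auc_oracle(stat[lab2$label == "differentiated"],
                             stat[lab2$label == "undifferentiated"]),
               tolerance = 1e-9)
  # permuted labels give chance-level AUC
  set.seed(21)
  lab3 <- lab2
  lab3$label <- sample(lab3$label)
  expect_lt(abs(roc_threshold_scan(ov, lab3)$auc - 0.5), 0.15)
  # single-class labels are an error
  lab4 <- lab2; lab4$label <- "differentiated"
  expect_error(roc_threshold_scan(ov, lab4), "both fate classes")
})

test_that("commitment times are first crossings with linear interpolation", {
  t <- seq(0, 96, 0.2)
  ramp <- trace_series(t, t, "pparg", "ramp")
  below <- trace_series(t, rep(10, length(t)), "pparg", "below")
  rec <- assign_commitment_times(list(ramp = ramp, below = below), 48)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$commit_time, 48, tolerance = 1e-9)
  # interpolation between samples: crossing of 47.9 on a 0.2-h grid
  rec2 <- assign_commitment_times(list(ramp = ramp), 47.9)
  expect_equal(rec2$commit_time, 47.9, tolerance = 1e-9)
  # monotone in threshold: higher thresholds never commit earlier
  set.seed(4)
  noisy <- trace_series(t, cumsum(rnorm(length(t), 0.05, 0.2)), "pparg", "n")
  ths <- quantile(noisy$value, c(0.3, 0.5, 0.7, 0.9))
  cts <- vapply(ths, function(th) {
    r <- assign_commitment_times(list(n = noisy), th)
    if (nrow(r)) r$commit_time else Inf
  }, numeric(1))
  expect_true(all(diff(cts) >= 0))
})

test_that("commitment-time recovery on synthetic populations is accurate", {
  cfg <- generator_config(n_cells = 150, condition = "rosi", seed = 41)
  pop <- generate_population(cfg)
  pparg <- lapply(population_traces(pop, "pparg"), smooth_moving_average)
  ctrl <- generate_population(generator_config(n_cells = 150,
                                               condition = "control",
                                               seed = 42))
  term_ctrl <- vapply(lapply(population_traces(ctrl, "pparg"),
                             smooth_moving_average),
                      function(tr) tr$value[length(tr$value)], numeric(1))
  cutoff <- ground_truth_cutoff(term_ctrl)
  term <- vapply(pparg, function(tr) tr$value[length(tr$value)], numeric(1))
  roc <- roc_threshold_scan(pparg, fate_labels(term, cutoff))
  rec <- assign_commitment_times(pparg, roc$optimal_threshold)
  truth <- vapply(pop$ground_truth, function(g) g$true_commit_time,
                  numeric(1))
  err <- rec$commit_time - truth[rec$cell_id]
  expect_lte(median(abs(err), na.rm = TRUE), 1)
})

test_that("alignment to commitment centers the switch at relative time 0", {
  cfg <- generator_config(n_cells = 120, condition = "rosi", seed = 43)
  pop <- generate_population(cfg)
  pparg <- lapply(population_traces(pop, "pparg"), smooth_moving_average)
  term <- vapply(pparg, function(tr) tr$value[length(tr$value)], numeric(1))
  roc <- roc_threshold_scan(pparg, fate_labels(term, 1.1))
  rec <- assign_commitment_times(pparg, roc$optimal_threshold)
  al <- align_to_commitment(pparg, rec, window = 12)
  i0 <- which.min(abs(al$rel_time))
  # median aligned trace crosses the threshold at relative time 0 (+/- dt)
  cross <- al$rel_time[which(al$median > roc$optimal_threshold)[1]]
  expect_lte(abs(cross), cfg$dt + 1e-9)
  # 10-90% rise of the median aligned trace ~ commit_switch_duration
  lo <- min(al$median, na.rm = TRUE); hi <- max(al$median, na.rm = TRUE)
  t10 <- al$rel_time[which(al$median >= lo + 0.1 * (hi - lo))[1]]
  t90 <- al$rel_time[which(al$median >= lo + 0.9 * (hi - lo))[1]]
  expect_equal(t90 - t10, cfg$commit_switch_duration, tolerance = 1.5)
  # single trace aligns to itself shifted
  one <- align_to_commitment(pparg[rec$cell_id[1]], rec[1, ], window = 6)
  expect_equal(one$median,
               approx(pparg[[rec$cell_id[1]]]$time - rec$commit_time[1],
                      pparg[[rec$cell_id[1]]]$value, xout = one$rel_time)$y)
  expect_error(align_to_commitment(pparg, rec[0, ], window = 6), "no commitment")
})
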