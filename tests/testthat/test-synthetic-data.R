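# Synthetic cohort generators: geometry, planted ground truth, simulators.

test_that("geometry is a valid great-circle metric on the unit sphere", {
  g <- generate_geometry(100, seed = 2)
  d <- g$distance_matrix
  expect_equal(diag(d), rep(0, 100))
  expect_true(isSymmetric(d))
  # brute-force bound over all pairs: geodesic distance on the unit sphere
  # can never exceed pi
  expect_true(all(d <= pi + 1e-12))
  # spot-check the triangle inequality on a subsample
  idx <- seq(1, 100, by = 7)
  for (i in idx) for (j in idx) for (k in idx)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-10)
  # rows are unit vectors
  expect_equal(rowSums(g$coordinates^2), rep(1, 100))
})

test_that("geometry is seeded-deterministic and validates its arguments", {
  expect_identical(generate_geometry(360, seed = 1),
                   generate_geometry(360, seed = 1))
  g3 <- generate_geometry(3, seed = 0)
  expect_equal(diag(g3$distance_matrix), rep(0, 3))
  expect_error(generate_geometry(2, seed = 1), "n_parcels")
})

test_that("ground truth plants the configured rank correlations", {
  gt <- generate_ground_truth(360, 24, seed = 5)
  amp <- rowMeans(abs(gt$evoked_amp))
  rho_tau <- spearman(gt$hierarchy, gt$tau_true)
  expect_gt(rho_tau, 0.5); expect_lt(rho_tau, 0.7)
  expect_lt(spearman(gt$hierarchy, gt$myelin_true), -0.5)
  expect_lt(spearman(gt$hierarchy, amp), -0.5)
  expect_true(all(gt$tau_true > 0))
  expect_true(all(gt$task_coupling_scale > 0 & gt$task_coupling_scale <= 1))
})

test_that("noiseless ground truth is an exact monotone image of the hierarchy", {
  gt <- generate_ground_truth(80, 4, seed = 9,
                              config = effect_config(noise_level = 0))
  expect_equal(spearman(gt$hierarchy, gt$tau_true), 1)
  expect_equal(spearman(gt$hierarchy, gt$myelin_true), -1)
  # mean |amplitude| equals the planted base amplitude exactly by row
  # normalization, so its rank correlation is exact too
  expect_equal(spearman(gt$hierarchy, rowMeans(abs(gt$evoked_amp))), -1)
})

test_that("ground truth is seeded-deterministic and rejects bad configs", {
  expect_identical(generate_ground_truth(50, 4, seed = 3),
                   generate_ground_truth(50, 4, seed = 3))
  expect_error(generate_ground_truth(50, 4, seed = 3,
                                     config = effect_config(rho_hierarchy_tau = 1.2)),
               "correlations")
})

test_that("rest simulation matches the analytic AR(1) autocorrelation", {
  gt <- with_constant_tau(tiny_gt(5, 2, seed = 1, coupling_strength = 0),
                          tau = 1.44)
  ts <- simulate_rest_timeseries(gt, n_tr = 20000, tr_s = 0.72, seed = 4)
  lag1 <- vapply(seq_len(5), function(j)
    stats::cor(ts[-1, j], ts[-nrow(ts), j]), numeric(1))
  expect_equal(lag1, rep(exp(-0.5), 5), tolerance = 0.05)
  # near-white limit: tiny timescale kills the lag-1 autocorrelation
  gt0 <- with_constant_tau(gt, 0.05)
  ts0 <- simulate_rest_timeseries(gt0, n_tr = 5000, tr_s = 0.72, seed = 4)
  expect_lt(max(abs(vapply(seq_len(5), function(j)
    stats::cor(ts0[-1, j], ts0[-nrow(ts0), j]), numeric(1)))), 0.06)
})

test_that("lag-k autocorrelation follows exp(-k tr / tau) out to three timescales", {
  gt <- tiny_gt(6, 2, seed = 7)   # coupling on: shared drivers are white, so
                                  # the per-parcel ACF is unchanged
  ts <- simulate_rest_timeseries(gt, n_tr = 10000, tr_s = 0.72, seed = 8)
  for (j in seq_len(6)) {
    tau <- gt$tau_true[j]
    kmax <- max(1L, floor(3 * tau / 0.72))
    emp <- autocorrelation(ts[, j], max_lag = kmax)$values[-1]
    expect_lt(max(abs(emp - exp(-(seq_len(kmax)) * 0.72 / tau))), 0.05)
  }
})

test_that("uncoupled parcels have near-zero off-diagonal correlation", {
  gt <- tiny_gt(10, 2, seed = 2, coupling_strength = 0)
  ts <- simulate_rest_timeseries(gt, n_tr = 8000, tr_s = 0.72, seed = 3)
  fc <- correlation_fc(ts)
  expect_lt(mean(abs(fc[upper.tri(fc)])), 0.03)
})

test_that("rest simulation validates arguments", {
  gt <- tiny_gt(5, 2)
  gt_bad <- gt; gt_bad$tau_true[2] <- -1
  expect_error(simulate_rest_timeseries(gt_bad, 300, 0.72, seed = 1), "tau")
  expect_error(simulate_rest_timeseries(gt, 100, 0.72, seed = 1), "n_tr")
})

test_that("null task with intact coupling reproduces the rest stream exactly", {
  gt <- tiny_gt(8, 3, seed = 5, amp_max = 0, coupling_reduction = 0)
  gt$evoked_amp[] <- 0
  d <- tiny_design(3)
  task <- simulate_task_timeseries(gt, d, seed = 21)
  rest <- simulate_rest_timeseries(gt, n_tr = d$n_tr, tr_s = d$tr_s, seed = 21)
  expect_equal(unname(task), unname(rest))
})

test_that("noiseless task equals amplitude times the convolved regressor", {
  gt <- tiny_gt(5, 2, seed = 5)
  gt$evoked_amp[] <- 0
  gt$evoked_amp[1, 1] <- 1
  d <- tiny_design(2)
  ts <- simulate_task_timeseries(gt, d, seed = 3, noise_scale = 0)
  regs <- build_condition_regressors(d)
  expect_equal(unname(ts[, 1]), unname(regs[, 1]))
  expect_equal(max(abs(ts[, -1])), 0)
})

test_that("overlapping blocks are rejected", {
  d <- tiny_design(2)
  d$events$onset[2] <- d$events$onset[1] + 0.5 * d$events$duration[1]
  gt <- tiny_gt(5, 2)
  expect_error(simulate_task_timeseries(gt, d, seed = 1), "overlap")
})

test_that("planted coupling reduction produces negative FC change for activating parcels", {
  gt <- tiny_gt(40, 4, seed = 11, coupling_tau_weight = 0)
  d <- tiny_design(4, blocks_per_condition = 3)
  dg <- matrix(NA_real_, 3, 40)
  for (s in 1:3) {
    rest <- simulate_rest_timeseries(gt, d$n_tr, d$tr_s, seed = 100 + s)
    task <- simulate_task_timeseries(gt, d, seed = 200 + s)
    tfc <- correlation_fc(suppressWarnings(fir_regress(task, d)),
                          intervals_from_design(d))
    rfc <- suppressWarnings(matched_rest_fc(rest, d))
    dg[s, ] <- fc_change_map(tfc, rfc)
  }
  amp <- rowMeans(abs(gt$evoked_amp))
  strong <- amp >= stats::quantile(amp, 0.75)
  expect_lt(mean(dg[, strong]), 0)
  expect_lt(mean(dg[, strong]), mean(dg[, !strong]))
})

test_that("block designs have the declared layout", {
  d <- generate_block_design(1, 2, 10, 10, 0.72)
  expect_equal(nrow(d$events), 2)
  expect_true(all(d$events$onset >= 0))
  b <- cortexflow:::design_block_tr(d)
  expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  expect_equal(nrow(generate_block_design(24, 3, 18, 10.8, 0.72)$events),
               24 * 3)
  expect_error(generate_block_design(2, 2, 0, 10, 0.72), "block_len_s")
  expect_error(generate_block_design(4, 2, 18, 10.8, 0.72, n_tr = 50),
               "longer than")
})

test_that("confound sets have the contracted shapes and are seeded", {
  cs <- generate_confounds(200, seed = 9)
  expect_equal(ncol(cs$motion), 6)
  expect_gte(ncol(cs$wm_ts), 5)
  expect_gte(ncol(cs$vent_ts), 5)
  expect_identical(cs, generate_confounds(200, seed = 9))
  cs10 <- generate_confounds(10, seed = 1)
  expect_equal(unique(c(nrow(cs10$motion), nrow(cs10$wm_ts),
                        nrow(cs10$vent_ts))), 10L)
})
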