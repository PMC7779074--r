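# Regression-free block-peak approach.

make_design_1cond <- function() tiny_design(1, blocks_per_condition = 3)

test_that("inter-block baselining subtracts the rest-period mean", {
  d <- make_design_1cond()
  b <- cortexflow:::design_block_tr(d)
  ts <- matrix(3, d$n_tr, 2)     # rest level 3 everywhere
  for (k in seq_len(nrow(b))) ts[b$start[k]:(b$end[k] - 1), ] <- 5
  out <- baseline_to_interblock_rest(ts, d)
  expect_equal(unique(out[b$start[1]:(b$end[1] - 1), 1]), 2)
  # constant series: all zeros
  expect_equal(max(abs(baseline_to_interblock_rest(matrix(7, d$n_tr, 1), d))), 0)
  # idempotence
  expect_equal(baseline_to_interblock_rest(out, d), out)
})

test_that("block peaks keep the sign of the max-absolute element", {
  d <- generate_block_design(1, 1, block_len_s = 3 * 0.72, rest_len_s = 7.2,
                             tr_s = 0.72)
  b <- cortexflow:::design_block_tr(d)
  ts <- matrix(0, d$n_tr, 2)
  ts[b$start[1]:(b$start[1] + 2), 1] <- c(1, -4, 2)
  ts[b$start[1]:(b$start[1] + 2), 2] <- c(3, -3, 0)   # tie: earliest wins
  pk <- extract_block_peaks(ts, d)
  expect_equal(unname(pk$peaks[1, ]), c(-4, 3))
  expect_equal(nrow(pk$peaks), nrow(d$events))
  pk_abs <- extract_block_peaks(ts, d, magnitude_only = TRUE)
  expect_equal(unname(pk_abs$peaks[1, ]), c(4, 3))
})

test_that("peak activation map averages peaks across blocks", {
  pk <- structure(list(peaks = matrix(c(2, 4, 0, 0), 2, 2),
                       block_condition = c("c01", "c01")),
                  class = "block_peaks")
  expect_equal(peak_activation_map(pk), c(3, 0))
})

test_that("peak FC matches the shared-gain closed form", {
  # planted model: peak_{b,i} = a_i * g_b + e_{b,i};
  # corr(i, j) = a_i a_j var(g) / sqrt((a_i^2 var g + s^2)(a_j^2 var g + s^2))
  set.seed(15)
  n_blocks <- 4000
  a <- c(2, 1, 0.5)
  g <- rnorm(n_blocks, sd = 1)
  peaks <- outer(g, a) + matrix(rnorm(n_blocks * 3, sd = 0.8), n_blocks, 3)
  pk <- structure(list(peaks = peaks,
                       block_condition = rep("c01", n_blocks)),
                  class = "block_peaks")
  fc <- peak_fc(pk)
  closed_form <- function(ai, aj)
    ai * aj / sqrt((ai^2 + 0.64) * (aj^2 + 0.64))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(fc[i, j], closed_form(a[i], a[j]), tolerance = 0.03)
  expect_symmetric_unit_diag(fc)
  # identical peak vectors correlate at exactly 1
  pk2 <- structure(list(peaks = cbind(peaks[, 1], peaks[, 1]),
                        block_condition = pk$block_condition),
                   class = "block_peaks")
  expect_equal(peak_fc(pk2)[1, 2], 1)
  pk3 <- pk; pk3$peaks <- pk$peaks[1:2, ]
  expect_error(peak_fc(pk3), "3 blocks")
})

test_that("pseudo-block rest peaks mirror the task machinery", {
  d <- make_design_1cond()
  gt <- tiny_gt(8, 1, seed = 16)
  rest_long <- simulate_rest_timeseries(gt, max(200L, d$n_tr), d$tr_s,
                                        seed = 17)
  rfc <- pseudo_block_rest_peak_fc(rest_long, d)
  expect_symmetric_unit_diag(rfc)
  # identical input on both sides gives zero FC change
  rest <- rest_long[seq_len(d$n_tr), ]
  task_like <- extract_block_peaks(baseline_to_interblock_rest(rest, d), d)
  expect_equal(max(abs(fc_change_map(peak_fc(task_like), rfc))), 0)
  # pseudo-block count equals the task block count
  expect_equal(nrow(task_like$peaks), nrow(d$events))
})

test_that("stationary null: peak FC change centred on zero over simulations", {
  d <- tiny_design(1, blocks_per_condition = 6)
  gt <- tiny_gt(10, 1, seed = 18)
  deltas <- vapply(1:10, function(s) {
    a <- simulate_rest_timeseries(gt, d$n_tr, d$tr_s, seed = 300 + s)
    b <- simulate_rest_timeseries(gt, d$n_tr, d$tr_s, seed = 600 + s)
    pk <- extract_block_peaks(baseline_to_interblock_rest(a, d), d)
    mean(fc_change_map(peak_fc(pk), pseudo_block_rest_peak_fc(b, d)))
  }, numeric(1))
  se <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 0.01)
})

test_that("the peak module never calls task regression", {
  # structural: the peak path is regression-free by construction
  fns <- c(baseline_to_interblock_rest, extract_block_peaks,
           peak_activation_map, peak_fc, pseudo_block_rest_peak_fc)
  for (f in fns) {
    body_text <- paste(deparse(body(f)), collapse = " ")
    expect_false(grepl("fir_regress|fit_activation_glm|nuisance_regress",
                       body_text))
  }
})
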