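# Canonical-HRF activation GLM, group magnitude maps, FIR task regression.

test_that("canonical HRF has the declared double-gamma shape", {
  h <- canonical_hrf(0.72)
  expect_equal(h[1], 0)
  expect_equal(length(h), ceiling(32 / 0.72))
  expect_equal(max(h), 1)
  # dense-grid oracle on the closed form: peak close to 5 s
  tr_fine <- 0.01
  h_fine <- canonical_hrf(tr_fine)
  oracle <- stats::optimize(function(t) stats::dgamma(t, 6, 1) -
                              stats::dgamma(t, 16, 1) / 6,
                            c(2, 10), maximum = TRUE)$maximum
  expect_equal((which.max(h_fine) - 1) * tr_fine, oracle, tolerance = 0.02)
  expect_error(canonical_hrf(0), "tr_s")
})

test_that("condition regressors are HRF-convolved boxcars", {
  tr <- 0.72
  # single 1-TR event: the column is the kernel shifted to the onset
  d1 <- generate_block_design(1, 1, block_len_s = tr, rest_len_s = 7.2,
                              tr_s = tr)
  h <- canonical_hrf(tr)
  r1 <- build_condition_regressors(d1, h)
  onset_tr <- floor(d1$events$onset / tr)
  expected <- c(rep(0, onset_tr), h, rep(0, d1$n_tr))[seq_len(d1$n_tr)]
  expect_equal(unname(r1[, 1]), expected, tolerance = 1e-12)
  # two non-overlapping blocks: direct summation oracle
  d2 <- generate_block_design(1, 2, block_len_s = 7.2, rest_len_s = 14.4,
                              tr_s = tr)
  r2 <- build_condition_regressors(d2, h)
  b <- cortexflow:::design_block_tr(d2)
  oracle <- numeric(d2$n_tr)
  for (k in 1:2) {                     # sum of kernels shifted to each in-block TR
    for (s in b$start[k]:(b$end[k] - 1)) {
      idx <- s + seq_along(h) - 1L
      ok <- idx <= d2$n_tr
      oracle[idx[ok]] <- oracle[idx[ok]] + h[ok]
    }
  }
  expect_equal(unname(r2[, 1]), oracle, tolerance = 1e-8)
  # unknown label errors
  expect_error(build_condition_regressors(d2, h, conditions = "zzz"),
               "unknown")
})

test_that("activation GLM recovers planted coefficients", {
  d <- tiny_design(3)
  regs <- build_condition_regressors(d)
  # noiseless recovery
  ts <- cbind(p1 = 2.5 * regs[, 1])
  fit <- fit_activation_glm(ts, regs)
  expect_equal(unname(fit$betas[1, ]), c(2.5, 0, 0), tolerance = 1e-10)
  # pseudoinverse oracle on noisy data
  set.seed(6)
  ts2 <- matrix(rnorm(d$n_tr * 4), d$n_tr, 4)
  fit2 <- fit_activation_glm(ts2, regs)
  X <- cbind(1, regs)
  oracle <- t(solve(crossprod(X)) %*% crossprod(X, ts2))[, -1]
  expect_equal(unname(fit2$betas), unname(oracle), tolerance = 1e-8)
  # rank deficiency is reported with the offending column
  expect_error(fit_activation_glm(ts2, cbind(regs, dup = regs[, 1])),
               "rank deficient")
})

test_that("pure-noise coefficients are centred on zero", {
  d <- tiny_design(2, blocks_per_condition = 2)
  regs <- build_condition_regressors(d)
  set.seed(7)
  betas <- replicate(60, {
    fit_activation_glm(matrix(rnorm(d$n_tr), ncol = 1), regs)$betas[1, 1]
  })
  expect_lt(abs(mean(betas)), 3 * stats::sd(betas) / sqrt(60))
})

test_that("group activation magnitude follows the one-sample t definition", {
  mk <- function(b) structure(list(betas = b, conditions = colnames(b),
                                   subject_id = "s"),
                              class = "activation_result")
  # n = 4 subjects, one parcel, one condition; oracle = stats::t.test
  vals <- c(0.8, 1.1, 1.3, 0.9)
  res <- lapply(vals, function(v) mk(matrix(v, 1, 1,
                                            dimnames = list("p1", "c01"))))
  mag <- group_activation_magnitude(res)
  expect_equal(as.numeric(mag), abs(unname(stats::t.test(vals)$statistic)))
  # all-zero convention: t = 0
  res0 <- lapply(1:4, function(i) mk(matrix(0, 1, 1)))
  expect_equal(as.numeric(group_activation_magnitude(res0)), 0)
  # sign-flip invariance through the absolute value
  res_neg <- lapply(-vals, function(v) mk(matrix(v, 1, 1)))
  expect_equal(group_activation_magnitude(res_neg), mag)
  expect_error(group_activation_magnitude(res[1:2]), "3 subjects")
})

test_that("FIR regression removes arbitrary evoked shapes completely", {
  d <- tiny_design(2, blocks_per_condition = 3)
  b <- cortexflow:::design_block_tr(d)
  # decidedly non-HRF evoked shape: sawtooth within each block
  ev <- numeric(d$n_tr)
  for (k in seq_len(nrow(b))) {
    len <- b$end[k] - b$start[k]
    amp <- if (b$trial_type[k] == "c01") 4 else -2
    ev[b$start[k]:(b$end[k] - 1)] <- amp * seq_len(len) / len
  }
  set.seed(8)
  ts <- cbind(ev + rnorm(d$n_tr, sd = 0.5))
  resid <- suppressWarnings(fir_regress(ts, d, post_offset_lags = 25))
  for (cond in d$conditions) {
    bta_before <- block_triggered_average(ts[, 1], d, cond)
    bta_after <- block_triggered_average(resid[, 1], d, cond)
    expect_lt(max(abs(bta_after)), 1e-8 * max(abs(bta_before)))
  }
})

test_that("FIR regression leaves orthogonal signals alone (up to demeaning)", {
  d <- tiny_design(1, blocks_per_condition = 2)
  F <- cortexflow:::fir_design(d, 25)
  # build a signal orthogonal to the FIR columns and the intercept
  set.seed(9)
  basis <- qr.Q(qr(cbind(1, F, rnorm(d$n_tr))))
  sig <- basis[, ncol(basis)]
  out <- fir_regress(cbind(sig), d, 25)
  expect_equal(unname(out[, 1]), sig - mean(sig), tolerance = 1e-8)
})

test_that("FIR window spans onset to offset + 25 TRs by default", {
  expect_equal(formals(fir_regress)$post_offset_lags, 25)
  # a long trailing rest so the full post-offset window fits inside the run
  d <- generate_block_design(1, 1, block_len_s = 14.4, rest_len_s = 21.6,
                             tr_s = 0.72)
  F <- cortexflow:::fir_design(d, 25)
  b <- cortexflow:::design_block_tr(d)
  expect_equal(ncol(F), (b$end[1] - b$start[1]) + 25)
})
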