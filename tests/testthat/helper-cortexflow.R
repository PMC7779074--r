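# Shared fixtures, built in code. Kept deliberately small; heavier cohorts
# are constructed inside the tests that need them.

# A compact ground truth + design reused by several integration tests.
tiny_gt <- function(n_parcels = 40, n_conditions = 4, seed = 42, ...) {
  generate_ground_truth(n_parcels, n_conditions, seed = seed,
                        config = effect_config(...))
}

tiny_design <- function(n_conditions = 4, blocks_per_condition = 2,
                        block_len_s = 14.4, rest_len_s = 10.8, tr_s = 0.72) {
  generate_block_design(n_conditions, blocks_per_condition, block_len_s,
                        rest_len_s, tr_s)
}

# Set every parcel's true timescale to a constant (keeps the rest of the
# planted structure intact); used for analytic AR(1) checks.
with_constant_tau <- function(gt, tau) {
  gt$tau_true[] <- tau
  gt
}

# Block-triggered average of a (residualized) series for one condition:
# the per-lag mean across that condition's blocks.
block_triggered_average <- function(ts_col, design, condition) {
  b <- cortexflow:::design_block_tr(design)
  b <- b[b$trial_type == condition, , drop = FALSE]
  len <- min(b$end - b$start)
  rowMeans(vapply(seq_len(nrow(b)), function(k)
    ts_col[b$start[k]:(b$start[k] + len - 1L)], numeric(len)))
}

expect_symmetric_unit_diag <- function(fc) {
  expect_true(isSymmetric(unname(fc), tol = 1e-12))
  expect_equal(unname(diag(fc)), rep(1, nrow(fc)))
  expect_true(all(fc >= -1 - 1e-12 & fc <= 1 + 1e-12))
}
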