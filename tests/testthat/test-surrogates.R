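# Variogram-matched surrogate maps and permutation/bootstrap statistics.

smooth_map <- function(geometry, seed, scale = 0.15) {
  L <- cortexflow:::spatial_chol(geometry, scale)
  withr::with_seed(seed,
    as.numeric(crossprod(L, stats::rnorm(nrow(geometry$distance_matrix)))))
}

test_that("empirical variogram matches hand enumeration on a 4-parcel toy", {
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 1; d[1, 3] <- d[3, 1] <- 2; d[1, 4] <- d[4, 1] <- 3
  d[2, 3] <- d[3, 2] <- 1; d[2, 4] <- d[4, 2] <- 2; d[3, 4] <- d[4, 3] <- 1
  x <- c(1, 2, 4, 7)
  vg <- empirical_variogram(x, d, n_bins = 3)
  # hand enumeration of all six pairs: bin 1 (h <= 1): pairs (1,2),(2,3),(3,4)
  # -> 0.5 * mean(1, 4, 9); bin 2: (1,3),(2,4) -> 0.5 * mean(9, 25);
  # bin 3: (1,4) -> 0.5 * 36
  expect_equal(vg$gamma, c(mean(c(1, 4, 9)) / 2, mean(c(9, 25)) / 2, 18))
  expect_equal(vg$n, c(3L, 2L, 1L))
  # homogeneity: scaling the map scales semivariance quadratically
  expect_equal(empirical_variogram(3 * x, d, n_bins = 3)$gamma, 9 * vg$gamma)
  # constant map: all-zero semivariance
  expect_equal(empirical_variogram(rep(5, 4), d, n_bins = 3)$gamma, rep(0, 3))
})

test_that("surrogates permute the source values and match its variogram", {
  g <- generate_geometry(100, seed = 3)
  map <- smooth_map(g, seed = 7)
  ens <- surrogate_maps(map, g, n_surrogates = 120, seed = 11)
  # value multiset is preserved exactly by rank-remapping
  for (s in c(1, 60, 120))
    expect_equal(sort(ens$maps[s, ]), sort(map))
  # median relative variogram error across surrogates within 15%
  vg <- empirical_variogram(map, g)
  relerr <- apply(ens$maps, 1, function(m) {
    v <- empirical_variogram(m, g)
    mean(abs(v$gamma - vg$gamma) / pmax(vg$gamma, 1e-12))
  })
  expect_lte(stats::median(relerr), 0.15)
  # determinism
  expect_identical(ens$maps[1:5, ],
                   surrogate_maps(map, g, 120, seed = 11)$maps[1:5, ])
  # constant maps give constant surrogates
  const <- surrogate_maps(rep(2, 100), g, 5, seed = 1)
  expect_equal(unique(as.numeric(const$maps)), 2)
})

test_that("the SA permutation test has the declared statistic and p bounds", {
  g <- generate_geometry(80, seed = 4)
  a <- smooth_map(g, seed = 8)
  ens <- surrogate_maps(a, g, n_surrogates = 99, seed = 12)
  self <- sa_perm_correlation_test(a, a, ens)
  expect_equal(self$rho, 1)
  expect_equal(self$p, 1 / 100)     # minimum attainable with 99 surrogates
  expect_error(sa_perm_correlation_test(rep(1, 80), a, ens), "constant")
  # p never below the formula bound for any second map
  b <- smooth_map(g, seed = 9)
  expect_gte(sa_perm_correlation_test(a, b, ens)$p, 1 / 100)
})

test_that("naive permutation rejects smooth-map nulls far above level", {
  g <- generate_geometry(100, seed = 5)
  n_rep <- 80
  rej_naive <- rej_sa <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    a <- smooth_map(g, seed = 1000 + 2 * r, scale = 0.3)
    b <- smooth_map(g, seed = 1001 + 2 * r, scale = 0.3)
    rej_naive[r] <- naive_perm_correlation_test(a, b, n_perm = 99,
                                                seed = 3000 + r)$p < 0.05
    ens <- surrogate_maps(a, g, n_surrogates = 99, seed = 4000 + r)
    rej_sa[r] <- sa_perm_correlation_test(a, b, ens)$p < 0.05
  }
  expect_gt(mean(rej_naive), 0.05)          # spatially blind null is too narrow
  expect_lt(mean(rej_sa), mean(rej_naive))  # surrogate null restores calibration
})

test_that("bootstrap CI behaves on degenerate and regular input", {
  g <- generate_geometry(60, seed = 6)
  a <- smooth_map(g, seed = 21)
  ci_self <- bootstrap_spearman_ci(a, a, n_boot = 200, seed = 1)
  expect_equal(as.numeric(ci_self), c(1, 1))
  b <- smooth_map(g, seed = 22)
  ci <- bootstrap_spearman_ci(a, b, n_boot = 200, seed = 2)
  rho <- attr(ci, "rho")
  expect_gte(rho, ci[1]); expect_lte(rho, ci[2])
  expect_error(bootstrap_spearman_ci(a[1:5], b[1:5], seed = 1), "10 parcels")
})

test_that("bootstrap CI coverage is near nominal on exchangeable maps", {
  # bivariate normal pairs without spatial structure, known rho
  rho_true <- 0.5
  set.seed(40)
  hits <- vapply(1:150, function(r) {
    x <- rnorm(120)
    y <- rho_true * x + sqrt(1 - rho_true^2) * rnorm(120)
    # population Spearman of a bivariate normal
    rho_s <- 6 / pi * asin(rho_true / 2)
    ci <- bootstrap_spearman_ci(x, y, n_boot = 400, seed = 5000 + r)
    ci[1] <= rho_s && rho_s <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.88)
  expect_lt(mean(hits), 1)
})

test_that("partition contrast matches the paired t definition", {
  part <- c(rep("unimodal", 4), rep("transmodal", 6))
  maps <- matrix(rnorm(5 * 10), 5, 10)
  ct <- partition_contrast(maps, part)
  diffs <- rowMeans(maps[, 5:10]) - rowMeans(maps[, 1:4])
  tt <- stats::t.test(diffs)
  expect_equal(ct$t, unname(tt$statistic))
  expect_equal(ct$p, tt$p.value)
  expect_equal(ct$df, 4)
  # swapping the labels negates the contrast
  part_sw <- ifelse(part == "unimodal", "transmodal", "unimodal")
  ct_sw <- partition_contrast(maps, part_sw)
  expect_equal(ct_sw$mean_diff, -ct$mean_diff)
  expect_equal(ct_sw$t, -ct$t)
  # all-zero maps: declared 0/0 convention
  expect_equal(partition_contrast(matrix(0, 4, 10), part)$t, 0)
  expect_error(partition_contrast(maps, rep("unimodal", 10)), "non-empty")
})

test_that("hierarchy partitions split into the configured proportions", {
  h <- sort(rnorm(90))
  part <- partition_from_hierarchy(h, prop_unimodal = 1/3)
  expect_equal(sum(part == "unimodal"), 30)
  expect_true(max(h[part == "unimodal"]) <= min(h[part == "transmodal"]))
})

test_that("BH FDR mask matches the hand step-up rule and is monotone", {
  expect_equal(fdr_correct(c(0.001, 0.02, 0.9), q = 0.05),
               c(TRUE, TRUE, FALSE))
  expect_true(all(fdr_correct(rep(0, 5), q = 0.01)))
  # hand step-up oracle on random vectors + monotonicity under shrinking
  set.seed(41)
  for (r in 1:10) {
    p <- runif(12)
    q <- 0.1
    o <- order(p)
    thresh <- max(c(0L, which(p[o] <= seq_along(p) / length(p) * q)))
    oracle <- logical(12)
    if (thresh > 0) oracle[o[seq_len(thresh)]] <- TRUE
    expect_equal(fdr_correct(p, q), oracle)
    p2 <- p; i <- sample(12, 1); p2[i] <- p2[i] / 2
    # shrinking a p-value never removes an existing discovery
    expect_true(all(!fdr_correct(p, q) | fdr_correct(p2, q)))
  }
})
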