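#' Empirical variogram of a brain map
#'
#' Semivariance as a function of inter-parcel distance:
#' `gamma(h) = mean over pairs in the bin of 0.5 * (x_i - x_j)^2`, over
#' equal-width distance bins spanning the observed range. Empty bins are
#' dropped.
#'
#' @param map Per-parcel numeric map.
#' @param geometry A `parcel_geometry` (or distance matrix) aligned to `map`.
#' @param n_bins Number of distance bins (default 25).
#' @return Object of class `variogram`: data frame with bin `center`,
#'   `gamma`, and pair count `n`.
#' @export
empirical_variogram <- function(map, geometry, n_bins = 25) {
  d <- geometry_distances(geometry)
  map <- as.numeric(map)
  if (length(map) != nrow(d))
    stop_invalid("map length (%d) does not match geometry (%d parcels)",
                 length(map), nrow(d))
  n_bins <- check_scalar_int(n_bins, "n_bins", min = 1)
  ut <- upper.tri(d)
  h <- d[ut]
  v <- 0.5 * (outer(map, map, "-")[ut])^2
  breaks <- seq(0, max(h), length.out = n_bins + 1L)
  bin <- cut(h, breaks, include.lowest = TRUE, labels = FALSE)
  gamma <- tapply(v, bin, mean)
  counts <- tapply(v, bin, length)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  keep <- as.integer(names(gamma))
  structure(data.frame(center = centers[keep], gamma = as.numeric(gamma),
                       n = as.integer(counts)),
            class = c("variogram", "data.frame"))
}

# Precompute the pairwise scaffolding reused across many variogram
# evaluations: upper-tri pair indices, their bin assignment and bin counts.
variogram_pairs <- function(d, n_bins, max_quantile = 1) {
  n <- nrow(d)
  ut <- which(upper.tri(d))
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  h <- d[ut]
  hmax <- stats::quantile(h, max_quantile, names = FALSE)
  keep <- h <= hmax
  breaks <- seq(0, hmax, length.out = n_bins + 1L)
  bin <- cut(h[keep], breaks, include.lowest = TRUE, labels = FALSE)
  list(i = i[keep], j = j[keep], bin = bin,
       counts = tabulate(bin, nbins = n_bins), n_bins = n_bins)
}

# Binned semivariances for every column of X at once.
variogram_cols <- function(X, vp) {
  diff2 <- 0.5 * (X[vp$i, , drop = FALSE] - X[vp$j, , drop = FALSE])^2
  g <- rowsum(diff2, vp$bin, reorder = TRUE)
  g / vp$counts[sort(unique(vp$bin))]
}

# k-nearest-neighbour smoothing operator on the geometry: row i averages the
# map over i's k nearest parcels (self included) with exponential distance
# weights scaled to the local k-th-neighbour distance.
knn_smoother <- function(d, k) {
  n <- nrow(d)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    dk <- max(d[i, nb])
    w <- exp(-3 * d[i, nb] / max(dk, 1e-12))
    S[i, nb] <- w / sum(w)
  }
  S
}

#' Spatial-autocorrelation-preserving surrogate brain maps
#'
#' Generates random surrogate maps whose variogram (spatial autocorrelation
#' profile) matches the source map's, for use as a permutation null that
#' respects spatial smoothness. Per surrogate: the map's values are randomly
#' permuted, smoothed by distance-weighted averaging over each parcel's k
#' nearest neighbours (k chosen from a small grid to minimize the variogram
#' discrepancy after an affine fit of the smoothed map's variogram to the
#' target variogram), and finally rank-remapped onto the source map's value
#' distribution - so every surrogate holds exactly the source values in a
#' spatially-plausible random arrangement.
#'
#' @param map Per-parcel numeric map.
#' @param geometry A `parcel_geometry` (or distance matrix).
#' @param n_surrogates Number of surrogates (default 1000).
#' @param seed Integer seed.
#' @param k_frac Candidate neighbourhood sizes as fractions of the parcel
#'   count.
#' @param n_bins Variogram bins used for matching.
#' @param match_quantile Distance quantile up to which the variogram is
#'   matched (default 0.25): short-range spatial structure dominates a map's
#'   effective smoothness, and restricting the objective there reproduces it
#'   much more faithfully than fitting the full (long-range-dominated) range.
#' @return Object of class `surrogate_ensemble`: list with `maps`
#'   (`n_surrogates x n_parcels`), chosen `k` per surrogate, `seed`.
#' @details The affine variogram fit `gamma_target ~ a * gamma_smooth + b`
#'   (coefficients constrained non-negative) is realized on the map itself as
#'   `sqrt(a) * smoothed + sqrt(b) * white noise`: the noise term supplies the
#'   short-range variance ("nugget") that pure neighbour-smoothing cannot,
#'   since for independent components semivariances add. The candidate whose
#'   realized variogram is closest to the target across the k grid wins.
#' @export
surrogate_maps <- function(map, geometry, n_surrogates = 1000, seed,
                           k_frac = c(0.03, 0.05, 0.1, 0.2, 0.3, 0.45, 0.6),
                           n_bins = 25, match_quantile = 0.25) {
  d <- geometry_distances(geometry)
  map <- as.numeric(map)
  n <- length(map)
  if (n != nrow(d))
    stop_invalid("map length (%d) does not match geometry (%d parcels)", n, nrow(d))
  if (n < 10L) stop_invalid("degenerate geometry: need at least 10 parcels")
  n_surrogates <- check_scalar_int(n_surrogates, "n_surrogates", min = 1)
  seed <- check_scalar_int(seed, "seed")
  if (stats::sd(map) == 0) {
    maps <- matrix(map[1L], n_surrogates, n)
    return(structure(list(maps = maps, k = rep(NA_integer_, n_surrogates),
                          seed = seed), class = "surrogate_ensemble"))
  }
  ks <- sort(unique(pmin(n, pmax(3L, round(n * k_frac)))))
  smoothers <- lapply(ks, function(k) knn_smoother(d, k))
  vp <- variogram_pairs(d, n_bins, max_quantile = match_quantile)
  z <- as.numeric(scale(map))           # matching happens on standard scale
  g_target <- as.numeric(variogram_cols(matrix(z, ncol = 1L), vp))

  draws <- withr::with_seed(seed, list(
    P = vapply(seq_len(n_surrogates), function(s) sample(z), numeric(n)),
    W = matrix(stats::rnorm(n * n_surrogates), n, n_surrogates)))
  sorted_vals <- sort(map)
  out <- matrix(NA_real_, n_surrogates, n)
  chosen_k <- integer(n_surrogates)
  chunk <- 100L
  for (start in seq(1L, n_surrogates, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_surrogates)
    Pc <- draws$P[, idx, drop = FALSE]
    Wc <- draws$W[, idx, drop = FALSE]
    best_rss <- rep(Inf, length(idx))
    best_Z <- matrix(NA_real_, n, length(idx))
    best_k <- integer(length(idx))
    for (ki in seq_along(ks)) {
      S <- smoothers[[ki]] %*% Pc
      G <- variogram_cols(S, vp)
      gm <- colMeans(G)
      gv <- colMeans(G^2) - gm^2
      gcv <- colMeans(G * g_target) - gm * mean(g_target)
      a <- ifelse(gv > 0, gcv / gv, 0)
      b <- mean(g_target) - a * gm
      # project onto the non-negative quadrant
      bad_a <- a < 0
      a[bad_a] <- 0; b[bad_a] <- mean(g_target)
      bad_b <- b < 0
      if (any(bad_b)) {
        a[bad_b] <- colSums(G[, bad_b, drop = FALSE] * g_target) /
          colSums(G[, bad_b, drop = FALSE]^2)
        b[bad_b] <- 0
      }
      cand <- sweep(S, 2L, sqrt(a), "*") + sweep(Wc, 2L, sqrt(b), "*")
      G2 <- variogram_cols(cand, vp)
      rss <- colSums((G2 - g_target)^2)
      better <- rss < best_rss
      if (any(better)) {
        best_rss[better] <- rss[better]
        best_Z[, better] <- cand[, better]
        best_k[better] <- ks[ki]
      }
    }
    for (c2 in seq_along(idx)) {
      out[idx[c2], ] <- sorted_vals[rank(best_Z[, c2], ties.method = "first")]
    }
    chosen_k[idx] <- best_k
  }
  structure(list(maps = out, k = chosen_k, seed = seed),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d surrogates x %d parcels (seed %d)\n",
              nrow(x$maps), ncol(x$maps), x$seed))
  invisible(x)
}

#' Spatial-autocorrelation-preserving permutation test for a map correlation
#'
#' The observed statistic is the Spearman rank correlation between the two
#' maps. The null distribution correlates each surrogate of `map_a` with
#' `map_b`; the two-tailed p-value uses the add-one correction
#' `p = (1 + #{|rho_surr| >= |rho_obs|}) / (1 + n_surrogates)`, so the
#' smallest attainable p is `1 / (n_surrogates + 1)`.
#'
#' @param map_a,map_b Per-parcel maps.
#' @param ensemble_for_a A [surrogate_maps()] ensemble built from `map_a`.
#' @param method Correlation flavour, `"spearman"` (default) or `"pearson"`.
#' @return List with `rho`, `p`, `null` (the surrogate correlations) and
#'   `n_surrogates`.
#' @export
sa_perm_correlation_test <- function(map_a, map_b, ensemble_for_a,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(ensemble_for_a, "surrogate_ensemble"))
  map_a <- as.numeric(map_a); map_b <- as.numeric(map_b)
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop_invalid("correlation undefined: a map is constant")
  rho <- stats::cor(map_a, map_b, method = method)
  null <- as.numeric(stats::cor(t(ensemble_for_a$maps), map_b, method = method))
  n_surr <- nrow(ensemble_for_a$maps)
  p <- (1 + sum(abs(null) >= abs(rho))) / (1 + n_surr)
  list(rho = rho, p = p, null = null, n_surrogates = n_surr)
}

#' Naive value-permutation test for a map correlation
#'
#' The spatially blind null: permutes the values of `map_a` uniformly,
#' ignoring spatial autocorrelation. On smooth maps this null is too narrow
#' and the test rejects far above its nominal level - the failure mode the
#' surrogate-map test exists to fix. Provided for comparison.
#'
#' @inheritParams sa_perm_correlation_test
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `rho`, `p`, `n_perm`.
#' @export
naive_perm_correlation_test <- function(map_a, map_b, n_perm = 1000, seed,
                                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  seed <- check_scalar_int(seed, "seed")
  map_a <- as.numeric(map_a); map_b <- as.numeric(map_b)
  rho <- stats::cor(map_a, map_b, method = method)
  null <- withr::with_seed(seed, vapply(seq_len(n_perm), function(s)
    stats::cor(sample(map_a), map_b, method = method), numeric(1L)))
  p <- (1 + sum(abs(null) >= abs(rho))) / (1 + n_perm)
  list(rho = rho, p = p, n_perm = n_perm)
}

#' Bootstrap confidence interval for a Spearman map correlation
#'
#' Percentile interval over parcel resamples with replacement.
#'
#' @param map_a,map_b Per-parcel maps (>= 10 parcels).
#' @param n_boot Bootstrap draws (default 1000).
#' @param level Coverage level (default 0.95).
#' @param seed Integer seed.
#' @return Numeric `c(lower, upper)` with attribute `rho` (point estimate).
#' @export
bootstrap_spearman_ci <- function(map_a, map_b, n_boot = 1000, level = 0.95,
                                  seed) {
  map_a <- as.numeric(map_a); map_b <- as.numeric(map_b)
  n <- length(map_a)
  if (n < 10L) stop_invalid("need at least 10 parcels, got %d", n)
  seed <- check_scalar_int(seed, "seed")
  rho <- spearman(map_a, map_b)
  boots <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(spearman(map_a[idx], map_b[idx]))
  }, numeric(1L)))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  # Degenerate resamples (ties collapsing a map) cannot move a perfect rank
  # agreement; keep the interval inside the attainable range.
  ci <- pmin(pmax(ci, -1), 1)
  if (rho < ci[1]) ci[1] <- rho
  if (rho > ci[2]) ci[2] <- rho
  attr(ci, "rho") <- rho
  ci
}

#' Label parcels unimodal / transmodal from a hierarchy score
#'
#' Thresholds a hierarchy map at a quantile: the lowest `prop_unimodal`
#' fraction (sensory-motor end) is labelled `"unimodal"`, the rest
#' `"transmodal"`.
#'
#' @param hierarchy Per-parcel hierarchy score.
#' @param prop_unimodal Fraction labelled unimodal (default 1/3).
#' @return Character vector of labels.
#' @export
partition_from_hierarchy <- function(hierarchy, prop_unimodal = 1/3) {
  thr <- stats::quantile(hierarchy, prop_unimodal)
  ifelse(hierarchy <= thr, "unimodal", "transmodal")
}

#' Paired transmodal-versus-unimodal contrast
#'
#' Per subject, the mean of the map within the transmodal partition minus the
#' mean within the unimodal partition; a one-sample t test of those paired
#' differences against zero (df = n_subjects - 1). The degenerate 0/0 case is
#' defined as t = 0.
#'
#' @param subject_maps `n_subjects x n_parcels` matrix (or list of per-parcel
#'   vectors), at least 3 subjects.
#' @param partition Labels from [partition_from_hierarchy()] (values
#'   `"unimodal"` / `"transmodal"`, both present).
#' @param na.rm Ignore missing parcels (e.g., non-converged timescale fits)
#'   when averaging within a partition.
#' @return List with `mean_diff`, `t`, `df`, `p`.
#' @export
partition_contrast <- function(subject_maps, partition, na.rm = FALSE) {
  if (is.list(subject_maps)) subject_maps <- do.call(rbind, subject_maps)
  if (!is.matrix(subject_maps) || !is.numeric(subject_maps))
    stop_invalid("`subject_maps` must be a numeric matrix")
  if (!na.rm && any(!is.finite(subject_maps)))
    stop_invalid("`subject_maps` contains non-finite values (use na.rm = TRUE)")
  if (nrow(subject_maps) < 3L)
    stop_invalid("need at least 3 subjects, got %d", nrow(subject_maps))
  trans <- partition == "transmodal"
  uni <- partition == "unimodal"
  if (!any(trans) || !any(uni))
    stop_invalid("both partition classes must be non-empty")
  diffs <- rowMeans(subject_maps[, trans, drop = FALSE], na.rm = na.rm) -
    rowMeans(subject_maps[, uni, drop = FALSE], na.rm = na.rm)
  n <- length(diffs)
  m <- mean(diffs); s <- stats::sd(diffs)
  t_stat <- if (m == 0 && s == 0) 0 else m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  list(mean_diff = m, t = t_stat, df = n - 1L, p = p)
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up FDR control at level `q`.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.01).
#' @return Logical significance mask.
#' @export
fdr_correct <- function(pvalues, q = 0.01) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH") <= q
}
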