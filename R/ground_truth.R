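#' Default effect configuration for the synthetic cohort
#'
#' Returns the planted effect structure used by [generate_ground_truth()].
#' The sign structure mirrors the hierarchy-organized cortex the package is
#' built to analyse: slower intrinsic timescales, lower myelin content and
#' weaker evoked responses toward the transmodal (high-hierarchy) end.
#'
#' @param rho_hierarchy_tau Target Spearman correlation between the hierarchy
#'   score and the true intrinsic timescale (positive: transmodal = slow).
#' @param rho_hierarchy_myelin Target Spearman correlation between hierarchy
#'   and the myelin proxy (negative: unimodal = heavily myelinated).
#' @param rho_hierarchy_amp Target Spearman correlation between hierarchy and
#'   the mean evoked amplitude (negative: unimodal = strongly activating).
#' @param noise_level In `[0, 1]`. 1 plants the configured correlations; 0
#'   makes every map an exact monotone transform of the hierarchy score
#'   (achieved rank correlation exactly +/-1).
#' @param spatial_scale Correlation length (radians on the unit sphere) of the
#'   exponential spatial kernel used to make every planted map spatially
#'   autocorrelated.
#' @param tau_range True timescale range in seconds, `c(min, max)`.
#' @param myelin_range Range of the myelin proxy (arbitrary T1w/T2w-like units).
#' @param amp_max Maximum mean evoked amplitude: the coefficient multiplying
#'   the HRF-convolved block regressor, in units of the unit-variance
#'   background BOLD fluctuation. The convolved regressor of an 18 s block
#'   plateaus near 7-8, so the default 0.2 yields realistic evoked responses
#'   peaking at roughly 1.5-2 noise standard deviations.
#' @param local_amp_sd Relative standard deviation of each parcel's
#'   condition-specific idiosyncratic amplitude component - the locally
#'   generated share of task activation that distributed activity flow cannot
#'   predict. 0 makes every parcel's condition profile proportional to the
#'   shared condition modulation.
#' @param n_drivers Number of shared latent drivers generating inter-parcel
#'   background coupling.
#' @param coupling_strength Fraction (0-1) of innovation amplitude each parcel
#'   receives from the shared drivers at rest.
#' @param coupling_reduction Maximum multiplicative loss of driver coupling
#'   during task; must lie in `[0, 1)` so the task coupling scale stays in
#'   `(0, 1]`.
#' @param coupling_tau_weight In `[0, 1]`: how much of the task coupling
#'   reduction follows the (inverse) intrinsic timescale rather than the
#'   evoked amplitude. Fast-timescale regions suppress their background
#'   coupling during task over and above their activation level; 0 ties the
#'   reduction to activation alone.
#' @return A named list understood by [generate_ground_truth()].
#' @export
effect_config <- function(rho_hierarchy_tau = 0.6,
                          rho_hierarchy_myelin = -0.6,
                          rho_hierarchy_amp = -0.6,
                          noise_level = 1,
                          spatial_scale = 0.15,
                          tau_range = c(0.5, 5),
                          myelin_range = c(1, 2),
                          amp_max = 0.2,
                          local_amp_sd = 0.5,
                          n_drivers = 5,
                          coupling_strength = 0.65,
                          coupling_reduction = 0.8,
                          coupling_tau_weight = 0.5) {
  cfg <- list(rho_hierarchy_tau = rho_hierarchy_tau,
              rho_hierarchy_myelin = rho_hierarchy_myelin,
              rho_hierarchy_amp = rho_hierarchy_amp,
              noise_level = noise_level,
              spatial_scale = spatial_scale,
              tau_range = tau_range,
              myelin_range = myelin_range,
              amp_max = amp_max,
              local_amp_sd = local_amp_sd,
              n_drivers = n_drivers,
              coupling_strength = coupling_strength,
              coupling_reduction = coupling_reduction,
              coupling_tau_weight = coupling_tau_weight)
  rhos <- unlist(cfg[1:3])
  if (any(abs(rhos) > 1))
    stop_invalid("target rank correlations must lie in [-1, 1]")
  if (noise_level < 0 || noise_level > 1)
    stop_invalid("noise_level must lie in [0, 1]")
  if (coupling_reduction < 0 || coupling_reduction >= 1)
    stop_invalid("coupling_reduction must lie in [0, 1)")
  if (coupling_strength < 0 || coupling_strength >= 1)
    stop_invalid("coupling_strength must lie in [0, 1)")
  if (local_amp_sd < 0) stop_invalid("local_amp_sd must be >= 0")
  if (coupling_tau_weight < 0 || coupling_tau_weight > 1)
    stop_invalid("coupling_tau_weight must lie in [0, 1]")
  if (tau_range[1] <= 0) stop_invalid("tau_range must be strictly positive")
  cfg
}

# Cholesky factor of an exponential spatial covariance on the supplied
# geometry; a small nugget keeps the factorization stable.
spatial_chol <- function(geometry, scale) {
  d <- geometry_distances(geometry)
  C <- exp(-d / scale)
  diag(C) <- diag(C) + 1e-8
  chol(C)
}

# Map a target Spearman correlation to the Pearson correlation of the
# underlying Gaussian latents (Pearson's 1907 relation for bivariate normals).
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate ground truth for a synthetic cortical cohort
#'
#' Plants, on a spherical parcel geometry, the latent quantities every
#' downstream stage tries to recover: a hierarchy score (the synthetic
#' stand-in for the principal resting-state gradient), per-parcel intrinsic
#' timescales, a myelin proxy, per-condition evoked amplitudes, shared-driver
#' background coupling, and the multiplicative task coupling reduction that
#' makes strongly activating parcels lose background connectivity during task.
#'
#' All maps are spatially autocorrelated Gaussian fields on the geometry.
#' Cross-map rank correlations are planted through a common hierarchy latent:
#' each map's latent is `r * hierarchy + sqrt(1 - r^2) * independent field`,
#' with `r` chosen so the configured Spearman target is met in expectation,
#' then pushed through a monotone transform into its natural range (so rank
#' structure is preserved exactly).
#'
#' @param n_parcels Number of parcels.
#' @param n_conditions Number of task conditions (default 24).
#' @param config Effect configuration from [effect_config()].
#' @param seed Integer seed.
#' @param geometry Optional [generate_geometry()] result; generated from a
#'   sub-seed when omitted.
#' @return An object of class `ground_truth`; see Details for fields.
#' @details Fields: `hierarchy`, `tau_true` (seconds), `myelin_true`,
#'   `evoked_amp` (`n_parcels x n_conditions`), `driver_loadings`
#'   (`n_parcels x n_drivers`, unit rows, non-negative),
#'   `coupling_strength`, `rest_coupling` (implied innovation correlation
#'   matrix), `task_coupling_scale` in `(0, 1]`, plus the geometry and the
#'   resolved config.
#' @export
generate_ground_truth <- function(n_parcels, n_conditions = 24,
                                  config = effect_config(), seed,
                                  geometry = NULL) {
  n_parcels <- check_scalar_int(n_parcels, "n_parcels", min = 3)
  n_conditions <- check_scalar_int(n_conditions, "n_conditions", min = 1)
  seed <- check_scalar_int(seed, "seed")
  config <- do.call(effect_config, config)
  if (is.null(geometry))
    geometry <- generate_geometry(n_parcels, seed = sub_seed(seed, 1))
  if (nrow(geometry_distances(geometry)) != n_parcels)
    stop_invalid("geometry has %d parcels, expected %d",
                 nrow(geometry_distances(geometry)), n_parcels)

  targets <- c(tau = config$rho_hierarchy_tau,
               myelin = config$rho_hierarchy_myelin,
               amp = config$rho_hierarchy_amp)
  # Effective rank target after the noise interpolation, then converted to the
  # Pearson correlation of the Gaussian latents.
  rho_eff <- sign(targets) * (1 - config$noise_level) +
    targets * config$noise_level
  r_lat <- spearman_to_pearson(rho_eff)
  # Feasibility: implied 4x4 latent correlation matrix (conditional
  # independence given the hierarchy latent) must be positive semi-definite.
  R <- diag(4)
  R[1, 2:4] <- R[2:4, 1] <- r_lat
  R[2:4, 2:4][upper.tri(diag(3))] <- (tcrossprod(r_lat))[upper.tri(diag(3))]
  R[2:4, 2:4][lower.tri(diag(3))] <- t(R[2:4, 2:4])[lower.tri(diag(3))]
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop_invalid("infeasible correlation structure: implied latent correlation matrix is not positive semi-definite")

  L <- spatial_chol(geometry, config$spatial_scale)
  gt <- withr::with_seed(seed, {
    n_fields <- 4L + config$n_drivers
    fields <- crossprod(L, matrix(stats::rnorm(n_parcels * n_fields),
                                  n_parcels, n_fields))
    h <- fields[, 1L]
    latents <- vapply(seq_along(r_lat), function(m) {
      r <- r_lat[m]
      r * h + sqrt(max(0, 1 - r^2)) * fields[, 1L + m]
    }, numeric(n_parcels))
    to01 <- function(z) stats::pnorm((z - mean(z)) / stats::sd(z))
    tau_true <- config$tau_range[1] +
      diff(config$tau_range) * to01(latents[, 1L])
    myelin_true <- config$myelin_range[1] +
      diff(config$myelin_range) * to01(latents[, 2L])
    amp_base <- config$amp_max * to01(latents[, 3L])
    cond_mod <- stats::runif(n_conditions, 0.8, 1.2)
    # Condition profile per parcel: a shared condition modulation plus a
    # parcel-specific idiosyncratic component. The idiosyncratic part is the
    # "local processing" ingredient: it is independent across parcels, so no
    # connectivity-weighted sum of other parcels' activations can predict it,
    # and it scales with amp_base - strongly activating (low-hierarchy)
    # parcels carry more locally generated activation. Rows are normalized to
    # unit mean absolute value so that the mean |amplitude| across conditions
    # equals amp_base exactly (rank structure planted without sampling noise).
    gmat <- outer(rep(1, n_parcels), cond_mod) +
      config$local_amp_sd * matrix(stats::rnorm(n_parcels * n_conditions),
                                   n_parcels, n_conditions)
    gmat <- gmat / rowMeans(abs(gmat))
    evoked_amp <- amp_base * gmat
    colnames(evoked_amp) <- sprintf("c%02d", seq_len(n_conditions))
    # Driver loadings: non-negative, spatially organized, unit row norm.
    W <- stats::pnorm(fields[, 4L + seq_len(config$n_drivers), drop = FALSE])
    W <- W / sqrt(rowSums(W^2))
    # Task-state suppression of background coupling: strongest for parcels
    # that activate strongly and operate at fast timescales (both are
    # unimodal-end properties of the planted hierarchy).
    w <- config$coupling_tau_weight
    suppression_drive <- rank01((1 - w) * rank01(amp_base) + w * rank01(-tau_true))
    task_coupling_scale <- 1 - config$coupling_reduction * suppression_drive
    rest_coupling <- config$coupling_strength^2 * tcrossprod(W)
    diag(rest_coupling) <- 1
    list(hierarchy = as.numeric(scale(h)),
         tau_true = tau_true,
         myelin_true = myelin_true,
         evoked_amp = evoked_amp,
         driver_loadings = W,
         coupling_strength = config$coupling_strength,
         rest_coupling = rest_coupling,
         task_coupling_scale = task_coupling_scale)
  })
  gt$geometry <- geometry
  gt$config <- config
  gt$seed <- seed
  gt$n_parcels <- n_parcels
  gt$n_conditions <- n_conditions
  class(gt) <- "ground_truth"
  gt
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d parcels, %d conditions (seed %d)\n",
              x$n_parcels, x$n_conditions, x$seed))
  cat(sprintf("  tau range [%.2f, %.2f] s; achieved rho(hierarchy, tau) = %.2f\n",
              min(x$tau_true), max(x$tau_true),
              spearman(x$hierarchy, x$tau_true)))
  cat(sprintf("  rho(hierarchy, myelin) = %.2f; rho(hierarchy, mean |amp|) = %.2f\n",
              spearman(x$hierarchy, x$myelin_true),
              spearman(x$hierarchy, rowMeans(abs(x$evoked_amp)))))
  invisible(x)
}
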