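#' Generate a block task design
#'
#' Lays out `n_conditions x blocks_per_condition` non-overlapping task blocks
#' separated by inter-block rest, cycling through all conditions in sorted
#' label order. By default the design mirrors a multi-task battery with 24
#' conditions split among 7 tasks.
#'
#' Block edges are snapped to the TR grid with the declared rounding rule:
#' onsets floor to the containing TR, offsets ceil to the next TR boundary.
#'
#' @param n_conditions Number of task conditions (default 24).
#' @param blocks_per_condition Blocks per condition.
#' @param block_len_s Block duration in seconds (> 0).
#' @param rest_len_s Inter-block rest in seconds (>= 0).
#' @param tr_s Sampling interval in seconds.
#' @param initial_rest_s Rest before the first block (defaults to
#'   `rest_len_s`).
#' @param n_tr Run length in TRs; computed to fit the design (plus a trailing
#'   rest) when omitted. An explicit value shorter than the design errors.
#' @return An object of class `task_design`: list with `events` (data frame
#'   with BIDS-style `onset`, `duration`, `trial_type` columns), `tr_s`,
#'   `n_tr`, and `conditions` (sorted labels).
#' @export
generate_block_design <- function(n_conditions = 24, blocks_per_condition = 3,
                                  block_len_s = 18, rest_len_s = 10.8,
                                  tr_s = 0.72, initial_rest_s = rest_len_s,
                                  n_tr = NULL) {
  n_conditions <- check_scalar_int(n_conditions, "n_conditions", min = 1)
  blocks_per_condition <- check_scalar_int(blocks_per_condition,
                                           "blocks_per_condition", min = 1)
  if (!is.numeric(block_len_s) || block_len_s <= 0)
    stop_invalid("block_len_s must be > 0")
  if (rest_len_s < 0 || initial_rest_s < 0)
    stop_invalid("rest durations must be >= 0")
  if (tr_s <= 0) stop_invalid("tr_s must be > 0")
  conditions <- sprintf("c%02d", seq_len(n_conditions))
  n_blocks <- n_conditions * blocks_per_condition
  trial_type <- rep(conditions, times = blocks_per_condition)
  onset <- initial_rest_s + (seq_len(n_blocks) - 1) * (block_len_s + rest_len_s)
  events <- data.frame(onset = onset, duration = block_len_s,
                       trial_type = trial_type, stringsAsFactors = FALSE)
  needed <- ceiling((max(onset) + block_len_s + rest_len_s) / tr_s)
  if (is.null(n_tr)) n_tr <- needed
  n_tr <- check_scalar_int(n_tr, "n_tr", min = 1)
  last_end <- ceiling((max(onset) + block_len_s) / tr_s)
  if (last_end > n_tr)
    stop_invalid("design is longer than the configured run (%d TRs needed, %d available)",
                 last_end, n_tr)
  structure(list(events = events, tr_s = tr_s, n_tr = n_tr,
                 conditions = conditions),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design> %d blocks, %d conditions, %d TRs @ %.3g s\n",
              nrow(x$events), length(x$conditions), x$n_tr, x$tr_s))
  invisible(x)
}

# Block boundaries on the TR grid, 1-based half-open [start, end):
# rows start:(end - 1) belong to the block. Onset floors, offset ceils.
design_block_tr <- function(design) {
  ev <- design$events
  # tolerance guards against 7.2 / 0.72 = 9.999... style float noise
  eps <- 1e-9
  start <- floor(ev$onset / design$tr_s + eps) + 1L
  end <- ceiling((ev$onset + ev$duration) / design$tr_s - eps) + 1L
  data.frame(start = as.integer(start), end = as.integer(pmin(end, design$n_tr + 1L)),
             trial_type = ev$trial_type, stringsAsFactors = FALSE)
}

# Check that no two blocks overlap on the TR grid.
check_no_overlap <- function(design) {
  b <- design_block_tr(design)
  b <- b[order(b$start), ]
  if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)]))
    stop_invalid("task design contains overlapping blocks")
  invisible(b)
}

# Shift all onsets by `shift_s` seconds (negative = earlier) and change run
# length; used after frame trimming so events stay aligned with the data.
shift_design <- function(design, shift_s, n_tr = design$n_tr) {
  design$events$onset <- design$events$onset + shift_s
  if (any(design$events$onset < 0))
    stop_invalid("shifted design has negative onsets")
  design$n_tr <- n_tr
  design
}

#' Generate a synthetic confound set
#'
#' Produces the nuisance signals the preprocessing module expects: six smooth
#' motion parameter traces plus white-matter and ventricle compartment signal
#' matrices, each driven by a few latent physiological components mixed with
#' sensor noise (so aCompCor has true structure to find).
#'
#' @param n_tr Number of timepoints (>= 10).
#' @param seed Integer seed.
#' @param n_wm,n_vent Number of compartment signal columns (default 8 each).
#' @param n_latent Latent physiological components per compartment.
#' @return Object of class `confound_set`: list with `motion`
#'   (`n_tr x 6`), `wm_ts`, `vent_ts`.
#' @export
generate_confounds <- function(n_tr, seed, n_wm = 8, n_vent = 8, n_latent = 3) {
  n_tr <- check_scalar_int(n_tr, "n_tr", min = 10)
  seed <- check_scalar_int(seed, "seed")
  n_wm <- check_scalar_int(n_wm, "n_wm", min = 1)
  n_vent <- check_scalar_int(n_vent, "n_vent", min = 1)
  smooth_ar <- function(n, m, phi = 0.95) {
    e <- matrix(stats::rnorm(n * m, sd = sqrt(1 - phi^2)), n, m)
    apply(e, 2L, function(col) stats::filter(col, phi, method = "recursive"))
  }
  withr::with_seed(seed, {
    motion <- smooth_ar(n_tr, 6L) * 0.2
    compartment <- function(m) {
      lat <- smooth_ar(n_tr, n_latent, phi = 0.9)
      load <- matrix(stats::rnorm(n_latent * m), n_latent, m)
      lat %*% load + matrix(stats::rnorm(n_tr * m, sd = 0.5), n_tr, m)
    }
    structure(list(motion = motion, wm_ts = compartment(n_wm),
                   vent_ts = compartment(n_vent)),
              class = "confound_set")
  })
}

# Shared background generator: every parcel follows a stationary AR(1)
# process x_t = phi * x_{t-1} + sqrt(1 - phi^2) * e_t with unit stationary
# variance, where the innovation e_t mixes a private white component with the
# parcel's projection of K shared white drivers:
#   e_it = sqrt(1 - c_i^2) * eps_it + c_i * (W_i . u_t),
# c_i = coupling_strength * coupling_scale_i. The AR coefficient
# phi_i = exp(-tr_s / tau_i) gives parcel i a lag-k autocorrelation of
# exp(-k * tr_s / tau_i), the exponential-decay form the timescale module fits.
simulate_background <- function(gt, n_tr, tr_s, seed, coupling_scale = NULL,
                                burn_in = 100L) {
  if (any(gt$tau_true <= 0)) stop_invalid("tau_true must be > 0 everywhere")
  if (tr_s <= 0) stop_invalid("tr_s must be > 0")
  n <- gt$n_parcels
  if (is.null(coupling_scale)) coupling_scale <- rep(1, n)
  c_i <- pmin(gt$coupling_strength * coupling_scale, 0.999)
  phi <- exp(-tr_s / gt$tau_true)
  total <- n_tr + burn_in
  withr::with_seed(seed, {
    eps <- matrix(stats::rnorm(total * n), total, n)
    u <- matrix(stats::rnorm(total * ncol(gt$driver_loadings)), total,
                ncol(gt$driver_loadings))
    shared <- u %*% t(gt$driver_loadings)       # unit variance per parcel
    innov <- sweep(eps, 2L, sqrt(1 - c_i^2), "*") + sweep(shared, 2L, c_i, "*")
    x <- matrix(0, total, n)
    x[1L, ] <- innov[1L, ]                       # stationary unit-variance start
    s <- sqrt(1 - phi^2)
    for (t in 2:total)
      x[t, ] <- phi * x[t - 1L, ] + s * innov[t, ]
    x[(burn_in + 1L):total, , drop = FALSE]
  })
}

#' Simulate resting-state parcellated BOLD time series
#'
#' Each parcel is a discrete Ornstein-Uhlenbeck (AR(1)) process with
#' coefficient `exp(-tr_s / tau_i)` and unit stationary variance; inter-parcel
#' coupling enters through shared latent drivers weighted by the ground
#' truth's driver loadings. See [generate_ground_truth()].
#'
#' @param gt A `ground_truth` object.
#' @param n_tr Number of timepoints (>= 200).
#' @param tr_s Sampling interval in seconds.
#' @param seed Integer seed.
#' @return `n_tr x n_parcels` numeric matrix with attribute `tr_s`.
#' @export
simulate_rest_timeseries <- function(gt, n_tr, tr_s = 0.72, seed) {
  stopifnot(inherits(gt, "ground_truth"))
  n_tr <- check_scalar_int(n_tr, "n_tr", min = 200)
  seed <- check_scalar_int(seed, "seed")
  ts <- simulate_background(gt, n_tr, tr_s, seed)
  colnames(ts) <- sprintf("p%03d", seq_len(ncol(ts)))
  attr(ts, "tr_s") <- tr_s
  ts
}

#' Simulate task-state parcellated BOLD time series
#'
#' Additive model: HRF-convolved evoked responses (per-condition amplitudes
#' from the ground truth) plus the same background process as rest, except
#' that each parcel's shared-driver coupling is multiplied by its
#' `task_coupling_scale` - strongly activating parcels lose background
#' coupling during task, planting a negative activation-to-FC-change relation.
#'
#' @param gt A `ground_truth` object.
#' @param design A [generate_block_design()] result; its condition count must
#'   match the ground truth.
#' @param seed Integer seed (the background stream matches
#'   [simulate_rest_timeseries()] for equal seed and run length).
#' @param noise_scale Multiplier on the background process; 0 gives the pure
#'   noiseless evoked signal.
#' @param hrf Hemodynamic kernel sampled at the design TR; defaults to
#'   [canonical_hrf()] at `design$tr_s` (the well-specified case where
#'   simulation and analysis share the HRF). Pass a different kernel for a
#'   mismatched-hemodynamics stress test.
#' @return `n_tr x n_parcels` matrix with attribute `tr_s`.
#' @export
simulate_task_timeseries <- function(gt, design, seed, noise_scale = 1,
                                     hrf = NULL) {
  stopifnot(inherits(gt, "ground_truth"), inherits(design, "task_design"))
  seed <- check_scalar_int(seed, "seed")
  check_no_overlap(design)
  if (ncol(gt$evoked_amp) != length(design$conditions))
    stop_invalid("design has %d conditions but ground truth has %d",
                 length(design$conditions), ncol(gt$evoked_amp))
  if (is.null(hrf)) hrf <- canonical_hrf(design$tr_s)
  regs <- build_condition_regressors(design, hrf)
  evoked <- regs %*% t(gt$evoked_amp)
  background <- simulate_background(gt, design$n_tr, design$tr_s, seed,
                                    coupling_scale = gt$task_coupling_scale)
  ts <- evoked + noise_scale * background
  colnames(ts) <- sprintf("p%03d", seq_len(ncol(ts)))
  attr(ts, "tr_s") <- design$tr_s
  ts
}

#' Mix confound signals into a simulated time series
#'
#' Adds a random linear image of the confound columns (motion + compartment
#' signals) to every parcel, so that the nuisance-regression stage has real
#' artifact to remove.
#'
#' @param ts Timepoints-by-parcels matrix.
#' @param confounds A `confound_set`.
#' @param weight Artifact amplitude relative to the unit-variance background.
#' @param seed Integer seed for the mixing weights.
#' @return Contaminated matrix, same shape and attributes as `ts`.
#' @export
inject_confounds <- function(ts, confounds, weight = 0.5, seed) {
  stopifnot(inherits(confounds, "confound_set"))
  seed <- check_scalar_int(seed, "seed")
  C <- scale(cbind(confounds$motion, confounds$wm_ts, confounds$vent_ts))
  if (nrow(C) != nrow(ts))
    stop_invalid("confound rows (%d) do not match time series rows (%d)",
                 nrow(C), nrow(ts))
  L <- withr::with_seed(seed,
    matrix(stats::rnorm(ncol(C) * ncol(ts)), ncol(C), ncol(ts)))
  out <- ts + weight * (C %*% L) / sqrt(ncol(C))
  attributes(out) <- attributes(ts)
  out
}
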