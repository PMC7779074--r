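#' Canonical double-gamma hemodynamic response function
#'
#' The SPM-style canonical HRF: a gamma-density response peaking near 5-6 s
#' minus a later, smaller gamma-density undershoot (peak delay 6 s, undershoot
#' delay 16 s, unit dispersions, peak:undershoot ratio 6), sampled on the TR
#' grid and scaled to peak amplitude 1.
#'
#' @param tr_s Sampling interval in seconds.
#' @param duration_s Kernel support in seconds (default 32).
#' @return Numeric vector of length `ceiling(duration_s / tr_s)`.
#' @export
canonical_hrf <- function(tr_s, duration_s = 32) {
  if (tr_s <= 0) stop_invalid("tr_s must be > 0")
  n <- ceiling(duration_s / tr_s)
  t <- (seq_len(n) - 1) * tr_s
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build HRF-convolved condition regressors
#'
#' Per condition: a boxcar at TR resolution over the condition's blocks
#' (onsets floored, offsets ceiled to the TR grid), convolved with the
#' hemodynamic kernel and truncated to the run length. Columns follow the
#' design's sorted condition order.
#'
#' @param design A `task_design`.
#' @param hrf Hemodynamic kernel sampled at the design TR; defaults to
#'   [canonical_hrf()].
#' @param conditions Optional condition subset/ordering; labels absent from
#'   the design error.
#' @return `n_tr x n_conditions` matrix, one named column per condition.
#' @export
build_condition_regressors <- function(design, hrf = NULL, conditions = NULL) {
  stopifnot(inherits(design, "task_design"))
  if (is.null(hrf)) hrf <- canonical_hrf(design$tr_s)
  if (is.null(conditions)) conditions <- design$conditions
  unknown <- setdiff(conditions, unique(design$events$trial_type))
  if (length(unknown))
    stop_invalid("unknown condition label(s): %s", paste(unknown, collapse = ", "))
  blocks <- design_block_tr(design)
  T_len <- design$n_tr
  out <- matrix(0, T_len, length(conditions),
                dimnames = list(NULL, conditions))
  for (ci in seq_along(conditions)) {
    box <- numeric(T_len)
    b <- blocks[blocks$trial_type == conditions[ci], , drop = FALSE]
    for (k in seq_len(nrow(b)))
      box[b$start[k]:(b$end[k] - 1L)] <- 1
    conv <- stats::convolve(box, rev(hrf), type = "open")
    out[, ci] <- conv[seq_len(T_len)]
  }
  out
}

#' Fit the task activation GLM
#'
#' Ordinary least squares of every parcel's time series on an intercept, any
#' nuisance columns, and the HRF-convolved condition regressors. Returns the
#' condition coefficients only.
#'
#' @param ts Timepoints-by-parcels matrix.
#' @param condition_regs Output of [build_condition_regressors()].
#' @param nuisance Optional extra regressor matrix (or `nuisance_design`).
#' @param subject_id Optional identifier carried through to group analysis.
#' @return Object of class `activation_result`: list with `betas`
#'   (`n_parcels x n_conditions`), `conditions`, `subject_id`.
#' @export
fit_activation_glm <- function(ts, condition_regs, nuisance = NULL,
                               subject_id = NA_character_) {
  ts <- check_matrix(ts, "ts")
  condition_regs <- check_matrix(condition_regs, "condition_regs")
  if (nrow(condition_regs) != nrow(ts))
    stop_invalid("condition regressors have %d rows but time series has %d",
                 nrow(condition_regs), nrow(ts))
  nuis <- if (inherits(nuisance, "nuisance_design")) nuisance$columns else nuisance
  X <- cbind(`(intercept)` = 1, nuis, condition_regs)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_invalid("task design is rank deficient; aliased column(s): %s",
                 paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qx, ts)
  cond_idx <- (ncol(X) - ncol(condition_regs) + 1L):ncol(X)
  betas <- t(coefs[cond_idx, , drop = FALSE])
  colnames(betas) <- colnames(condition_regs)
  rownames(betas) <- colnames(ts)
  structure(list(betas = betas, conditions = colnames(condition_regs),
                 subject_id = subject_id),
            class = "activation_result")
}

#' @export
print.activation_result <- function(x, ...) {
  cat(sprintf("<activation_result> %d parcels x %d conditions (subject %s)\n",
              nrow(x$betas), ncol(x$betas), x$subject_id))
  invisible(x)
}

#' Group task activation magnitude map
#'
#' For each parcel and condition, the one-sample t statistic of the subject
#' coefficients against zero; its absolute value is then averaged across
#' conditions, yielding a non-negative per-parcel activation magnitude map.
#' The degenerate 0/0 case (all-zero coefficients) is defined as t = 0; a
#' zero-variance parcel with nonzero mean yields an infinite t and the parcel
#' is flagged.
#'
#' @param results List of `activation_result` objects (>= 3 subjects) with
#'   identical parcel/condition layout.
#' @return Numeric per-parcel map with attribute `flagged` (indices of
#'   parcels with undefined statistics).
#' @export
group_activation_magnitude <- function(results) {
  if (length(results) < 3L)
    stop_invalid("need at least 3 subjects, got %d", length(results))
  nr <- nrow(results[[1L]]$betas); nc <- ncol(results[[1L]]$betas)
  betas <- array(vapply(results, function(r) as.numeric(r$betas),
                        numeric(nr * nc)),
                 dim = c(nr, nc, length(results)))
  n_subj <- dim(betas)[3L]
  m <- apply(betas, c(1L, 2L), mean)
  s <- apply(betas, c(1L, 2L), stats::sd)
  t_stat <- m / (s / sqrt(n_subj))
  t_stat[m == 0 & s == 0] <- 0
  mag <- rowMeans(abs(t_stat))
  flagged <- which(!is.finite(mag))
  attr(mag, "flagged") <- flagged
  mag
}

#' Remove the mean evoked response with an FIR model
#'
#' Per condition, one indicator regressor for each peri-onset TR from block
#' onset through block offset plus `post_offset_lags` TRs, pooled across that
#' condition's blocks; the time series is replaced by the OLS residuals on the
#' full FIR design plus an intercept. Unlike canonical-HRF regression this
#' removes the mean evoked response exactly, whatever its shape, so the
#' residual block-triggered average vanishes - which is why FIR (not the
#' canonical GLM) precedes task-state FC estimation.
#'
#' @param ts Timepoints-by-parcels matrix (aligned with `design`).
#' @param design A `task_design`.
#' @param post_offset_lags FIR extent beyond block offset, in TRs (default 25).
#' @return Residual matrix, same shape; `tr_s` attribute kept.
#' @export
fir_regress <- function(ts, design, post_offset_lags = 25) {
  ts <- check_matrix(ts, "ts")
  stopifnot(inherits(design, "task_design"))
  post_offset_lags <- check_scalar_int(post_offset_lags, "post_offset_lags",
                                       min = 0)
  if (design$n_tr != nrow(ts))
    stop_invalid("design run length (%d) does not match time series rows (%d)",
                 design$n_tr, nrow(ts))
  F <- fir_design(design, post_offset_lags)
  qx <- qr(cbind(1, F))
  if (qx$rank < ncol(F) + 1L) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    warning(sprintf("FIR design rank deficient; dropping %d aliased column(s)",
                    ncol(F) + 1L - qx$rank))
    F <- cbind(1, F)[, keep, drop = FALSE]
    out <- ols_residuals(ts, F)
  } else {
    out <- ts - qr.fitted(qx, ts)
  }
  colnames(out) <- colnames(ts)
  attr(out, "tr_s") <- attr(ts, "tr_s")
  out
}

# Pooled peri-onset indicator columns, one set per condition. Lag l (0-based)
# of condition c marks TR onset + l of every block of c whose window
# (block length + post-offset lags) covers l.
fir_design <- function(design, post_offset_lags) {
  blocks <- design_block_tr(design)
  T_len <- design$n_tr
  cols <- list()
  for (cond in design$conditions) {
    b <- blocks[blocks$trial_type == cond, , drop = FALSE]
    if (!nrow(b)) next
    lens <- b$end - b$start
    n_lag <- max(lens) + post_offset_lags
    m <- matrix(0, T_len, n_lag)
    for (k in seq_len(nrow(b))) {
      lag_max <- min(lens[k] + post_offset_lags, n_lag)
      rows <- b$start[k] + seq_len(lag_max) - 1L
      ok <- rows <= T_len
      m[cbind(rows[ok], seq_len(lag_max)[ok])] <- 1
    }
    colnames(m) <- sprintf("%s_lag%03d", cond, seq_len(n_lag) - 1L)
    cols[[cond]] <- m
  }
  F <- do.call(cbind, cols)
  F[, colSums(F) > 0, drop = FALSE]
}
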