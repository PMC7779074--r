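#' Trim initial frames, demean and detrend
#'
#' Removes the first `n_drop` frames of a run, then removes each parcel's mean
#' and least-squares linear trend. This is the first preprocessing step
#' applied to every parcellated run before nuisance regression.
#'
#' @param ts Timepoints-by-parcels matrix.
#' @param n_drop Number of initial frames to discard (default 5).
#' @return Matrix with `nrow(ts) - n_drop` rows; every column has zero mean
#'   and zero linear trend. The `tr_s` attribute, if present, is kept.
#' @export
trim_demean_detrend <- function(ts, n_drop = 5) {
  ts <- check_matrix(ts, "ts")
  n_drop <- check_scalar_int(n_drop, "n_drop", min = 0)
  if (nrow(ts) <= n_drop + 2L)
    stop_invalid("time series too short: %d rows with n_drop = %d",
                 nrow(ts), n_drop)
  tr <- attr(ts, "tr_s")
  out <- ts[(n_drop + 1L):nrow(ts), , drop = FALSE]
  t_idx <- seq_len(nrow(out))
  out <- ols_residuals(out, cbind(trend = t_idx))
  colnames(out) <- colnames(ts)
  attr(out, "tr_s") <- tr
  out
}

#' Expand motion parameters into the 24-regressor set
#'
#' From the six rigid-body motion parameters, builds the standard expansion:
#' the 6 parameters, their temporal derivatives (backward differences, first
#' row zero), and the elementwise squares of those 12 columns - 24 motion
#' regressors in total.
#'
#' @param motion Timepoints-by-6 matrix of motion parameters.
#' @return Timepoints-by-24 matrix with descriptive column labels.
#' @export
build_motion_regressors <- function(motion) {
  motion <- check_matrix(motion, "motion")
  if (ncol(motion) != 6L)
    stop_invalid("motion must have exactly 6 columns, got %d", ncol(motion))
  expand_with_derivatives_quadratics(motion, prefix = "mot")
}

# Shared expansion: [X, backward-diff(X), X^2, diff(X)^2]. The derivative's
# first row is defined as 0 (no pre-run sample exists).
expand_with_derivatives_quadratics <- function(x, prefix) {
  d <- rbind(0, diff(x))
  base <- cbind(x, d)
  out <- cbind(base, base^2)
  p <- ncol(x)
  colnames(out) <- c(sprintf("%s%02d", prefix, 1:p),
                     sprintf("%s%02d_d", prefix, 1:p),
                     sprintf("%s%02d_sq", prefix, 1:p),
                     sprintf("%s%02d_d_sq", prefix, 1:p))
  out
}

#' aCompCor: principal components of a compartment signal matrix
#'
#' Extracts the top principal-component time series of the column-demeaned
#' compartment matrix (white matter or ventricle signals), ordered by
#' explained variance. Components are unit-norm with the sign convention that
#' the first nonzero loading is positive.
#'
#' @param compartment_ts Timepoints-by-signals matrix.
#' @param n_components Number of components to keep (default 5).
#' @return Timepoints-by-`n_components` matrix of component time series.
#' @export
acompcor <- function(compartment_ts, n_components = 5) {
  x <- check_matrix(compartment_ts, "compartment_ts")
  n_components <- check_scalar_int(n_components, "n_components", min = 1)
  if (ncol(x) < n_components)
    stop_invalid("need at least %d compartment signals, got %d",
                 n_components, ncol(x))
  xc <- demean_cols(x)
  sv <- svd(xc, nu = n_components, nv = n_components)
  comp <- sv$u
  for (j in seq_len(n_components)) {
    load <- sv$v[, j]
    first <- load[which(abs(load) > 1e-12)[1L]]
    if (!is.na(first) && first < 0) comp[, j] <- -comp[, j]
  }
  colnames(comp) <- sprintf("pc%d", seq_len(n_components))
  comp
}

#' Assemble the full nuisance design
#'
#' Combines the 24 expanded motion regressors with the physiological block:
#' the white-matter and ventricle aCompCor components, their derivatives, and
#' the squares of all of those (with 5 + 5 components this is 40
#' physiological regressors, 64 regressors in total). The mean across parcels
#' is deliberately never included - no global-signal regression.
#'
#' @param motion24 Output of [build_motion_regressors()].
#' @param wm_components,vent_components aCompCor component matrices.
#' @return Object of class `nuisance_design`: list with `columns` (the
#'   regressor matrix) and `labels`.
#' @export
assemble_nuisance <- function(motion24, wm_components, vent_components) {
  motion24 <- check_matrix(motion24, "motion24")
  wm_components <- check_matrix(wm_components, "wm_components")
  vent_components <- check_matrix(vent_components, "vent_components")
  if (ncol(motion24) != 24L)
    stop_invalid("motion24 must have 24 columns, got %d", ncol(motion24))
  rows <- c(nrow(motion24), nrow(wm_components), nrow(vent_components))
  if (length(unique(rows)) != 1L)
    stop_invalid("row counts differ across nuisance blocks: %s",
                 paste(rows, collapse = ", "))
  phys <- cbind(wm_components, vent_components)
  colnames(phys) <- c(sprintf("wm_pc%d", seq_len(ncol(wm_components))),
                      sprintf("vent_pc%d", seq_len(ncol(vent_components))))
  phys40 <- expand_with_derivatives_quadratics(phys, prefix = "phys")
  colnames(phys40) <- c(colnames(phys),
                        paste0(colnames(phys), "_d"),
                        paste0(colnames(phys), "_sq"),
                        paste0(colnames(phys), "_d_sq"))
  columns <- cbind(motion24, phys40)
  structure(list(columns = columns, labels = colnames(columns)),
            class = "nuisance_design")
}

#' @export
print.nuisance_design <- function(x, ...) {
  cat(sprintf("<nuisance_design> %d regressors x %d timepoints\n",
              ncol(x$columns), nrow(x$columns)))
  invisible(x)
}

#' Nuisance regression
#'
#' Regresses every parcel's time series on the nuisance design (plus an
#' intercept) by ordinary least squares and returns the residuals, which are
#' orthogonal to every design column.
#'
#' @param ts Timepoints-by-parcels matrix.
#' @param design A `nuisance_design` (or a bare regressor matrix).
#' @return Residual matrix, same shape as `ts`; `tr_s` attribute kept.
#' @export
nuisance_regress <- function(ts, design) {
  ts <- check_matrix(ts, "ts")
  X <- if (inherits(design, "nuisance_design")) design$columns else design
  X <- check_matrix(X, "design")
  if (nrow(X) != nrow(ts))
    stop_invalid("design has %d rows but time series has %d", nrow(X), nrow(ts))
  out <- ols_residuals(ts, X)
  colnames(out) <- colnames(ts)
  attr(out, "tr_s") <- attr(ts, "tr_s")
  out
}
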