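#' Baseline a run to its inter-block rest level
#'
#' Subtracts, per parcel, the mean over all TRs lying outside every task
#' block. This sets the resting activity level to zero so that in-block peak
#' values measure evoked deviation from baseline. Idempotent.
#'
#' @param ts Timepoints-by-parcels matrix aligned with `design`.
#' @param design A `task_design`.
#' @param washout_tr TRs after each block offset excluded from the baseline
#'   (hemodynamic washout; default 0).
#' @return Baselined matrix, same shape; `tr_s` attribute kept.
#' @export
baseline_to_interblock_rest <- function(ts, design, washout_tr = 0) {
  ts <- check_matrix(ts, "ts")
  stopifnot(inherits(design, "task_design"))
  washout_tr <- check_scalar_int(washout_tr, "washout_tr", min = 0)
  if (design$n_tr != nrow(ts))
    stop_invalid("design run length (%d) does not match time series rows (%d)",
                 design$n_tr, nrow(ts))
  blocks <- design_block_tr(design)
  in_block <- rep(FALSE, nrow(ts))
  for (k in seq_len(nrow(blocks))) {
    end <- min(blocks$end[k] - 1L + washout_tr, nrow(ts))
    in_block[blocks$start[k]:end] <- TRUE
  }
  if (!any(!in_block))
    stop_invalid("design leaves no inter-block rest TRs to baseline against")
  base <- colMeans(ts[!in_block, , drop = FALSE])
  out <- sweep(ts, 2L, base, "-")
  attr(out, "tr_s") <- attr(ts, "tr_s")
  out
}

#' Extract signed block peaks
#'
#' Per block and parcel, the element of maximal absolute value among the
#' block's TRs. By default the value keeps its sign (so deactivations stay
#' negative); `magnitude_only = TRUE` returns `|peak|`. Ties are broken by
#' the earliest TR.
#'
#' @param baselined_ts Output of [baseline_to_interblock_rest()] (or any
#'   matrix aligned with the design).
#' @param design A `task_design`.
#' @param magnitude_only Drop the sign?
#' @return Object of class `block_peaks`: list with `peaks`
#'   (`n_blocks x n_parcels`) and `block_condition` labels.
#' @export
extract_block_peaks <- function(baselined_ts, design, magnitude_only = FALSE) {
  ts <- check_matrix(baselined_ts, "baselined_ts")
  stopifnot(inherits(design, "task_design"))
  blocks <- design_block_tr(design)
  if (any(blocks$end - blocks$start < 1L))
    stop_invalid("design contains an empty block on the TR grid")
  if (max(blocks$end) - 1L > nrow(ts))
    stop_invalid("design blocks extend past the time series")
  peaks <- matrix(NA_real_, nrow(blocks), ncol(ts))
  for (k in seq_len(nrow(blocks))) {
    seg <- ts[blocks$start[k]:(blocks$end[k] - 1L), , drop = FALSE]
    idx <- max.col(t(abs(seg)), ties.method = "first")
    peaks[k, ] <- seg[cbind(idx, seq_len(ncol(seg)))]
  }
  if (magnitude_only) peaks <- abs(peaks)
  colnames(peaks) <- colnames(ts)
  structure(list(peaks = peaks, block_condition = blocks$trial_type),
            class = "block_peaks")
}

#' Peak-based task activation map
#'
#' Per parcel, the mean of its block peaks across all blocks.
#'
#' @param peaks A `block_peaks` object.
#' @return Per-parcel numeric map.
#' @export
peak_activation_map <- function(peaks) {
  stopifnot(inherits(peaks, "block_peaks"))
  if (!nrow(peaks$peaks)) stop_invalid("no blocks in peak set")
  colMeans(peaks$peaks)
}

#' Block-to-block peak functional connectivity
#'
#' Pearson correlation between parcels' block-peak vectors: FC from
#' block-to-block covariance of evoked peaks rather than timepoint-to-
#' timepoint covariance, requiring no task regression at all.
#'
#' @param peaks A `block_peaks` object with at least 3 blocks.
#' @return Symmetric FC matrix (unit diagonal; zero-variance parcels
#'   flagged and set to 0 as in [correlation_fc()]).
#' @export
peak_fc <- function(peaks) {
  stopifnot(inherits(peaks, "block_peaks"))
  if (nrow(peaks$peaks) < 3L)
    stop_invalid("need at least 3 blocks for peak FC, got %d", nrow(peaks$peaks))
  correlation_fc(peaks$peaks)
}

#' Pseudo-block peak FC from resting-state data
#'
#' Applies the identical block machinery to a rest run: the task design marks
#' temporally equivalent pseudo-blocks, the run is baselined to the
#' pseudo-inter-block rest level, signed peaks are extracted per pseudo-block,
#' and their block-to-block correlation is returned. Subtracting the weighted
#' degree of this matrix from the task peak FC (via [fc_change_map()]) gives
#' the peak-approach FC change.
#'
#' @param rest_ts Resting-state matrix covering the design's run length.
#' @param design The task `task_design`.
#' @param magnitude_only Passed to [extract_block_peaks()].
#' @return Symmetric FC matrix over pseudo-block peaks.
#' @export
pseudo_block_rest_peak_fc <- function(rest_ts, design, magnitude_only = FALSE) {
  rest_ts <- check_matrix(rest_ts, "rest_ts")
  if (nrow(rest_ts) < design$n_tr)
    stop_invalid("rest run (%d TRs) does not cover the design (%d TRs)",
                 nrow(rest_ts), design$n_tr)
  rest <- rest_ts[seq_len(design$n_tr), , drop = FALSE]
  attr(rest, "tr_s") <- attr(rest_ts, "tr_s")
  baselined <- baseline_to_interblock_rest(rest, design)
  peak_fc(extract_block_peaks(baselined, design, magnitude_only))
}
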