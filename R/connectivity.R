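#' Task-block intervals on the TR grid
#'
#' The union of all task-block TR intervals of a design, as 1-based half-open
#' `[start, end)` index pairs. Applying the same interval set to task and rest
#' data guarantees both FC estimates use identical temporal samples.
#'
#' @param design A `task_design`.
#' @param T_len Run length in TRs the intervals must fit into.
#' @return Object of class `interval_set`: data frame with `start`, `end`.
#' @export
intervals_from_design <- function(design, T_len = design$n_tr) {
  stopifnot(inherits(design, "task_design"))
  if (!nrow(design$events)) stop_invalid("design has no blocks")
  b <- check_no_overlap(design)
  if (any(b$end - 1L > T_len))
    stop_invalid("design blocks extend past %d TRs", T_len)
  structure(data.frame(start = b$start, end = b$end), class = c("interval_set",
                                                                "data.frame"))
}

interval_rows <- function(intervals, T_len) {
  idx <- unlist(lapply(seq_len(nrow(intervals)), function(k)
    intervals$start[k]:(intervals$end[k] - 1L)))
  if (any(idx < 1L | idx > T_len))
    stop_invalid("intervals fall outside the run")
  idx
}

#' Correlation functional connectivity
#'
#' Pearson correlation between all parcel pairs over the concatenation of the
#' supplied interval samples (the whole run when `intervals` is `NULL`).
#' Zero-variance parcels get correlation 0 to every other parcel and are
#' recorded in the `flagged` attribute; the diagonal is always 1.
#'
#' @param ts Timepoints-by-parcels matrix.
#' @param intervals Optional `interval_set`.
#' @return Symmetric `n_parcels x n_parcels` correlation matrix, unit
#'   diagonal, entries in `[-1, 1]`.
#' @export
correlation_fc <- function(ts, intervals = NULL) {
  ts <- check_matrix(ts, "ts")
  if (!is.null(intervals))
    ts <- ts[interval_rows(intervals, nrow(ts)), , drop = FALSE]
  if (nrow(ts) < 3L)
    stop_invalid("need at least 3 timepoints for correlation FC, got %d", nrow(ts))
  sds <- apply(ts, 2L, stats::sd)
  flagged <- which(sds == 0)
  fc <- suppressWarnings(stats::cor(ts))
  if (length(flagged)) {
    fc[flagged, ] <- 0
    fc[, flagged] <- 0
  }
  diag(fc) <- 1
  fc <- (fc + t(fc)) / 2
  attr(fc, "flagged") <- flagged
  fc
}

#' Interval-matched resting-state functional connectivity
#'
#' Applies the identical task-FC computation to resting-state data: the task
#' FIR design is regressed out of the rest run (so both states receive the
#' same regression), then FC is computed over the same task-block intervals.
#' The rest run must be at least as long as the task design requires.
#'
#' @param rest_ts Timepoints-by-parcels resting-state matrix.
#' @param design The task `task_design`.
#' @param post_offset_lags FIR extent in TRs, as in [fir_regress()].
#' @return Correlation FC matrix as in [correlation_fc()].
#' @export
matched_rest_fc <- function(rest_ts, design, post_offset_lags = 25) {
  rest_ts <- check_matrix(rest_ts, "rest_ts")
  if (nrow(rest_ts) < design$n_tr)
    stop_invalid("rest run (%d TRs) shorter than the task design requires (%d)",
                 nrow(rest_ts), design$n_tr)
  rest <- rest_ts[seq_len(design$n_tr), , drop = FALSE]
  attr(rest, "tr_s") <- attr(rest_ts, "tr_s")
  resid <- fir_regress(rest, design, post_offset_lags)
  correlation_fc(resid, intervals_from_design(design))
}

#' Weighted degree centrality (global brain connectivity)
#'
#' Per parcel, the mean of its off-diagonal FC values. With
#' `positive_only = TRUE`, negative entries are zeroed before averaging
#' (the positive-FC-thresholded variant).
#'
#' @param fc Symmetric FC matrix.
#' @param positive_only Zero out negative FC before averaging?
#' @return Per-parcel numeric map.
#' @export
weighted_degree <- function(fc, positive_only = FALSE) {
  fc <- check_matrix(fc, "fc")
  if (nrow(fc) != ncol(fc) || any(abs(fc - t(fc)) > 1e-8))
    stop_invalid("fc must be a symmetric square matrix")
  m <- fc
  if (positive_only) m[m < 0] <- 0
  diag(m) <- NA
  rowMeans(m, na.rm = TRUE)
}

#' Task-to-rest change in weighted degree centrality
#'
#' `weighted_degree(task_fc) - weighted_degree(rest_fc)`, per parcel. The sign
#' convention is task minus rest throughout the package, so a region whose
#' connectivity drops during task gets a negative value.
#'
#' @param task_fc,rest_fc FC matrices of identical dimension.
#' @param positive_only Passed to [weighted_degree()] for both matrices.
#' @return Per-parcel numeric map of FC change.
#' @export
fc_change_map <- function(task_fc, rest_fc, positive_only = FALSE) {
  if (!identical(dim(task_fc), dim(rest_fc)))
    stop_invalid("task and rest FC matrices have different dimensions")
  weighted_degree(task_fc, positive_only) - weighted_degree(rest_fc, positive_only)
}
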