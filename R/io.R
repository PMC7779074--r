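# Plain-text interfaces: TSV for matrices, maps and events; JSON for configs.

#' Write / read a parcellated time series as TSV
#'
#' Rows are timepoints, columns parcels; the header row carries parcel IDs.
#'
#' @param ts Timepoints-by-parcels matrix.
#' @param path File path.
#' @export
write_parcel_ts <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcel_ts
#' @param tr_s Sampling interval to attach to the matrix read back.
#' @export
read_parcel_ts <- function(path, tr_s = NULL) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  if (!is.null(tr_s)) attr(m, "tr_s") <- tr_s
  m
}

#' Write / read a task design as a BIDS-style events TSV
#'
#' Columns `onset`, `duration`, `trial_type` (seconds); the sampling interval
#' and run length live in a JSON sidecar next to the events file.
#'
#' @param design A `task_design`.
#' @param path Events TSV path; the sidecar takes the same path with a
#'   `.json` extension.
#' @export
write_task_design <- function(design, path) {
  stopifnot(inherits(design, "task_design"))
  utils::write.table(design$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(tr_s = design$tr_s, n_tr = design$n_tr),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_task_design
#' @export
read_task_design <- function(path) {
  events <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path))
  structure(list(events = events, tr_s = side$tr_s, n_tr = side$n_tr,
                 conditions = sort(unique(events$trial_type))),
            class = "task_design")
}

#' Write / read a per-parcel brain map as two-column TSV
#'
#' @param map Per-parcel numeric vector.
#' @param path File path.
#' @export
write_brain_map <- function(map, path) {
  df <- data.frame(parcel_id = seq_along(map), value = as.numeric(map))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_brain_map
#' @export
read_brain_map <- function(path) {
  utils::read.delim(path)$value
}

#' Write a square matrix (FC, distances) as TSV
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, header = FALSE))
}
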