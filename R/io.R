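#' Read and write spike-density rasters as delimited text
#'
#' The on-disk layout is cells x bins with a header row of bin start times
#' (seconds) and a leading `cell_id` column; an optional second column
#' `cell_type` carries per-cell tags. The bin width is recovered from the
#' header times.
#'
#' @param path File path.
#' @param sep Field separator (`","` for CSV, `"\t"` for TSV).
#' @return `read_raster_csv()` returns a [spike_raster()];
#'   `write_raster_csv()` returns `path` invisibly.
#' @export
read_raster_csv <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "cell_id")
    rlang::abort("expected first column `cell_id`.")
  has_type <- names(df)[2] == "cell_type"
  meta_cols <- if (has_type) 2L else 1L
  times <- as.numeric(names(df)[-seq_len(meta_cols)])
  if (anyNA(times) || length(times) < 1L)
    rlang::abort("header must contain numeric bin times.")
  dt <- if (length(times) > 1L) stats::median(diff(times)) else 1
  vals <- as.matrix(df[, -seq_len(meta_cols), drop = FALSE])
  spike_raster(vals, dt = dt, cell_ids = df$cell_id,
               cell_type = if (has_type) df$cell_type)
}

#' @rdname read_raster_csv
#' @param raster A [spike_raster()].
#' @export
write_raster_csv <- function(raster, path, sep = ",") {
  stopifnot(inherits(raster, "spike_raster"))
  times <- (seq_len(n_bins(raster)) - 1L) * raster$dt
  df <- data.frame(cell_id = raster$cell_ids,
                   stringsAsFactors = FALSE)
  if (!is.null(raster$cell_type)) df$cell_type <- raster$cell_type
  m <- as.data.frame(raster$values)
  names(m) <- format(times, trim = TRUE, scientific = FALSE)
  utils::write.table(cbind(df, m), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a trial table (condition, start_bin, end_bin)
#'
#' Intervals are 0-based and half-open: a trial occupies bins
#' `start_bin, ..., end_bin - 1`.
#'
#' @param path CSV file path.
#' @return A tibble with columns `condition`, `start_bin`, `end_bin`.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("condition", "start_bin", "end_bin")
  if (!all(req %in% names(df)))
    rlang::abort("trial table needs columns condition, start_bin, end_bin.")
  tibble::as_tibble(df[req])
}

#' Write an avalanche table to CSV
#'
#' Columns: `k`, `offset`, `start_bin`, `duration_bins`, `size`,
#' `duration_seconds`.
#'
#' @param avalanches Avalanche tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_avalanches_csv <- function(avalanches, path) {
  utils::write.csv(
    avalanches[c("k", "offset", "start_bin", "duration_bins", "size",
                 "duration_seconds")],
    path, row.names = FALSE)
  invisible(path)
}
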