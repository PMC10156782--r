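#' Spike-density raster
#'
#' Container for a neurons-by-time-bins matrix of nonnegative spike densities,
#' as produced by spike deconvolution of calcium-imaging movies or by the
#' bundled network simulator. Values need not be integers: a bin may carry a
#' fractional spike-probability mass.
#'
#' @param values Numeric matrix, cells in rows, time bins in columns. All
#'   values must be nonnegative and finite.
#' @param dt Bin width in seconds (single positive number).
#' @param cell_ids Optional character vector of cell labels (default
#'   `"cell_1"`, ...).
#' @param cell_type Optional character vector of per-cell type tags (e.g.
#'   `"E"`/`"I"` for simulator output).
#'
#' @return An object of class `spike_raster`: a list with elements `values`,
#'   `dt`, `cell_ids`, `cell_type`.
#' @examples
#' r <- spike_raster(matrix(rpois(40, 1), nrow = 4), dt = 0.022)
#' r
#' population_activity(r)
#' @export
spike_raster <- function(values, dt, cell_ids = NULL, cell_type = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1L || ncol(values) < 1L)
    rlang::abort("`values` must be a non-empty numeric matrix (cells x bins).")
  if (anyNA(values) || any(values < 0))
    rlang::abort("raster values must be nonnegative and non-missing.")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    rlang::abort("`dt` must be a single positive number (seconds per bin).")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(values))
    rlang::abort("`cell_ids` must have one entry per row of `values`.")
  if (!is.null(cell_type) && length(cell_type) != nrow(values))
    rlang::abort("`cell_type` must have one entry per row of `values`.")
  structure(
    list(values = unname(values), dt = dt, cell_ids = cell_ids,
         cell_type = cell_type),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d cells x %d bins, dt = %g s (%.1f s total)\n",
              nrow(x$values), ncol(x$values), x$dt, ncol(x$values) * x$dt))
  cat(sprintf("  total spike mass: %.4g; active cells: %d\n",
              sum(x$values), sum(rowSums(x$values) > 0)))
  invisible(x)
}

#' @export
dim.spike_raster <- function(x) dim(x$values)

#' @rdname spike_raster
#' @param x A `spike_raster`.
#' @param ... Unused.
#' @export
as_tibble.spike_raster <- function(x, ...) {
  tibble::tibble(
    cell_id = rep(x$cell_ids, times = ncol(x$values)),
    bin = rep(seq_len(ncol(x$values)) - 1L, each = nrow(x$values)),
    time = rep((seq_len(ncol(x$values)) - 1L) * x$dt, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

n_bins <- function(raster) ncol(raster$values)
n_cells <- function(raster) nrow(raster$values)

#' Population activity of a raster
#'
#' Sums the spike densities of all cells in each time bin, giving the
#' population activity trace that thresholding and avalanche extraction
#' operate on.
#'
#' @param raster A [spike_raster()].
#' @return A tibble with columns `bin` (0-based), `time` (seconds) and
#'   `activity`, carrying the bin width as attribute `dt`.
#' @export
population_activity <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  p <- colSums(raster$values)
  out <- tibble::tibble(
    bin = seq_along(p) - 1L,
    time = (seq_along(p) - 1L) * raster$dt,
    activity = unname(p)
  )
  attr(out, "dt") <- raster$dt
  out
}

# Accept a population-activity tibble, a spike_raster, or a bare numeric
# vector and return list(p = numeric, dt = seconds).
as_activity <- function(x, dt = NULL) {
  if (inherits(x, "spike_raster")) {
    return(list(p = colSums(x$values), dt = x$dt))
  }
  if (is.data.frame(x)) {
    if (!"activity" %in% names(x))
      rlang::abort("expected a column `activity` (see population_activity()).")
    d <- attr(x, "dt")
    if (is.null(d)) d <- if (is.null(dt)) 1 else dt
    return(list(p = x$activity, dt = d))
  }
  if (is.numeric(x)) {
    return(list(p = as.numeric(x), dt = if (is.null(dt)) 1 else dt))
  }
  rlang::abort("cannot interpret input as population activity.")
}

#' Population-coupling z-scores against a circular-shift null
#'
#' For each cell the population correlation `c_i` is the Pearson correlation
#' between the cell's activity and the summed activity of all other cells.
#' A null distribution is built by circularly shifting the cell's own trace
#' by every lag `tau` in `[-max_shift, max_shift]` and recomputing the
#' correlation; `z_i` standardises `c_i` against that null. Cells with
#' `z_i` below `z_threshold` are flagged for removal, the criterion used to
#' discard neurons that do not take part in population synchronisation.
#'
#' The zero lag reproduces `c_i` itself and would bias the null upward, so it
#' is excluded by default (`include_zero_shift = FALSE`). The null spread can
#' divide by the null standard deviation (`scale = "sd"`, ordinary z-score,
#' the default) or by the null variance (`scale = "var"`).
#'
#' @param raster A [spike_raster()] with more than `2 * max_shift` bins.
#' @param max_shift Largest circular lag of the null, in bins.
#' @param z_threshold Removal criterion on `z`.
#' @param include_zero_shift Keep `tau = 0` in the null distribution?
#' @param scale `"sd"` or `"var"`: denominator of the standardisation.
#' @return A tibble with one row per cell: `cell_id`, `c` (population
#'   correlation), `null_mean`, `null_sd`, `z`, `removed`. Constant
#'   (zero-variance) cells get `z = NA` and `removed = TRUE`, with a warning.
#' @seealso [remove_uncorrelated()]
#' @export
population_correlation_z <- function(raster, max_shift = 100L,
                                     z_threshold = 0.01,
                                     include_zero_shift = FALSE,
                                     scale = c("sd", "var")) {
  stopifnot(inherits(raster, "spike_raster"))
  scale <- rlang::arg_match(scale)
  nb <- n_bins(raster)
  if (nb <= 2L * max_shift)
    rlang::abort("raster must have more than 2 * max_shift bins.")
  taus <- seq.int(-max_shift, max_shift)
  if (!include_zero_shift) taus <- taus[taus != 0L]
  tot <- colSums(raster$values)

  res <- purrr::map(seq_len(n_cells(raster)), function(i) {
    ri <- raster$values[i, ]
    rest <- tot - ri
    if (stats::sd(ri) == 0 || stats::sd(rest) == 0) {
      return(list(c = NA_real_, null_mean = NA_real_, null_sd = NA_real_,
                  z = NA_real_, removed = TRUE, constant = TRUE))
    }
    ci <- stats::cor(ri, rest)
    null <- vapply(taus, function(tau) {
      stats::cor(rotate_vec(ri, tau), rest)
    }, numeric(1))
    m <- mean(null); s <- stats::sd(null)
    denom <- if (scale == "sd") s else s^2
    z <- (ci - m) / denom
    list(c = ci, null_mean = m, null_sd = s, z = z,
         removed = is.na(z) || z < z_threshold, constant = FALSE)
  })

  if (any(purrr::map_lgl(res, "constant")))
    rlang::warn("constant (zero-variance) cells found; flagged as removed.")

  out <- tibble::tibble(
    cell_id = raster$cell_ids,
    c = purrr::map_dbl(res, "c"),
    null_mean = purrr::map_dbl(res, "null_mean"),
    null_sd = purrr::map_dbl(res, "null_sd"),
    z = purrr::map_dbl(res, "z"),
    removed = purrr::map_lgl(res, "removed")
  )
  attr(out, "z_threshold") <- z_threshold
  attr(out, "max_shift") <- as.integer(max_shift)
  out
}

# circular rotation: positive tau shifts the series forward in time,
# wrapping the tail to the front
rotate_vec <- function(x, tau) {
  n <- length(x)
  tau <- ((tau %% n) + n) %% n
  if (tau == 0) return(x)
  c(x[(n - tau + 1L):n], x[1L:(n - tau)])
}

#' Drop cells flagged as uncorrelated with the population
#'
#' @param raster A [spike_raster()].
#' @param report Output of [population_correlation_z()] computed from the
#'   same raster.
#' @return The raster restricted to retained cells, order preserved.
#' @export
remove_uncorrelated <- function(raster, report) {
  stopifnot(inherits(raster, "spike_raster"))
  if (nrow(report) != n_cells(raster))
    rlang::abort("report does not match raster (cell count differs).")
  keep <- !report$removed
  if (!any(keep))
    rlang::abort("all cells were flagged as uncorrelated; nothing remains.")
  spike_raster(raster$values[keep, , drop = FALSE], raster$dt,
               cell_ids = raster$cell_ids[keep],
               cell_type = if (!is.null(raster$cell_type))
                 raster$cell_type[keep])
}
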