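#' Circular-shift surrogate: destroy inter-neuronal correlations
#'
#' Rotates every cell's time series by an independent uniform random offset,
#' wrapping around the recording edge. Per-cell spike totals and all
#' rotation-invariant single-cell statistics (inter-spike-interval sequences
#' up to the wrap point) are preserved exactly, while zero-lag correlations
#' between cells are destroyed in expectation. Offsets are drawn from
#' `1 .. n_bins - 1` so a surrogate is never the identity.
#'
#' @param raster A [spike_raster()].
#' @param seed Optional integer seed.
#' @return A new `spike_raster`.
#' @export
surrogate_circular_shift <- function(raster, seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (!is.null(seed)) set.seed(seed)
  nb <- n_bins(raster)
  offs <- sample.int(nb - 1L, n_cells(raster), replace = TRUE)
  v <- raster$values
  for (i in seq_len(nrow(v))) v[i, ] <- rotate_vec(v[i, ], offs[i])
  spike_raster(v, raster$dt, raster$cell_ids, raster$cell_type)
}

#' Random spike addition surrogate
#'
#' Adds unit spikes at uniformly random (cell, bin) positions until the
#' requested noise level is reached: `pct = 100` doubles the total spike
#' count. Positions may repeat (a bin then accumulates more than one added
#' spike). The added count is `round(pct / 100 * sum(values))`.
#'
#' @param raster A [spike_raster()].
#' @param pct Percentage of the original total spike count to add (>= 0).
#' @param seed Optional integer seed.
#' @return A new `spike_raster`.
#' @export
surrogate_add_spikes <- function(raster, pct, seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (!is.numeric(pct) || length(pct) != 1L || is.na(pct) || pct < 0)
    rlang::abort("`pct` must be a single nonnegative number.")
  if (!is.null(seed)) set.seed(seed)
  n_add <- round(pct / 100 * sum(raster$values))
  if (n_add == 0) return(raster)
  v <- raster$values
  idx <- sample.int(length(v), n_add, replace = TRUE)
  tab <- tabulate(idx, nbins = length(v))
  v <- v + tab
  spike_raster(v, raster$dt, raster$cell_ids, raster$cell_type)
}

#' Random cell removal surrogate
#'
#' Retains a uniformly random subset of `round((1 - pct/100) * n_cells)`
#' cells. Used to probe the robustness of avalanche scaling to reductions of
#' the neuronal sampling fraction; callers typically repeat over several
#' seeds and average the downstream scaling estimates.
#'
#' @param raster A [spike_raster()].
#' @param pct Percentage of cells to remove, `0 <= pct < 100`.
#' @param seed Optional integer seed.
#' @return A new `spike_raster` with the retained cells in original order.
#' @export
surrogate_remove_cells <- function(raster, pct, seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (!is.numeric(pct) || length(pct) != 1L || is.na(pct) ||
      pct < 0 || pct >= 100)
    rlang::abort("`pct` must be in [0, 100).")
  if (!is.null(seed)) set.seed(seed)
  n_keep <- round((1 - pct / 100) * n_cells(raster))
  if (n_keep < 1L)
    rlang::abort("cell removal would leave an empty raster.")
  keep <- sort(sample.int(n_cells(raster), n_keep))
  spike_raster(raster$values[keep, , drop = FALSE], raster$dt,
               raster$cell_ids[keep],
               if (!is.null(raster$cell_type)) raster$cell_type[keep])
}

#' Trial-shuffle surrogate for evoked data
#'
#' For each cell independently and each stimulus condition, permutes the
#' cell's activity segments across the trials of that condition. Every
#' trial of the shuffled raster still holds a response to the same stimulus,
#' but taken from a different presentation, which destroys within-trial
#' inter-neuronal correlations while preserving per-cell tuning. Activity
#' outside the listed trials is left untouched.
#'
#' @param raster A [spike_raster()].
#' @param trials A data frame with columns `condition`, `start_bin`,
#'   `end_bin`: 0-based half-open bin intervals, non-overlapping, within the
#'   raster. Trials of the same condition must have equal length.
#' @param seed Optional integer seed.
#' @return A new `spike_raster`.
#' @export
surrogate_trial_shuffle <- function(raster, trials, seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  trials <- tibble::as_tibble(trials)
  req <- c("condition", "start_bin", "end_bin")
  if (!all(req %in% names(trials)))
    rlang::abort("`trials` needs columns condition, start_bin, end_bin.")
  if (any(trials$start_bin < 0) || any(trials$end_bin > n_bins(raster)) ||
      any(trials$end_bin <= trials$start_bin))
    rlang::abort("trial intervals must be half-open, increasing and in range.")
  ord <- order(trials$start_bin)
  if (any(trials$end_bin[ord][-nrow(trials)] >
          trials$start_bin[ord][-1]))
    rlang::abort("trial intervals must not overlap.")
  lens <- trials$end_bin - trials$start_bin
  bad <- tapply(lens, trials$condition, function(l) length(unique(l)) > 1L)
  if (any(bad))
    rlang::abort("trials of the same condition must have equal length.")

  if (!is.null(seed)) set.seed(seed)
  v <- raster$values
  for (cond in unique(trials$condition)) {
    tr <- trials[trials$condition == cond, ]
    m <- nrow(tr)
    if (m < 2L) next
    segs <- purrr::map(seq_len(m), function(j)
      (tr$start_bin[j] + 1L):tr$end_bin[j])
    for (i in seq_len(nrow(v))) {
      perm <- sample.int(m)
      old <- purrr::map(segs, function(s) v[i, s])
      for (j in seq_len(m)) v[i, segs[[j]]] <- old[[perm[j]]]
    }
  }
  spike_raster(v, raster$dt, raster$cell_ids, raster$cell_type)
}

#' Toy raster with planted suprathreshold epochs
#'
#' Generates a small synthetic raster for testing and demonstrations:
#' independent Poisson background spiking, optionally modulated by a latent
#' drive shared across cells (which creates zero-lag correlations), plus
#' planted population epochs whose summed amplitude follows a parabolic or
#' flat envelope distributed across cells.
#'
#' The `correlation` knob is the standard deviation of a shared log-normal
#' gain applied to every cell's background rate: 0 gives independent cells,
#' larger values give increasingly correlated population fluctuations.
#'
#' @param n_cells,n_bins Raster dimensions.
#' @param dt Bin width in seconds.
#' @param background_rate Expected background spikes per bin per cell.
#' @param planted_epochs Optional data frame with columns `start_bin`
#'   (0-based), `duration` (bins), `amplitude` (peak summed population
#'   activity) and optionally `shape` (`"parabola"` or `"flat"`).
#' @param correlation Shared-gain standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return A [spike_raster()].
#' @export
make_toy_raster <- function(n_cells, n_bins, dt = 0.022,
                            background_rate = 0.05, planted_epochs = NULL,
                            correlation = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_cells >= 1, n_bins >= 1, background_rate >= 0,
            correlation >= 0)
  lam <- matrix(background_rate, n_cells, n_bins)
  if (correlation > 0 && background_rate > 0) {
    gain <- exp(correlation * stats::rnorm(n_bins) - correlation^2 / 2)
    lam <- sweep(lam, 2, gain, `*`)
  }
  v <- matrix(stats::rpois(n_cells * n_bins, as.vector(lam)),
              n_cells, n_bins)
  if (!is.null(planted_epochs)) {
    pe <- tibble::as_tibble(planted_epochs)
    if (!"shape" %in% names(pe)) pe$shape <- "parabola"
    for (j in seq_len(nrow(pe))) {
      L <- pe$duration[j]
      bins <- pe$start_bin[j] + seq_len(L)
      if (any(bins < 1L) || any(bins > n_bins))
        rlang::abort("planted epoch outside raster bounds.")
      u <- (seq_len(L) - 0.5) / L
      env <- switch(pe$shape[j],
        parabola = pe$amplitude[j] * 4 * u * (1 - u),
        flat = rep(pe$amplitude[j], L),
        rlang::abort("unknown epoch shape.")
      )
      # distribute the envelope across cells as coincident firing
      for (b in seq_along(bins)) {
        add <- stats::rmultinom(1, size = round(env[b]),
                                prob = rep(1, n_cells))[, 1]
        v[, bins[b]] <- v[, bins[b]] + add
      }
    }
  }
  spike_raster(v, dt)
}
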