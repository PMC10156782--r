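#' Per-avalanche activity segments
#'
#' Recovers the suprathreshold activity time course of each avalanche in a
#' detection table by rebuilding the coarse-grained ensemble the table was
#' extracted from.
#'
#' @param p Population activity (tibble, raster or vector).
#' @param avalanches Avalanche tibble from [detect_avalanches()]; attribute
#'   `theta` (or argument `theta`) supplies the threshold to re-apply.
#' @param theta,mode Thresholding used at detection (defaults to the
#'   attributes stored on `avalanches`).
#' @param dt Bin width when `p` is a bare vector.
#' @return The avalanche tibble with a list-column `values` holding each
#'   epoch's activity vector.
#' @export
avalanche_segments <- function(p, avalanches, theta = NULL,
                               mode = c("hard", "soft"), dt = NULL) {
  mode <- rlang::arg_match(mode)
  a <- as_activity(p, dt)
  if (is.null(theta)) theta <- attr(avalanches, "theta")
  if (is.null(theta)) rlang::abort("`theta` not supplied and not stored on the table.")
  thr <- apply_threshold(a$p, theta, mode = mode, dt = a$dt)
  out <- avalanches
  out$values <- vector("list", nrow(out))
  for (kk in unique(out$k)) {
    ens <- coarse_grain(thr, kk, dt = a$dt)
    rows <- which(out$k == kk)
    for (r in rows) {
      s <- ens[[out$offset[r] + 1L]]
      idx <- (out$start_bin[r] + 1L):(out$start_bin[r] + out$duration_bins[r])
      out$values[[r]] <- s[idx]
    }
  }
  out
}

#' Mean temporal profile per duration class
#'
#' Avalanches are grouped by duration; the suprathreshold activity time
#' courses within each group are averaged element-wise (the bounding zero
#' bins are excluded). Classes with fewer than `min_count` avalanches are
#' dropped.
#'
#' @param segments Output of [avalanche_segments()] (or any tibble with
#'   `duration_bins` and a `values` list-column).
#' @param durations Optional durations (bins) to keep.
#' @param min_count Minimum avalanches per class (default 5).
#' @return A tibble of class `avalanche_profiles`: `duration_bins`,
#'   `t_index` (1-based position within the epoch), `mean`, `sd`, `n`.
#' @export
temporal_profile <- function(segments, durations = NULL, min_count = 5L) {
  stopifnot("values" %in% names(segments))
  if (!is.null(durations))
    segments <- segments[segments$duration_bins %in% durations, ]
  keep <- table(segments$duration_bins)
  keep <- as.integer(names(keep)[keep >= min_count])
  segments <- segments[segments$duration_bins %in% keep, ]
  if (nrow(segments) == 0L)
    rlang::abort("no duration class has enough avalanches.")
  out <- purrr::map(sort(unique(segments$duration_bins)), function(L) {
    m <- do.call(rbind, segments$values[segments$duration_bins == L])
    tibble::tibble(
      duration_bins = L,
      t_index = seq_len(ncol(m)),
      mean = colMeans(m),
      sd = apply(m, 2, stats::sd),
      n = nrow(m)
    )
  }) |> purrr::list_rbind()
  class(out) <- c("avalanche_profiles", class(out))
  out
}

# x-rescale a profile to [0, 1] and linearly interpolate to n points;
# endpoints pinned to the first/last bin values
interp_profile <- function(v, n = 500L) {
  if (length(v) == 1L) return(rep(v, n))
  stats::approx(seq(0, 1, length.out = length(v)), v,
                xout = seq(0, 1, length.out = n))$y
}

#' Avalanche shape-collapse exponent
#'
#' Rescales each duration class's mean profile onto the unit interval,
#' interpolates to 500 points, divides by `L^(chi - 1)`, and finds the
#' exponent `chi` that makes the rescaled shapes coincide: the collapse
#' exponent minimises the amplitude-normalised RMS difference between
#' shapes. At a critical point the collapse exponent equals the
#' size-duration scaling exponent (`chi = 2` for parabolic avalanches);
#' duration-independent flat profiles collapse at `chi = 1`.
#'
#' The objective is the mean pairwise RMS difference between collapsed
#' shapes (default) or the RMS deviation from the mean collapsed shape,
#' both normalised by the grand mean amplitude so the minimisation cannot
#' cheat by shrinking every profile toward zero. The 1-D minimisation uses
#' golden-section search on `range` with tolerance `1e-4`.
#'
#' @param profiles An [temporal_profile()] table with at least 3 duration
#'   classes.
#' @param range Search interval for `chi`.
#' @param objective `"pairwise"` or `"mean_shape"`.
#' @param n_points Interpolation grid size (default 500).
#' @return A list of class `collapse_result`: `chi_coll`, `rms` (objective
#'   at the optimum), `durations`, `objective`.
#' @export
collapse_exponent <- function(profiles, range = c(0.5, 4),
                              objective = c("pairwise", "mean_shape"),
                              n_points = 500L) {
  objective <- rlang::arg_match(objective)
  Ls <- sort(unique(profiles$duration_bins))
  if (length(Ls) < 3L)
    rlang::abort("need at least 3 duration classes to collapse.")
  curves <- purrr::map(Ls, function(L) {
    interp_profile(profiles$mean[profiles$duration_bins == L], n_points)
  })
  obj <- function(chi) {
    M <- vapply(seq_along(Ls),
                function(i) curves[[i]] / Ls[i]^(chi - 1),
                numeric(n_points))
    mm <- mean(M)
    if (mm <= 0) return(Inf)
    M <- M / mm
    if (objective == "pairwise") {
      tot <- 0; np <- 0L
      for (a in 1:(ncol(M) - 1)) for (b in (a + 1):ncol(M)) {
        tot <- tot + sqrt(mean((M[, a] - M[, b])^2)); np <- np + 1L
      }
      tot / np
    } else {
      mu <- rowMeans(M)
      mean(sqrt(colMeans((M - mu)^2)))
    }
  }
  opt <- stats::optimize(obj, interval = range, tol = 1e-4)
  structure(
    list(chi_coll = opt$minimum, rms = opt$objective, durations = Ls,
         objective = objective),
    class = "collapse_result"
  )
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf(
    "<collapse_result> chi_coll = %.3f (normalised rms %.3g) over L = {%s}\n",
    x$chi_coll, x$rms, paste(x$durations, collapse = ", ")))
  invisible(x)
}

#' Inverted-parabola goodness of a mean profile
#'
#' Least-squares fit of `a * x * (1 - x) + b` (with `a >= 0`) to a profile
#' on the unit interval; returns `1 - RMS residual / amplitude range`, so an
#' exact inverted parabola scores 1 and flat or sawtooth profiles score
#' measurably lower.
#'
#' @param profile Numeric profile vector, or one class of an
#'   [temporal_profile()] table (column `mean`).
#' @param n_points Interpolation grid (default 500).
#' @return A single quality value (typically in `[0, 1]`).
#' @export
parabola_quality <- function(profile, n_points = 500L) {
  if (is.data.frame(profile)) {
    stopifnot(length(unique(profile$duration_bins)) == 1L)
    profile <- profile$mean
  }
  v <- interp_profile(profile, n_points)
  x <- seq(0, 1, length.out = n_points)
  X <- cbind(par = x * (1 - x), int = 1)
  cf <- stats::coef(stats::lm.fit(X, v))
  if (cf[1] < 0) {
    cf[1] <- 0
    cf[2] <- mean(v)
  }
  res <- v - X %*% cf
  rng <- diff(range(v))
  if (rng == 0) rng <- max(abs(v), 1)
  1 - sqrt(mean(res^2)) / rng
}

#' Remap coarse-grained avalanches to the original resolution
#'
#' Converts each avalanche's coarse bin interval back to original-resolution
#' bins (`[start * k + offset, (start + L) * k + offset)`) and extracts the
#' raw activity over those windows, so that profiles of epochs detected at
#' coarse resolution can be inspected at the native frame rate.
#'
#' @param p Population activity at the original resolution.
#' @param avalanches Avalanche tibble carrying `k`, `offset`, `start_bin`,
#'   `duration_bins`.
#' @param dt Bin width when `p` is a bare vector.
#' @return The avalanche tibble with list-column `values` holding the
#'   original-resolution activity of each epoch (length `L * k`) and columns
#'   `orig_start_bin`, `orig_n_bins`.
#' @export
remap_to_original_dt <- function(p, avalanches, dt = NULL) {
  a <- as_activity(p, dt)
  nb <- length(a$p)
  out <- avalanches
  out$orig_start_bin <- out$start_bin * out$k + out$offset
  out$orig_n_bins <- out$duration_bins * out$k
  if (any(out$orig_start_bin + out$orig_n_bins > nb))
    rlang::abort("remapped epoch extends beyond the original series.")
  out$values <- purrr::map(seq_len(nrow(out)), function(r) {
    a$p[(out$orig_start_bin[r] + 1L):(out$orig_start_bin[r] + out$orig_n_bins[r])]
  })
  out
}

#' Inter-avalanche interval regularity diagnostic
#'
#' Coefficient of variation of the gaps between consecutive avalanche
#' onsets (per offset, pooled). Values near 0 indicate clock-like recurrence
#' (an oscillation); values near 1 are consistent with irregular,
#' Poisson-like avalanche timing.
#'
#' @param avalanches Avalanche tibble.
#' @return CV of inter-onset intervals (NA with fewer than 3 avalanches in
#'   every offset).
#' @export
interval_cv <- function(avalanches) {
  gaps <- avalanches |>
    dplyr::group_by(.data$k, .data$offset) |>
    dplyr::arrange(.data$start_bin, .by_group = TRUE) |>
    dplyr::summarise(g = list(diff(.data$start_bin)), .groups = "drop")
  g <- unlist(gaps$g)
  if (length(g) < 2L) return(NA_real_)
  stats::sd(g) / mean(g)
}
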