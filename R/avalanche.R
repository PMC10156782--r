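#' Threshold a population-activity series
#'
#' Applies a hard or soft threshold `theta` to population activity. Hard
#' thresholding zeroes bins with `activity <= theta` and keeps suprathreshold
#' bins unchanged; soft thresholding additionally subtracts `theta` from the
#' surviving bins, discarding the subthreshold area under each epoch.
#' Suprathreshold means strictly greater than `theta`.
#'
#' @param p Population activity: the tibble from [population_activity()], a
#'   [spike_raster()], or a numeric vector.
#' @param theta Threshold, in activity units (>= 0).
#' @param mode `"hard"` (default) or `"soft"`.
#' @param dt Bin width in seconds, used only when `p` is a bare vector.
#' @return A numeric vector of thresholded activity with attribute `dt`.
#' @export
apply_threshold <- function(p, theta, mode = c("hard", "soft"), dt = NULL) {
  mode <- rlang::arg_match(mode)
  stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0)
  a <- as_activity(p, dt)
  x <- a$p
  sub <- x <= theta
  if (mode == "soft") x <- x - theta
  x[sub] <- 0
  attr(x, "dt") <- a$dt
  x
}

#' Temporal coarse-graining ensemble
#'
#' For a coarse-graining factor `k`, sums non-overlapping windows of `k`
#' consecutive bins, once for every phase offset `j = 0, ..., k - 1`. Only
#' complete windows are kept (a trailing partial window would bias window
#' sums low). `k = 1` returns the input as the single ensemble member.
#' Coarse-graining is applied to the *thresholded* series: two epochs
#' separated by a short subthreshold gap at the original resolution merge
#' into one at a sufficiently large `k`, which is the mechanism that
#' reassembles subsampled avalanches.
#'
#' @param p Thresholded population activity (vector with `dt` attribute, as
#'   returned by [apply_threshold()], or any input accepted by it).
#' @param k Coarse-graining factor (integer >= 1, at most the series length).
#' @param dt Bin width in seconds when `p` is a bare vector.
#' @return A list of `k` numeric vectors (one per offset), with attributes
#'   `k` and `dt` (the original bin width).
#' @export
coarse_grain <- function(p, k, dt = NULL) {
  a <- as_activity(p, dt)
  x <- a$p
  k <- as.integer(k)
  if (k < 1L) rlang::abort("`k` must be >= 1.")
  if (k > length(x)) rlang::abort("`k` exceeds the series length.")
  out <- purrr::map(0:(k - 1L), function(j) {
    m <- (length(x) - j) %/% k
    if (m < 1L) return(numeric(0))
    colSums(matrix(x[(j + 1L):(j + m * k)], nrow = k))
  })
  attr(out, "k") <- k
  attr(out, "dt") <- a$dt
  out
}

#' Extract avalanches (suprathreshold epochs) from one series
#'
#' Finds maximal runs of strictly positive bins bounded by zero bins. The
#' size `S` of an epoch is the summed activity over the run and its duration
#' `L` is the run length in bins (equivalently `tau2 - tau1 - 1` for the
#' bracketing zero bins at `tau1`, `tau2`). Runs that touch either end of
#' the series are discarded, because their bounding zeros are unobserved.
#'
#' @param series Nonnegative numeric vector (typically one member of a
#'   [coarse_grain()] ensemble).
#' @param k Coarse-graining factor the series was built with.
#' @param offset Phase offset of the series within the ensemble.
#' @param dt Original bin width in seconds.
#' @return A tibble with columns `k`, `offset`, `start_bin` (0-based index
#'   into the coarse series), `duration_bins`, `size`, `duration_seconds`
#'   (`duration_bins * k * dt`).
#' @export
extract_avalanches <- function(series, k = 1L, offset = 0L, dt = 1) {
  if (length(series) == 0L) return(empty_avalanche_tbl())
  if (any(series < 0)) rlang::abort("series must be nonnegative.")
  r <- rle(series > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts > 1L & ends < length(series)
  if (!any(keep)) return(empty_avalanche_tbl())
  cs <- c(0, cumsum(series))
  sizes <- cs[ends[keep] + 1L] - cs[starts[keep]]
  durs <- r$lengths[keep]
  tibble::tibble(
    k = as.integer(k), offset = as.integer(offset),
    start_bin = starts[keep] - 1L,
    duration_bins = as.integer(durs),
    size = as.numeric(sizes),
    duration_seconds = durs * as.integer(k) * dt
  )
}

empty_avalanche_tbl <- function() {
  tibble::tibble(k = integer(), offset = integer(), start_bin = integer(),
                 duration_bins = integer(), size = numeric(),
                 duration_seconds = numeric())
}

#' Detect avalanches across the full coarse-graining ensemble
#'
#' Orchestrates threshold -> coarse-grain -> epoch extraction and pools the
#' epochs of all `k` phase offsets into one table (no deduplication; every
#' offset contributes its own pass over the data).
#'
#' @param p Population activity (tibble, raster or vector).
#' @param k Coarse-graining factor.
#' @param theta Threshold in activity units, or `"auto"` to select it with
#'   [select_threshold()] at this `k`.
#' @param mode Thresholding mode, `"hard"` or `"soft"`.
#' @param dt Bin width in seconds when `p` is a bare vector.
#' @param ... Passed to [select_threshold()] when `theta = "auto"`.
#' @return A tibble of avalanches (see [extract_avalanches()]), with the
#'   threshold used stored in attribute `theta`.
#' @examples
#' p <- c(0, 3, 4, 0, 0, 2, 5, 1, 0, 0)
#' detect_avalanches(p, k = 1, theta = 0)
#' @export
detect_avalanches <- function(p, k = 1L, theta = 0, mode = c("hard", "soft"),
                              dt = NULL, ...) {
  mode <- rlang::arg_match(mode)
  a <- as_activity(p, dt)
  if (identical(theta, "auto")) {
    sel <- select_threshold(a$p, k = k, dt = a$dt, mode = mode, ...)
    theta <- sel$theta_star
  }
  thr <- apply_threshold(a$p, theta, mode = mode, dt = a$dt)
  ens <- coarse_grain(thr, k, dt = a$dt)
  out <- purrr::list_rbind(purrr::imap(ens, function(s, j) {
    extract_avalanches(s, k = k, offset = j - 1L, dt = a$dt)
  }))
  if (nrow(out) == 0L) out <- empty_avalanche_tbl()
  attr(out, "theta") <- theta
  attr(out, "dt") <- a$dt
  out
}

#' Data-driven threshold selection from the epoch-count curve
#'
#' Counts suprathreshold epochs (pooled over the coarse-graining ensemble at
#' factor `k`) for a grid of thresholds spanning "removes nothing" to
#' "removes everything". The count curve `N(theta)` is typically well
#' approximated by a log-normal shape; a scaled log-normal density is fitted
#' and the working threshold is placed two shape standard deviations below
#' the shape location: `theta* = exp(mu_log - 2 sigma_log)`. Shape
#' parameters of a log-normal live on the log axis, which is how the
#' `mu - 2 sigma` rule is interpreted here; `space = "linear"` instead
#' applies the rule to the linear-scale mean and SD of the fitted curve.
#' If the nonlinear fit fails, a quantile fallback places `theta*` at the
#' 2.3rd percentile of the count-weighted threshold distribution (the
#' Gaussian mass below `mu - 2 sigma`), with a warning.
#'
#' @param p Population activity (tibble, raster or vector).
#' @param k Coarse-graining factor at which epochs are counted.
#' @param theta_grid Optional numeric grid; by default 100 logarithmically
#'   spaced values from just below the smallest positive activity to the
#'   maximum.
#' @param mode Thresholding mode used while counting.
#' @param dt Bin width when `p` is a bare vector.
#' @return An object of class `threshold_selection`: list with `curve`
#'   (tibble `theta`, `n_epochs`), `mu_log`, `sigma_log`, `theta_star`,
#'   `k`, `method`.
#' @export
select_threshold <- function(p, k = 1L, theta_grid = NULL,
                             mode = c("hard", "soft"), dt = NULL,
                             space = c("log", "linear")) {
  mode <- rlang::arg_match(mode)
  space <- rlang::arg_match(space)
  a <- as_activity(p, dt)
  pos <- a$p[a$p > 0]
  if (length(pos) == 0L) rlang::abort("series has no positive activity.")
  if (is.null(theta_grid)) {
    lo <- min(pos) * 0.5
    hi <- max(a$p)
    theta_grid <- exp(seq(log(lo), log(hi), length.out = 100L))
  }
  n_ep <- vapply(theta_grid, function(th) {
    thr <- apply_threshold(a$p, th, mode = mode, dt = a$dt)
    ens <- coarse_grain(thr, k, dt = a$dt)
    sum(vapply(ens, function(s) {
      r <- rle(s > 0)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      sum(r$values & starts > 1L & ends < length(s))
    }, numeric(1)))
  }, numeric(1))

  curve <- tibble::tibble(theta = theta_grid, n_epochs = n_ep)
  fit <- fit_lognormal_curve(curve)
  if (is.null(fit)) {
    rlang::warn("log-normal fit of N(theta) failed; using quantile fallback.")
    w <- n_ep / sum(n_ep)
    cw <- cumsum(w)
    theta_star <- theta_grid[which(cw >= stats::pnorm(-2))[1]]
    mu_log <- NA_real_; sigma_log <- NA_real_
    method <- "quantile_fallback"
  } else {
    mu_log <- fit[["mu"]]; sigma_log <- fit[["sigma"]]
    if (space == "log") {
      theta_star <- exp(mu_log - 2 * sigma_log)
    } else {
      m_lin <- exp(mu_log + sigma_log^2 / 2)
      sd_lin <- m_lin * sqrt(exp(sigma_log^2) - 1)
      theta_star <- max(m_lin - 2 * sd_lin, min(theta_grid))
    }
    method <- paste0("lognormal_", space)
  }
  structure(
    list(curve = curve, mu_log = mu_log, sigma_log = sigma_log,
         amplitude = if (is.null(fit)) NA_real_ else fit[["A"]],
         theta_star = theta_star, k = as.integer(k), method = method),
    class = "threshold_selection"
  )
}

# least-squares fit of N(theta) ~ A * dlnorm(theta, mu, sigma); returns
# named vector c(A, mu, sigma) or NULL on failure
fit_lognormal_curve <- function(curve) {
  d <- curve[curve$n_epochs > 0 & curve$theta > 0, ]
  if (nrow(d) < 5L) return(NULL)
  w <- d$n_epochs / sum(d$n_epochs)
  mu0 <- sum(w * log(d$theta))
  s0 <- sqrt(max(sum(w * (log(d$theta) - mu0)^2), 1e-4))
  A0 <- max(d$n_epochs) / stats::dlnorm(exp(mu0 - s0^2), mu0, s0)
  out <- tryCatch({
    ft <- minpack.lm::nlsLM(
      n_epochs ~ A * stats::dlnorm(theta, mu, sigma),
      data = d,
      start = list(A = A0, mu = mu0, sigma = s0),
      lower = c(0, mu0 - 10, 1e-3),
      upper = c(Inf, mu0 + 10, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    stats::coef(ft)
  }, error = function(e) NULL)
  out
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf(
    "<threshold_selection> k = %d, method = %s\n  theta* = %.4g (mu_log = %.3f, sigma_log = %.3f)\n",
    x$k, x$method, x$theta_star, x$mu_log, x$sigma_log))
  invisible(x)
}

#' @export
tidy.threshold_selection <- function(x, ...) {
  tibble::tibble(
    term = c("mu_log", "sigma_log", "amplitude", "theta_star"),
    estimate = c(x$mu_log, x$sigma_log, x$amplitude, x$theta_star)
  )
}
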