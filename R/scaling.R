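#' Maximum-likelihood power-law exponent on a bounded range
#'
#' Fits `P(x) ~ x^(-exponent)` to samples restricted to `[x_min, x_max]` by
#' maximum likelihood, using the discrete truncated form when all in-range
#' samples are integers and the continuous truncated form otherwise. When
#' `x_max` is omitted it is set to the finite-size cutoff detected by
#' [detect_cutoff()]; when `x_min` is omitted it is chosen on a logarithmic
#' grid by minimising the Kolmogorov-Smirnov distance between the fitted and
#' empirical distributions (the standard automated lower-bound selection for
#' empirical power laws).
#'
#' @param x Numeric sample (avalanche sizes or durations).
#' @param x_min,x_max Fit range bounds; either may be `NULL` for automatic
#'   selection.
#' @param min_n Minimum number of in-range samples (default 100).
#' @return An object of class `powerlaw_fit`: list with `exponent`,
#'   `se` (curvature-based standard error), `x_min`, `x_max`, `n`,
#'   `estimator` (`"discrete_mle"` or `"continuous_mle"`).
#' @examples
#' x <- round(1 / runif(2000)^(1 / 0.5))  # discrete-ish power law, alpha = 1.5
#' fit_powerlaw_exponent(x, x_min = 1, x_max = 1000)
#' @export
fit_powerlaw_exponent <- function(x, x_min = NULL, x_max = NULL,
                                  min_n = 100L) {
  x <- x[is.finite(x) & x > 0]
  if (length(unique(x)) < 2L)
    rlang::abort("degenerate sample: all values identical.")
  if (is.null(x_max)) x_max <- detect_cutoff(x)
  if (is.null(x_min)) x_min <- select_xmin_ks(x, x_max)
  xs <- x[x >= x_min & x <= x_max]
  if (length(xs) < min_n)
    rlang::abort(sprintf("only %d samples in [%g, %g]; need >= %d.",
                         length(xs), x_min, x_max, min_n))
  if (length(unique(xs)) < 2L)
    rlang::abort("degenerate support within the fit range.")
  # the discrete normalising sum costs O(x_max - x_min) per likelihood
  # evaluation; beyond ~1e5 support points it is numerically
  # indistinguishable from the continuous integral
  discrete <- all(xs == round(xs)) && (x_max - x_min) <= 1e5
  nll <- powerlaw_nll(xs, x_min, x_max, discrete)
  opt <- stats::optimize(nll, interval = c(0.05, 6))
  a <- opt$minimum
  # SE from the curvature of the per-sample mean log-likelihood
  h <- 1e-3
  d2 <- (nll(a + h) - 2 * nll(a) + nll(a - h)) / h^2
  se <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2 * length(xs)) else NA_real_
  structure(
    list(exponent = a, se = se, x_min = x_min, x_max = x_max,
         n = length(xs),
         estimator = if (discrete) "discrete_mle" else "continuous_mle"),
    class = "powerlaw_fit"
  )
}

# mean negative log-likelihood (per sample) as a function of the exponent
powerlaw_nll <- function(xs, x_min, x_max, discrete) {
  mlog <- mean(log(xs))
  if (discrete) {
    supp <- seq(ceiling(x_min), floor(x_max))
    function(a) a * mlog + log(sum(supp^(-a)))
  } else {
    function(a) {
      Z <- if (abs(a - 1) < 1e-9) log(x_max / x_min)
      else abs((x_min^(1 - a) - x_max^(1 - a)) / (a - 1))
      a * mlog + log(Z)
    }
  }
}

#' Detect the finite-size cutoff of a heavy-tailed sample
#'
#' Fits a provisional power law over the mid-quantile range
#' `[q50, q99.5]` and walks up the tail: the cutoff is the smallest value
#' above `q99.5` at which the empirical conditional CCDF falls more than
#' three binomial standard errors below the fitted power-law CCDF, i.e.
#' where the data start being depleted relative to scale-free behaviour.
#' Returns `max(x)` when no departure is found.
#'
#' @param x Numeric sample.
#' @return The cutoff location (same units as `x`).
#' @export
detect_cutoff <- function(x) {
  x <- x[is.finite(x) & x > 0]
  q <- stats::quantile(x, c(0.5, 0.995), names = FALSE)
  if (q[1] >= q[2] || length(unique(x[x >= q[1] & x <= q[2]])) < 2L)
    return(max(x))
  nll <- powerlaw_nll(x[x >= q[1] & x <= q[2]], q[1], q[2],
                      discrete = FALSE)
  a <- stats::optimize(nll, interval = c(0.05, 6))$minimum
  ss <- sort(x[x >= q[1]])
  n <- length(ss)
  emp <- (n - seq_len(n) + 1) / n
  mod <- (ss / q[1])^(1 - a)
  se <- sqrt(pmax(mod * (1 - mod), 1e-12) / n)
  bad <- which(ss > q[2] & (mod - emp) > 3 * se)
  if (length(bad) == 0L) max(x) else ss[bad[1]]
}

# KS-minimising lower bound on a log grid
select_xmin_ks <- function(x, x_max, n_grid = 30L, min_n = 200L) {
  lo <- max(min(x), .Machine$double.eps)
  hi <- x_max / 10
  if (hi <= lo) return(lo)
  grid <- unique(signif(exp(seq(log(lo), log(hi), length.out = n_grid)), 3))
  ks <- vapply(grid, function(xm) {
    xs <- x[x >= xm & x <= x_max]
    if (length(xs) < min_n || length(unique(xs)) < 2L) return(NA_real_)
    discrete <- all(xs == round(xs)) && (x_max - xm) <= 1e5
    a <- stats::optimize(powerlaw_nll(xs, xm, x_max, discrete),
                         interval = c(0.05, 6))$minimum
    xs <- sort(xs)
    n <- length(xs)
    Fm <- if (abs(a - 1) < 1e-9) log(xs / xm) / log(x_max / xm)
    else (xm^(1 - a) - xs^(1 - a)) / (xm^(1 - a) - x_max^(1 - a))
    max(abs(Fm - (seq_len(n) - 0.5) / n))
  }, numeric(1))
  if (all(is.na(ks))) return(lo)
  grid[which.min(ks)]
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> exponent = %.3f (se %.3g), range [%g, %g], n = %d, %s\n",
    x$exponent, x$se, x$x_min, x$x_max, x$n, x$estimator))
  invisible(x)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(term = "exponent", estimate = x$exponent,
                 std.error = x$se)
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, se = x$se, x_min = x$x_min,
                 x_max = x$x_max, n = x$n, estimator = x$estimator)
}

#' Mean avalanche size per duration
#'
#' @param avalanches Avalanche tibble from [detect_avalanches()] (any pooling
#'   of offsets at one coarse-graining level).
#' @return A tibble of class `size_duration_table`: `duration_bins`,
#'   `mean_size`, `sd_size`, `n`, and `duration_seconds` (mean over the
#'   group) when present in the input; sorted by duration.
#' @export
mean_size_vs_duration <- function(avalanches) {
  if (nrow(avalanches) == 0L)
    rlang::abort("no avalanches supplied.")
  out <- avalanches |>
    dplyr::group_by(.data$duration_bins) |>
    dplyr::summarise(
      mean_size = mean(.data$size),
      sd_size = stats::sd(.data$size),
      n = dplyr::n(),
      duration_seconds = if ("duration_seconds" %in% names(avalanches))
        mean(.data$duration_seconds) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$duration_bins)
  class(out) <- c("size_duration_table", class(out))
  out
}

#' Double power-law (crossover) fit of mean size versus duration
#'
#' Fits `S(d) = C d^chi_sh / (1 + (d / Phi)^gamma)^((chi_sh + chi_lg) / gamma)`
#' to a [mean_size_vs_duration()] table. The curve follows an initial slope
#' `chi_sh` for `d << Phi` and crosses over to slope `chi_lg` beyond the
#' crossover duration `Phi`; `gamma` sets the abruptness of the transition
#' and is fixed at 4. The fit is performed in log-log space, each populated
#' duration weighted equally, with the slopes bounded to `[0, 4]` and `Phi`
#' to `[min L, 10 max L]`; starting values come from [chi_simple()].
#'
#' @param table A `size_duration_table` (or any data frame with
#'   `duration_bins` and `mean_size`).
#' @param gamma Crossover sharpness (fixed, not fitted).
#' @return An object of class `scaling_fit`: list with `C`, `chi_sh`,
#'   `chi_lg`, `Phi`, `gamma`, `residual` (root-mean-square log residual),
#'   `n_durations`, `table`.
#' @export
fit_scaling_crossover <- function(table, gamma = 4) {
  tb <- tibble::as_tibble(table)
  tb <- tb[is.finite(tb$mean_size) & tb$mean_size > 0, ]
  if (nrow(tb) < 5L)
    rlang::abort("need at least 5 populated durations for the crossover fit.")
  if (max(tb$duration_bins) / min(tb$duration_bins) < 4)
    rlang::warn("duration range spans less than ~0.6 decades; fit may be ill-constrained.")
  d <- tibble::tibble(ld = log(tb$duration_bins), ls = log(tb$mean_size))
  init <- chi_simple(tb)
  sh0 <- clamp(ifelse(is.na(init$chi_sh), 1.5, init$chi_sh), 0.05, 3.95)
  lg0 <- clamp(ifelse(is.na(init$chi_lg), 1, init$chi_lg), 0.05, 3.95)
  lPhi0 <- log(stats::median(tb$duration_bins))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ls ~ lC + sh * ld - (sh + lg) / gamma * log1p(exp(gamma * (ld - lPhi))),
      data = d,
      start = list(lC = 0, sh = sh0, lg = lg0, lPhi = lPhi0),
      lower = c(-Inf, 0, 0, log(min(tb$duration_bins))),
      upper = c(Inf, 4, 4, log(10 * max(tb$duration_bins))),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e)
      rlang::abort(paste0("crossover fit did not converge: ",
                          conditionMessage(e)))
  )
  cf <- stats::coef(fit)
  structure(
    list(C = exp(unname(cf["lC"])), chi_sh = unname(cf["sh"]),
         chi_lg = unname(cf["lg"]), Phi = exp(unname(cf["lPhi"])),
         gamma = gamma,
         residual = sqrt(mean(stats::residuals(fit)^2)),
         n_durations = nrow(tb), table = tb),
    class = "scaling_fit"
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> chi_sh = %.3f, chi_lg = %.3f, Phi = %.3g, C = %.3g (gamma = %g)\n  %d durations, rms log residual %.3g\n",
    x$chi_sh, x$chi_lg, x$Phi, x$C, x$gamma, x$n_durations, x$residual))
  invisible(x)
}

#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble::tibble(
    term = c("C", "chi_sh", "chi_lg", "Phi"),
    estimate = c(x$C, x$chi_sh, x$chi_lg, x$Phi)
  )
}

#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(chi_sh = x$chi_sh, chi_lg = x$chi_lg, Phi = x$Phi,
                 C = x$C, gamma = x$gamma, residual = x$residual,
                 n_durations = x$n_durations)
}

#' Predicted mean size of a crossover fit
#'
#' @param object A `scaling_fit`.
#' @param durations Durations (bins) at which to evaluate the curve.
#' @param ... Unused.
#' @return Numeric vector of predicted mean sizes.
#' @export
predict.scaling_fit <- function(object, durations, ...) {
  with(object, C * durations^chi_sh /
         (1 + (durations / Phi)^gamma)^((chi_sh + chi_lg) / gamma))
}

#' Simple two-range slope estimates of the scaling exponent
#'
#' Ordinary least-squares slopes of `log(mean size)` versus `log(duration)`
#' over a short-duration range (few-generation avalanches, default
#' `L = 1..4`) and a long-duration range (default `L >= 10`). An empty or
#' single-point range yields `NA` for that slope.
#'
#' @param table A [mean_size_vs_duration()] table.
#' @param short_range,long_range Two-element numeric ranges (inclusive) of
#'   `duration_bins`.
#' @return A one-row tibble with `chi_sh`, `chi_lg`.
#' @export
chi_simple <- function(table, short_range = c(1, 4),
                       long_range = c(10, Inf)) {
  tb <- tibble::as_tibble(table)
  slope <- function(rg) {
    d <- tb[tb$duration_bins >= rg[1] & tb$duration_bins <= rg[2] &
              tb$mean_size > 0, ]
    if (nrow(d) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(log(mean_size) ~ log(duration_bins),
                                 data = d))[2])
  }
  tibble::tibble(chi_sh = slope(short_range), chi_lg = slope(long_range))
}

#' Bootstrap uncertainty of the scaling exponents
#'
#' Resamples the avalanche pool with replacement (each replicate pool has
#' the same number of avalanches as the original), recomputes the
#' size-duration table and the scaling exponents per replicate, and returns
#' the across-replicate standard deviations. Per-replicate seeds are derived
#' deterministically from `seed`.
#'
#' @param avalanches Avalanche tibble.
#' @param n_reps Number of bootstrap replicates (default 10).
#' @param method `"crossover"` ([fit_scaling_crossover()]) or `"simple"`
#'   ([chi_simple()]).
#' @param seed Optional integer seed.
#' @param ... Passed to the chosen estimator.
#' @return A list with `sd` (one-row tibble `chi_sh_sd`, `chi_lg_sd`) and
#'   `replicates` (tibble of per-replicate estimates).
#' @export
bootstrap_scaling <- function(avalanches, n_reps = 10,
                              method = c("crossover", "simple"),
                              seed = NULL, ...) {
  method <- rlang::arg_match(method)
  if (nrow(avalanches) == 0L) rlang::abort("empty avalanche pool.")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  reps <- purrr::map(seq_len(n_reps), function(r) {
    set.seed(rep_seeds[r])
    idx <- sample.int(nrow(avalanches), nrow(avalanches), replace = TRUE)
    tb <- mean_size_vs_duration(avalanches[idx, ])
    est <- if (method == "crossover") {
      ft <- tryCatch(fit_scaling_crossover(tb, ...), error = function(e) NULL)
      if (is.null(ft)) tibble::tibble(chi_sh = NA_real_, chi_lg = NA_real_)
      else tibble::tibble(chi_sh = ft$chi_sh, chi_lg = ft$chi_lg)
    } else {
      chi_simple(tb, ...)
    }
    est$replicate <- r
    est
  }) |> purrr::list_rbind()
  list(
    sd = tibble::tibble(
      chi_sh_sd = stats::sd(reps$chi_sh, na.rm = TRUE),
      chi_lg_sd = stats::sd(reps$chi_lg, na.rm = TRUE)
    ),
    replicates = reps
  )
}

#' Crackling-noise exponent relation
#'
#' Evaluates `(beta - 1) / (alpha - 1)`, the scaling exponent `chi` implied
#' by the size exponent `alpha` and duration exponent `beta` at a critical
#' point. The ratio has a singularity at `alpha = 1`; estimates with
#' `|alpha - 1| < 0.05` are flagged as unstable (thresholded and subsampled
#' data push `alpha` toward 1, making the ratio unusable there).
#'
#' @param alpha Size-distribution exponent (must differ from 1).
#' @param beta Duration-distribution exponent.
#' @return A list with `value` and `unstable`.
#' @examples
#' exponent_relation(1.5, 2)  # value 2
#' @export
exponent_relation <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            length(alpha) == 1L, length(beta) == 1L)
  if (alpha == 1)
    rlang::abort("alpha = 1: the exponent relation is singular.")
  list(value = (beta - 1) / (alpha - 1), unstable = abs(alpha - 1) < 0.05)
}
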