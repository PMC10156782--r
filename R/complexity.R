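#' Ordinal (rank-order) pattern distribution of a series
#'
#' Slides a window of `D` consecutive bins along the series (stride 1) and
#' maps each window to its rank-order word: the pattern of a monotonically
#' increasing window of depth 4 is `0123`. Ties -- common in thresholded
#' count data -- are broken by temporal order (the earlier bin gets the
#' lower rank); `tie_jitter = TRUE` instead adds an infinitesimal random
#' jitter before ranking, for sensitivity checks. With
#' `within_epochs = TRUE` (default) only windows lying entirely inside
#' suprathreshold epochs are evaluated, i.e. subthreshold activity
#' contributes no patterns; `within_epochs = FALSE` keeps every window that
#' touches at least one suprathreshold bin; `"all"` keeps all windows.
#'
#' @param series Numeric vector (typically thresholded, coarse-grained
#'   population activity) or a list of such vectors (a [coarse_grain()]
#'   ensemble), whose windows are pooled.
#' @param D Pattern depth, 3 to 7.
#' @param within_epochs `TRUE`, `FALSE`, or `"all"` (see above).
#' @param tie_jitter Break ties with random jitter instead of temporal
#'   order.
#' @return An object of class `pattern_distribution`: tibble with `pattern`
#'   (rank word, e.g. `"0123"`), `count` and `p`, covering all `D!`
#'   patterns (unobserved ones with zero probability); attributes `D` and
#'   `n_windows`.
#' @export
ordinal_patterns <- function(series, D = 5L, within_epochs = TRUE,
                             tie_jitter = FALSE) {
  D <- as.integer(D)
  if (D < 3L || D > 7L) rlang::abort("`D` must be between 3 and 7.")
  if (!is.list(series)) series <- list(series)
  codes <- purrr::map(series, function(s) {
    s <- as.numeric(s)
    if (tie_jitter && length(s) >= D) {
      eps <- min(diff(sort(unique(s)))) %||% 1
      s <- s + stats::runif(length(s), 0, eps * 1e-9)
    }
    r <- .ordinal_codes(s, D)
    keep <- if (isTRUE(within_epochs)) !r$has_zero
    else if (identical(within_epochs, "all")) rep(TRUE, length(r$code))
    else !r$all_zero
    r$code[keep]
  })
  codes <- unlist(codes)
  if (length(codes) == 0L)
    rlang::abort("no valid pattern windows in the series.")
  perms <- all_patterns(D)
  idx <- match(codes, perms$code)
  counts <- tabulate(idx, nbins = nrow(perms))
  out <- tibble::tibble(pattern = perms$pattern, count = counts,
                        p = counts / sum(counts))
  attr(out, "D") <- D
  attr(out, "n_windows") <- length(codes)
  class(out) <- c("pattern_distribution", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a) || !is.finite(a)) b else a

# all D! rank words with their integer codes (sum of rank_i * D^i)
all_patterns <- function(D) {
  perms <- permutations_of(D)
  code <- vapply(perms, function(p) sum(p * D^(seq_along(p) - 1L)),
                 numeric(1))
  tibble::tibble(
    pattern = vapply(perms, function(p) paste(p, collapse = ""),
                     character(1)),
    code = as.integer(code)
  )
}

permutations_of <- function(D) {
  if (D == 1L) return(list(0L))
  sub <- permutations_of(D - 1L)
  out <- list()
  for (p in sub) for (pos in 0:(D - 1L)) {
    out[[length(out) + 1L]] <- append(p, D - 1L, after = pos)
  }
  out
}

shannon_S <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalised Shannon entropy of a pattern distribution
#'
#' `H = S(P) / S(P_e)` with `S` the Shannon entropy (natural log,
#' `0 log 0 = 0`) and `P_e` the uniform distribution over all `D!`
#' patterns, so `H` is dimensionless in `[0, 1]`.
#'
#' @param P A [ordinal_patterns()] distribution, or a bare probability
#'   vector (assumed to span the full pattern alphabet).
#' @return `H` in `[0, 1]`.
#' @export
shannon_entropy <- function(P) {
  p <- pattern_probs(P)
  shannon_S(p) / log(length(p))
}

pattern_probs <- function(P) {
  p <- if (is.data.frame(P)) P$p else as.numeric(P)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    rlang::abort("`P` must be a probability distribution.")
  p
}

#' Jensen-Shannon statistical complexity
#'
#' Computes the disequilibrium
#' `Q_J = Q_0 * (S((P + P_e)/2) - S(P)/2 - S(P_e)/2)`, the Jensen-Shannon
#' divergence of `P` from the uniform distribution `P_e` normalised by its
#' maximum attainable value `1 / Q_0` (reached by a point mass), and the
#' complexity `C = Q_J * H`. `C` vanishes both for the uniform distribution
#' (no disequilibrium) and for a point mass (no entropy), and peaks for
#' distributions between those extremes; it is invariant under any strictly
#' monotone transform of the underlying series because rank orders do not
#' change.
#'
#' @param P A [ordinal_patterns()] distribution or probability vector over
#'   the full pattern alphabet.
#' @return A one-row tibble: `D` (when known), `H`, `Q_J`, `C`, `Q_0`,
#'   `n_states`.
#' @export
statistical_complexity <- function(P) {
  p <- pattern_probs(P)
  n <- length(p)
  H <- shannon_S(p) / log(n)
  pe <- rep(1 / n, n)
  J <- shannon_S((p + pe) / 2) - shannon_S(p) / 2 - shannon_S(pe) / 2
  Q0 <- 1 / max_js_divergence(n)
  QJ <- Q0 * J
  tibble::tibble(
    D = attr(P, "D") %||% NA_integer_,
    H = H, Q_J = QJ, C = QJ * H, Q_0 = Q0, n_states = n
  )
}

# maximum of the Jensen-Shannon term over distributions on n states,
# attained by a point mass: closed form from mixing a delta with uniform
max_js_divergence <- function(n) {
  -0.5 * ((n + 1) / n * log(n + 1) - 2 * log(2 * n) + log(n))
}

#' Pattern complexity as a function of temporal coarse-graining
#'
#' For each coarse-graining factor `k`: thresholds the population activity,
#' builds the offset ensemble, pools the ordinal patterns of all offsets
#' (windows within suprathreshold epochs only, by default) and evaluates the
#' statistical complexity. The spread is estimated by splitting the
#' recording into `n_sections` equal contiguous sections and recomputing `C`
#' per section. In subsampled critical dynamics `C(k)` rises to a peak near
#' the coarse-graining level that restores `chi_sh = 2`; in subsampled
#' subcritical dynamics it decreases with `k` over the range where enough
#' suprathreshold windows exist.
#'
#' @param p Population activity (tibble, raster or vector).
#' @param D Pattern depth (default 5).
#' @param ks Coarse-graining factors to scan.
#' @param theta Threshold (activity units) applied at the original
#'   resolution, or `"auto"` to re-select it per `k` with
#'   [select_threshold()].
#' @param mode Thresholding mode.
#' @param within_epochs Window validity rule (see [ordinal_patterns()]).
#' @param n_sections Sections for the SD estimate (default 10).
#' @param min_windows Minimum pooled windows for a defined estimate
#'   (default 100); `k` values below that yield `NA`.
#' @param dt Bin width when `p` is a bare vector.
#' @return A tibble of class `complexity_curve`: `k`, `D`, `H`, `Q_J`, `C`,
#'   `C_sd`, `n_windows`.
#' @export
complexity_curve <- function(p, D = 5L, ks = 1:20, theta = 0,
                             mode = c("hard", "soft"), within_epochs = TRUE,
                             n_sections = 10L, min_windows = 100L,
                             dt = NULL) {
  mode <- rlang::arg_match(mode)
  a <- as_activity(p, dt)
  auto_theta <- identical(theta, "auto")
  thr <- if (auto_theta) a$p
  else apply_threshold(a$p, theta, mode = mode, dt = a$dt)
  sec <- split(seq_along(thr),
               cut(seq_along(thr), n_sections, labels = FALSE))
  out <- purrr::map(ks, function(k) {
    if (auto_theta) {
      th_k <- select_threshold(a$p, k = k, mode = mode, dt = a$dt)$theta_star
      thr <- apply_threshold(a$p, th_k, mode = mode, dt = a$dt)
    }
    ens <- coarse_grain(thr, k, dt = a$dt)
    pd <- tryCatch(
      ordinal_patterns(ens, D = D, within_epochs = within_epochs),
      error = function(e) NULL)
    if (is.null(pd) || attr(pd, "n_windows") < min_windows) {
      return(tibble::tibble(k = k, D = D, H = NA_real_, Q_J = NA_real_,
                            C = NA_real_, C_sd = NA_real_,
                            n_windows = if (is.null(pd)) 0L
                            else attr(pd, "n_windows")))
    }
    cx <- statistical_complexity(pd)
    sec_C <- vapply(sec, function(ix) {
      pe <- tryCatch(
        ordinal_patterns(coarse_grain(thr[ix], min(k, length(ix)), dt = a$dt),
                         D = D, within_epochs = within_epochs),
        error = function(e) NULL)
      if (is.null(pe) || attr(pe, "n_windows") < min_windows / n_sections)
        return(NA_real_)
      statistical_complexity(pe)$C
    }, numeric(1))
    tibble::tibble(k = k, D = D, H = cx$H, Q_J = cx$Q_J, C = cx$C,
                   C_sd = stats::sd(sec_C, na.rm = TRUE),
                   n_windows = attr(pd, "n_windows"))
  }) |> purrr::list_rbind()
  class(out) <- c("complexity_curve", class(out))
  out
}

#' Lag-1 autocorrelation of coarse-grained suprathreshold activity
#'
#' Pearson correlation between the thresholded, coarse-grained population
#' activity and its lag-1 copy, using only bin pairs that lie entirely
#' within suprathreshold epochs -- optionally restricted to epochs of a
#' given duration class. High AC(1) within few-generation avalanches
#' indicates smooth (parabolic) rise-and-fall rather than bin-to-bin noise.
#'
#' @param p Population activity.
#' @param k Coarse-graining factor.
#' @param theta Threshold applied at the original resolution.
#' @param durations Optional durations (coarse bins) selecting the epoch
#'   class; `NULL` uses all epochs.
#' @param mode Thresholding mode.
#' @param dt Bin width when `p` is a bare vector.
#' @return The lag-1 Pearson correlation (single number).
#' @export
ac1 <- function(p, k = 1L, theta = 0, durations = NULL,
                mode = c("hard", "soft"), dt = NULL) {
  mode <- rlang::arg_match(mode)
  a <- as_activity(p, dt)
  thr <- apply_threshold(a$p, theta, mode = mode, dt = a$dt)
  ens <- coarse_grain(thr, k, dt = a$dt)
  pairs <- list()
  for (j in seq_along(ens)) {
    s <- ens[[j]]
    av <- extract_avalanches(s, k = k, offset = j - 1L, dt = a$dt)
    if (!is.null(durations))
      av <- av[av$duration_bins %in% durations, ]
    av <- av[av$duration_bins >= 2L, ]
    for (r in seq_len(nrow(av))) {
      idx <- (av$start_bin[r] + 1L):(av$start_bin[r] + av$duration_bins[r])
      v <- s[idx]
      pairs[[length(pairs) + 1L]] <- cbind(v[-length(v)], v[-1])
    }
  }
  if (length(pairs) == 0L)
    rlang::abort("fewer than 2 valid lag pairs inside the selected epochs.")
  m <- do.call(rbind, pairs)
  xs <- m[, 1]; ys <- m[, 2]
  if (length(xs) < 2L)
    rlang::abort("fewer than 2 valid lag pairs inside the selected epochs.")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}
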