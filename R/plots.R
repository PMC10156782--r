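#' Plot a size-duration table with an optional crossover fit
#'
#' @param object A [mean_size_vs_duration()] table.
#' @param fit Optional [fit_scaling_crossover()] object to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.size_duration_table <- function(object, fit = NULL, ...) {
  g <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$duration_bins,
                                    y = .data$mean_size)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "duration L (bins)", y = "mean size <S>") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    dd <- exp(seq(log(min(object$duration_bins)),
                  log(max(object$duration_bins)), length.out = 200))
    line <- tibble::tibble(duration_bins = dd,
                           mean_size = predict(fit, dd))
    g <- g + ggplot2::geom_line(data = line, colour = "firebrick")
  }
  g
}

#' Plot a coarse-graining scan of the scaling exponents
#'
#' @param object A `chi_scan` tibble from [scan_coarse_graining()] (a
#'   `regime` column, if present, is mapped to colour).
#' @param ... Unused.
#' @return A ggplot of `chi_sh` and `chi_lg` versus `k`.
#' @export
autoplot.chi_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("k", "chi_sh", "chi_lg",
                                intersect("regime", names(object)))],
    cols = c("chi_sh", "chi_lg"), names_to = "exponent",
    values_to = "value")
  aes <- if ("regime" %in% names(object))
    ggplot2::aes(x = .data$k, y = .data$value,
                 linetype = .data$exponent, colour = .data$regime)
  else ggplot2::aes(x = .data$k, y = .data$value,
                    linetype = .data$exponent)
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 2, linetype = 3, colour = "grey50") +
    ggplot2::labs(x = "coarse-graining k", y = "scaling exponent") +
    ggplot2::theme_minimal()
}

#' Plot a complexity curve
#'
#' @param object A [complexity_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot of `C(k)` with an SD ribbon.
#' @export
autoplot.complexity_curve <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$C)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$C - .data$C_sd,
                                      ymax = .data$C + .data$C_sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "coarse-graining k",
                  y = "statistical complexity C") +
    ggplot2::theme_minimal()
}

#' Plot mean temporal profiles by duration class
#'
#' @param object An [temporal_profile()] tibble.
#' @param rescale Rescale time to `[0, 1]` per class?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.avalanche_profiles <- function(object, rescale = TRUE, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$duration_bins) |>
    dplyr::mutate(t_rel = if (rescale)
      (.data$t_index - 1) / pmax(.data$duration_bins - 1, 1)
      else .data$t_index) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_rel, y = .data$mean,
                                  colour = factor(.data$duration_bins))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (rescale) "t / L" else "bin within epoch",
                  y = "mean activity", colour = "L (bins)") +
    ggplot2::theme_minimal()
}

#' Raster plot of a spike-density raster
#'
#' @param raster A [spike_raster()].
#' @param max_cells Subsample at most this many cells for display.
#' @return A ggplot tile plot.
#' @export
plot_raster <- function(raster, max_cells = 100L) {
  stopifnot(inherits(raster, "spike_raster"))
  idx <- seq_len(min(n_cells(raster), max_cells))
  d <- as_tibble(spike_raster(raster$values[idx, , drop = FALSE],
                              raster$dt, raster$cell_ids[idx]))
  d <- d[d$value > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$cell_id,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "spikes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
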