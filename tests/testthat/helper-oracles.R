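# Independent reference implementations used as oracles. These deliberately
# use the dumbest possible algorithms so they cannot share bugs with the
# package code paths they check.

# one-pass run-length scan over a series: returns data.frame(S, L) of
# maximal positive runs not touching either end
oracle_runs <- function(x) {
  S <- numeric(0); L <- integer(0)
  cur_s <- 0; cur_l <- 0L; started_inside <- FALSE
  for (i in seq_along(x)) {
    if (x[i] > 0) {
      if (cur_l == 0L) started_inside <- i > 1L
      cur_s <- cur_s + x[i]; cur_l <- cur_l + 1L
    } else if (cur_l > 0L) {
      if (started_inside) { S <- c(S, cur_s); L <- c(L, cur_l) }
      cur_s <- 0; cur_l <- 0L
    }
  }
  # a run still open at the series end touches the boundary: dropped
  data.frame(S = S, L = L)
}

# sample n draws from a discrete power law p(x) ~ x^-alpha on [x_min, x_max]
oracle_rpowerlaw_discrete <- function(n, alpha, x_min, x_max) {
  supp <- x_min:x_max
  sample(supp, n, replace = TRUE, prob = supp^(-alpha))
}

# numerically maximise the Jensen-Shannon bracket over the n-simplex by
# optimising over softmax-parameterised distributions from many starts
oracle_max_js <- function(n, n_starts = 20, seed = 99) {
  set.seed(seed)
  S <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pe <- rep(1 / n, n)
  js <- function(theta) {
    p <- exp(theta) / sum(exp(theta))
    -(S((p + pe) / 2) - S(p) / 2 - S(pe) / 2)
  }
  best <- -Inf
  for (s in seq_len(n_starts)) {
    th0 <- stats::rnorm(n, sd = 4)
    o <- stats::optim(th0, js, method = "BFGS",
                      control = list(maxit = 500))
    best <- max(best, -o$value)
  }
  best
}

# Poisson toy raster with a planted fraction of cells that ignore the
# shared drive (for planted-truth recovery of uncorrelated-cell removal)
planted_uncorrelated_raster <- function(n_corr, n_indep, n_bins,
                                        rate = 0.5, gain_sd = 1.2,
                                        seed = 1) {
  set.seed(seed)
  gain <- exp(gain_sd * stats::rnorm(n_bins) - gain_sd^2 / 2)
  v_corr <- matrix(stats::rpois(n_corr * n_bins, rate * rep(gain, each = n_corr)),
                   n_corr, n_bins)
  v_ind <- matrix(stats::rpois(n_indep * n_bins, rate), n_indep, n_bins)
  spike_raster(rbind(v_corr, v_ind), dt = 0.022,
               cell_ids = c(paste0("corr_", seq_len(n_corr)),
                            paste0("ind_", seq_len(n_indep))))
}
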