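#' Parameters of the balanced E/I probabilistic integrate-and-fire network
#'
#' The network has `N` all-to-all connected non-leaky probabilistic
#' integrate-and-fire neurons, a fraction `frac_E` excitatory. Excitatory
#' presynaptic weights are `J`, inhibitory ones `-g * J`. Membrane potential
#' evolves as `V(t+1) = (mu * V(t) + sum_j W_ij X_j(t)) * (1 - X_i(t))`; the
#' `(1 - X)` factor resets the potential after a spike and acts as an
#' absolute refractory period. A neuron fires with probability
#' `clamp(Gamma * V, 0, 1)`, and an external Poisson drive activates each
#' quiescent neuron with probability `lam` per step.
#'
#' The default `J = 10 / N` places the balance parameter's critical value at
#' `g_c = 3.5`: the mean-field branching ratio is
#' `N * J * Gamma * (frac_E - (1 - frac_E) * g)`, which equals 1 at
#' `g = 3.5` for these defaults. `g > g_c` yields inhibition-dominated,
#' subcritical cascades. The default drive `lam = 20 / N` activates ~20
#' neurons per step regardless of `N`.
#'
#' @param N Number of neurons.
#' @param frac_E Excitatory fraction (0 < frac_E < 1).
#' @param J Excitatory synaptic weight (> 0).
#' @param g Inhibition balance scalar (>= 0); 3.5 is critical, 3.75 weakly
#'   subcritical for the default gain and weights.
#' @param Gamma Neuronal gain.
#' @param mu Leakage parameter; the studied regime is `mu = 0`.
#' @param lam Per-neuron, per-step external activation probability.
#' @param T Number of simulation steps (after burn-in).
#' @param burn_in Steps discarded before statistics are collected.
#' @param seed Optional integer seed.
#' @return A list of class `ei_network_params`.
#' @export
ei_network_params <- function(N = 1e6, frac_E = 0.8, J = 10 / N, g = 3.5,
                              Gamma = 1, mu = 0, lam = 20 / N,
                              T = 1e5, burn_in = 1e4, seed = NULL) {
  stopifnot(N >= 2, frac_E > 0, frac_E < 1, J > 0, g >= 0, Gamma > 0,
            mu >= 0, lam >= 0, lam <= 1, T >= 1, burn_in >= 0)
  structure(
    list(N = N, frac_E = frac_E, J = J, g = g, Gamma = Gamma, mu = mu,
         lam = lam, T = as.integer(T), burn_in = as.integer(burn_in),
         seed = seed),
    class = "ei_network_params"
  )
}

#' @export
print.ei_network_params <- function(x, ...) {
  sigma <- x$N * x$J * x$Gamma * (x$frac_E - (1 - x$frac_E) * x$g)
  cat(sprintf(
    "<ei_network_params> N = %g (%.0f%% E), J = %g, g = %g, Gamma = %g, mu = %g\n  drive lam = %g (%.3g spikes/step), T = %d (+%d burn-in)\n  mean-field branching ratio: %.4g\n",
    x$N, 100 * x$frac_E, x$J, x$g, x$Gamma, x$mu, x$lam, x$lam * x$N,
    x$T, x$burn_in, sigma))
  invisible(x)
}

#' Simulate the balanced E/I network under subsampled observation
#'
#' Runs the network and observes a random fraction `f` of its neurons. Two
#' engines are available. The `"cohort"` engine exploits the uniform
#' all-to-all weights: with `mu = 0` every non-refractory neuron carries the
#' identical membrane potential, so the whole population reduces to
#' aggregate counts with binomially distributed per-step firing, and one
#' step costs O(1) in `N` (a million neurons run as fast as a hundred). The
#' `"naive"` engine keeps per-neuron state and is the reference
#' implementation (use it for `mu > 0` or for small networks); both engines
#' produce draws from the same process distribution.
#'
#' @param params An [ei_network_params()] object.
#' @param f Sampling fraction in (0, 1], or use `n_tracked`.
#' @param n_tracked Alternative to `f`: the number of observed neurons.
#' @param engine `"cohort"` (default) or `"naive"`.
#' @param drive `"activate"` (default): the external drive sets a quiescent
#'   neuron firing outright with probability `lam` per step. `"voltage"`:
#'   the drive instead adds `drive_kick` to the membrane potential with
#'   probability `lam`, so activation passes through the gain function one
#'   step later (naive engine only).
#' @param drive_kick Potential increment of the `"voltage"` drive.
#' @param record_raster Keep the per-neuron binary raster of the tracked
#'   subset? (Memory is `n_tracked * T` bytes; leave off for long runs when
#'   only population counts are needed.)
#' @param seed Optional integer seed (overrides `params$seed`).
#' @return An object of class `ei_sim`: list with `counts` (tibble `step`,
#'   `n_e`, `n_i`, `n_sampled`, burn-in discarded), `raster` (a
#'   [spike_raster()] of the tracked subset with `dt = 1` step, or `NULL`),
#'   `f`, `n_tracked`, `params`.
#' @examples
#' pars <- ei_network_params(N = 2000, T = 2000, burn_in = 200)
#' sim <- simulate_ei_network(pars, f = 0.5, seed = 1)
#' branching_ratio(sim)
#' @export
simulate_ei_network <- function(params, f = 1, n_tracked = NULL,
                                engine = c("cohort", "naive"),
                                record_raster = FALSE, seed = NULL,
                                drive = c("activate", "voltage"),
                                drive_kick = 1) {
  stopifnot(inherits(params, "ei_network_params"))
  engine <- rlang::arg_match(engine)
  drive <- rlang::arg_match(drive)
  seed <- if (!is.null(seed)) seed else params$seed
  if (!is.null(seed)) set.seed(seed)

  N <- params$N
  NE <- round(params$frac_E * N); NI <- N - NE
  if (is.null(n_tracked)) {
    stopifnot(f > 0, f <= 1)
    n_tracked <- max(1L, round(f * N))
  }
  n_tracked <- as.integer(n_tracked)
  stopifnot(n_tracked >= 1L, n_tracked <= N)
  f <- n_tracked / N
  trE <- round(params$frac_E * n_tracked); trI <- n_tracked - trE
  Ttot <- params$T + params$burn_in

  if (engine == "cohort") {
    if (params$mu != 0)
      rlang::abort("the cohort engine requires mu = 0; use engine = 'naive'.")
    if (drive != "activate")
      rlang::abort("the voltage drive is only available in the naive engine.")
    raw <- .ei_cohort_engine(NE, NI, params$J, params$g, params$Gamma,
                             params$lam, Ttot, trE, trI, record_raster)
  } else {
    raw <- ei_naive_engine(NE, NI, params$J, params$g, params$Gamma,
                           params$mu, params$lam, Ttot, trE, trI,
                           record_raster, drive, drive_kick)
  }

  keep <- (params$burn_in + 1L):Ttot
  counts <- tibble::tibble(
    step = seq_along(keep),
    n_e = raw$n_e[keep],
    n_i = raw$n_i[keep],
    n_sampled = raw$n_sampled[keep]
  )
  raster <- NULL
  if (record_raster) {
    m <- raw$raster
    vals <- matrix(as.integer(m), nrow = nrow(m))[, keep, drop = FALSE]
    raster <- spike_raster(
      vals, dt = 1,
      cell_ids = paste0("n_", seq_len(n_tracked)),
      cell_type = rep(c("E", "I"), c(trE, trI))
    )
  }
  structure(
    list(counts = counts, raster = raster, f = f, n_tracked = n_tracked,
         params = params),
    class = "ei_sim"
  )
}

# Reference per-neuron engine (R). Handles mu >= 0. Intended for N up to
# ~1e4; the first trE + trI neurons (E block then I block) are the tracked
# subset.
ei_naive_engine <- function(NE, NI, J, g, Gamma, mu, lam, Ttot, trE, trI,
                            record_raster, drive = "activate",
                            drive_kick = 1) {
  N <- NE + NI
  # order: tracked E, untracked E, tracked I, untracked I
  is_E <- c(rep(TRUE, NE), rep(FALSE, NI))
  tracked <- c(rep(TRUE, trE), rep(FALSE, NE - trE),
               rep(TRUE, trI), rep(FALSE, NI - trI))
  V <- numeric(N)
  X <- integer(N)
  n_e <- integer(Ttot); n_i <- integer(Ttot); n_s <- integer(Ttot)
  ntr <- trE + trI
  raster <- if (record_raster) matrix(0L, ntr, Ttot) else NULL
  tr_idx <- which(tracked)
  for (t in seq_len(Ttot)) {
    input <- J * (sum(X[is_E]) - g * sum(X[!is_E]))
    V <- (mu * V + input) * (1 - X)
    if (drive == "voltage")
      V <- V + drive_kick * (X == 0L) * (stats::runif(N) < lam)
    q <- pmin(pmax(Gamma * V, 0), 1)
    pfire <- if (drive == "activate") {
      ifelse(X == 1L, 0, lam + (1 - lam) * q)
    } else {
      ifelse(X == 1L, 0, q)
    }
    X <- as.integer(stats::runif(N) < pfire)
    n_e[t] <- sum(X[is_E]); n_i[t] <- sum(X[!is_E])
    n_s[t] <- sum(X[tr_idx])
    if (record_raster) raster[, t] <- X[tr_idx]
  }
  list(n_e = n_e, n_i = n_i, n_sampled = n_s, raster = raster)
}

#' @export
print.ei_sim <- function(x, ...) {
  rate <- mean(x$counts$n_e + x$counts$n_i) / x$params$N * 1000
  cat(sprintf(
    "<ei_sim> N = %g, g = %g, %d steps; tracked %d neurons (f = %.3g%%)\n  firing rate: %.3g spikes / 1000 steps / neuron\n",
    x$params$N, x$params$g, nrow(x$counts), x$n_tracked, 100 * x$f, rate))
  invisible(x)
}

#' Per-neuron firing rate of a simulation
#'
#' @param sim An `ei_sim` object.
#' @param per Report spikes per this many time steps (default 1000).
#' @return Spikes per `per` steps per neuron, across the whole network.
#' @export
firing_rate <- function(sim, per = 1000) {
  stopifnot(inherits(sim, "ei_sim"))
  mean(sim$counts$n_e + sim$counts$n_i) / sim$params$N * per
}

#' Empirical branching ratio of a simulation
#'
#' Estimates the expected number of descendant spikes per spike as the
#' through-origin regression slope of the drive-corrected next-step count on
#' the current count, over steps with nonzero activity:
#' `sigma = sum(n_t * (n_{t+1} - drive)) / sum(n_t^2)`, where `drive` is the
#' expected number of externally driven spikes per step. At the balance
#' point (`g = 3.5` for the default weights) the estimate is close to 1;
#' larger `g` gives values below 1.
#'
#' @param sim An `ei_sim` object.
#' @param max_count Use only steps with at most this many spikes. Strongly
#'   supercritical networks saturate (refractoriness and the firing-
#'   probability clamp cap the activity), which drags the regression slope
#'   below the true branching ratio; capping the regressor to the linear
#'   regime avoids that.
#' @return The branching-ratio estimate (a single number).
#' @export
branching_ratio <- function(sim, max_count = Inf) {
  stopifnot(inherits(sim, "ei_sim"))
  n <- sim$counts$n_e + sim$counts$n_i
  if (length(n) < 2L || all(n == 0))
    rlang::abort("no active steps: cannot estimate a branching ratio.")
  n0 <- n[-length(n)]; n1 <- n[-1]
  act <- n0 > 0 & n0 <= max_count
  if (!any(act)) rlang::abort("no active steps with successors.")
  drive <- sim$params$lam * sim$params$N
  sum(n0[act] * (n1[act] - drive)) / sum(n0[act]^2)
}

#' Baseline population threshold from the expected external drive
#'
#' Returns the expected number of externally driven spikes per time step
#' within the observed (tracked) population, `f * N * lam`. Thresholding the
#' sampled population activity above this baseline focuses the epoch
#' extraction on actual cascading activity rather than the drive itself;
#' any analysis threshold should be at least this value. For strongly
#' subsampled observation the baseline falls below one spike and the
#' practical minimum becomes `theta = 1`, i.e. at least two coincident
#' spikes per bin.
#'
#' @param sim An `ei_sim` object.
#' @return The baseline threshold, in spikes per time step.
#' @export
drive_threshold <- function(sim) {
  stopifnot(inherits(sim, "ei_sim"))
  sim$f * sim$params$N * sim$params$lam
}

#' Sampled population activity of a simulation
#'
#' @param sim An `ei_sim` object.
#' @param population Use the full-network counts instead of the tracked
#'   subset?
#' @return A population-activity tibble as from [population_activity()]
#'   (`dt` = 1 time step).
#' @export
sampled_activity <- function(sim, population = FALSE) {
  stopifnot(inherits(sim, "ei_sim"))
  p <- if (population) sim$counts$n_e + sim$counts$n_i else
    sim$counts$n_sampled
  out <- tibble::tibble(
    bin = seq_along(p) - 1L,
    time = as.numeric(seq_along(p) - 1L),
    activity = as.numeric(p)
  )
  attr(out, "dt") <- 1
  out
}
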