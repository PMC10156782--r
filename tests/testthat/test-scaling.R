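test_that("the MLE recovers a known discrete power-law exponent", {
  set.seed(91)
  x <- oracle_rpowerlaw_discrete(1e5, 1.5, 1, 1000)
  fit <- fit_powerlaw_exponent(x, x_min = 1, x_max = 1000)
  expect_equal(fit$exponent, 1.5, tolerance = 0.03)
  expect_equal(fit$estimator, "discrete_mle")
  expect_lt(fit$se, 0.02)

  y <- oracle_rpowerlaw_discrete(5e4, 2.2, 2, 500)
  expect_equal(fit_powerlaw_exponent(y, 2, 500)$exponent, 2.2,
               tolerance = 0.05)
})

test_that("degenerate samples are rejected", {
  expect_error(fit_powerlaw_exponent(rep(7, 500)), "degenerate")
  expect_error(fit_powerlaw_exponent(1:20, x_min = 1, x_max = 20),
               "need >=")
})

test_that("cutoff detection finds a planted truncation", {
  set.seed(92)
  # power law truncated by an exponential shoulder at ~300
  x <- oracle_rpowerlaw_discrete(2e5, 1.5, 1, 5000)
  x <- x[x <= 300 | runif(length(x)) < exp(-(x - 300) / 30)]
  cut <- detect_cutoff(x)
  expect_gt(cut, 150)
  expect_lt(cut, 600)
  # an untruncated sample keeps (nearly) its full range
  y <- oracle_rpowerlaw_discrete(2e4, 1.8, 1, 3000)
  expect_gt(detect_cutoff(y), quantile(y, 0.99))
})

test_that("mean size per duration is a plain group average", {
  av <- tibble::tibble(k = 1L, offset = 0L, start_bin = 0L,
                       duration_bins = c(1L, 1L, 2L),
                       size = c(2, 4, 9),
                       duration_seconds = c(1, 1, 2))
  tb <- mean_size_vs_duration(av)
  expect_equal(tb$mean_size, c(3, 9))
  expect_equal(tb$n, c(2L, 1L))
})

test_that("crossover fit recovers noiseless parameters to 1e-3", {
  d <- unique(round(exp(seq(log(1), log(500), length.out = 60))))
  truth <- list(C = 1, chi_sh = 2, chi_lg = 1, Phi = 50, gamma = 4)
  S <- truth$C * d^truth$chi_sh /
    (1 + (d / truth$Phi)^4)^((truth$chi_sh + truth$chi_lg) / 4)
  tb <- tibble::tibble(duration_bins = d, mean_size = S)
  fit <- fit_scaling_crossover(tb)
  expect_equal(fit$chi_sh, 2, tolerance = 1e-3)
  expect_equal(fit$chi_lg, 1, tolerance = 1e-3)
  expect_equal(fit$Phi, 50, tolerance = 0.05)
  expect_equal(fit$C, 1, tolerance = 1e-3)
  expect_equal(predict(fit, d), S, tolerance = 1e-3)
})

test_that("a pure power law yields chi_sh at the single slope", {
  d <- 1:30
  tb <- tibble::tibble(duration_bins = d, mean_size = d^1.5)
  fit <- fit_scaling_crossover(tb)
  expect_equal(fit$chi_sh, 1.5, tolerance = 0.02)
  expect_gt(fit$Phi, max(d) * 0.9)  # crossover pushed beyond the data
})

test_that("chi estimates ignore a uniform rescaling of sizes", {
  d <- unique(round(exp(seq(log(1), log(300), length.out = 40))))
  S <- 2 * d^2 / (1 + (d / 30)^4)^(3 / 4)
  f1 <- fit_scaling_crossover(tibble::tibble(duration_bins = d,
                                             mean_size = S))
  f2 <- fit_scaling_crossover(tibble::tibble(duration_bins = d,
                                             mean_size = 17 * S))
  expect_equal(f1$chi_sh, f2$chi_sh, tolerance = 1e-6)
  expect_equal(f1$chi_lg, f2$chi_lg, tolerance = 1e-6)
  expect_equal(f2$C / f1$C, 17, tolerance = 1e-4)
})

test_that("crossover parameters are recovered under noise without bias", {
  set.seed(93)
  for (pars in list(c(sh = 2, lg = 1, Phi = 30),
                    c(sh = 1.5, lg = 0.5, Phi = 60))) {
    d <- unique(round(exp(seq(log(1), log(400), length.out = 50))))
    S0 <- d^pars["sh"] / (1 + (d / pars["Phi"])^4)^((pars["sh"] + pars["lg"]) / 4)
    ests <- replicate(8, {
      S <- S0 * exp(rnorm(length(d), 0, 0.05))
      ft <- fit_scaling_crossover(tibble::tibble(duration_bins = d,
                                                 mean_size = S))
      c(ft$chi_sh, ft$chi_lg)
    })
    expect_equal(mean(ests[1, ]), unname(pars["sh"]), tolerance = 0.05)
    expect_equal(mean(ests[2, ]), unname(pars["lg"]), tolerance = 0.15)
  }
})

test_that("simple two-range slopes behave on constructed tables", {
  d <- 1:20
  tb <- tibble::tibble(duration_bins = d, mean_size = d^2)
  cs <- chi_simple(tb)
  expect_equal(cs$chi_sh, 2, tolerance = 1e-9)
  expect_equal(cs$chi_lg, 2, tolerance = 1e-9)

  lin <- tibble::tibble(duration_bins = 10:40, mean_size = (10:40)^1)
  expect_equal(chi_simple(lin)$chi_lg, 1, tolerance = 1e-9)
  expect_true(is.na(chi_simple(lin)$chi_sh))  # empty short range

  # sharp piecewise power law: simple slopes match the generating pieces
  dd <- 1:60
  Sv <- ifelse(dd <= 7, dd^2, 7^2 * (dd / 7)^1)
  pw <- chi_simple(tibble::tibble(duration_bins = dd, mean_size = Sv))
  expect_equal(pw$chi_sh, 2, tolerance = 1e-6)
  expect_equal(pw$chi_lg, 1, tolerance = 1e-6)
})

test_that("bootstrap pools keep their size and degenerate pools give SD 0", {
  av <- tibble::tibble(k = 1L, offset = 0L, start_bin = seq_len(300),
                       duration_bins = rep(c(1L, 2L, 4L, 8L), 75),
                       size = rep(c(2, 8, 32, 128), 75),
                       duration_seconds = rep(c(1, 2, 4, 8), 75))
  bs <- bootstrap_scaling(av, n_reps = 5, method = "simple", seed = 1,
                          short_range = c(1, 8), long_range = c(2, 8))
  expect_equal(bs$sd$chi_sh_sd, 0, tolerance = 1e-9)
  expect_equal(nrow(bs$replicates), 5L)
})

test_that("bootstrap spread shrinks roughly like 1/sqrt(pool size)", {
  set.seed(94)
  mk <- function(n) {
    L <- sample(1:30, n, replace = TRUE, prob = (1:30)^-1.5)
    tibble::tibble(k = 1L, offset = 0L, start_bin = seq_len(n),
                   duration_bins = as.integer(L),
                   size = L^2 * exp(rnorm(n, 0, 0.6)),
                   duration_seconds = as.numeric(L))
  }
  sd_small <- bootstrap_scaling(mk(300), n_reps = 10, method = "simple",
                                seed = 2)$sd$chi_sh_sd
  sd_big <- bootstrap_scaling(mk(4800), n_reps = 10, method = "simple",
                              seed = 3)$sd$chi_sh_sd
  expect_lt(sd_big, sd_small)
  expect_equal(sd_small / sd_big, 4, tolerance = 2.5)
})

test_that("the exponent relation evaluates and guards its singularity", {
  expect_equal(exponent_relation(1.5, 2)$value, 2)
  expect_equal(exponent_relation(2, 2)$value, 1)
  expect_true(exponent_relation(1.01, 2)$unstable)
  expect_false(exponent_relation(1.5, 2)$unstable)
  expect_error(exponent_relation(1, 2), "singular")
})
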