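test_that("hard and soft thresholds follow their defining rules", {
  p <- c(0, 3, 1, 0, 5)
  expect_equal(as.numeric(apply_threshold(p, 1, "hard")), c(0, 3, 0, 0, 5))
  expect_equal(as.numeric(apply_threshold(p, 1, "soft")), c(0, 2, 0, 0, 4))
  # theta = 0 keeps every strictly positive bin unchanged
  expect_equal(as.numeric(apply_threshold(p, 0, "hard")), p)
  # integer counts with theta = 1: only bins with >= 2 spikes survive
  counts <- c(1, 2, 0, 3, 1, 1, 4)
  thr <- as.numeric(apply_threshold(counts, 1, "hard"))
  expect_identical(thr > 0, counts >= 2)
  # scalar brute-force cross-check of both rules
  set.seed(51)
  x <- rpois(200, 2)
  th <- 1.5
  hard <- vapply(x, function(v) if (v > th) v else 0, numeric(1))
  soft <- vapply(x, function(v) if (v > th) v - th else 0, numeric(1))
  expect_equal(as.numeric(apply_threshold(x, th, "hard")), hard)
  expect_equal(as.numeric(apply_threshold(x, th, "soft")), soft)
})

test_that("soft-mode sizes never exceed hard-mode sizes", {
  set.seed(52)
  x <- rpois(500, 1.2)
  for (th in c(0, 1, 2)) {
    hard <- detect_avalanches(x, k = 1, theta = th, mode = "hard")
    soft <- detect_avalanches(x, k = 1, theta = th, mode = "soft")
    expect_equal(nrow(hard), nrow(soft))
    if (th == 0) expect_equal(soft$size, hard$size)
    else expect_true(all(soft$size < hard$size))
  }
})

test_that("coarse-graining sums complete windows at every offset", {
  p <- c(1, 2, 3, 4)
  ens <- coarse_grain(p, 2)
  expect_equal(ens[[1]], c(3, 7))
  expect_equal(ens[[2]], 5)  # trailing incomplete window dropped
  expect_equal(coarse_grain(p, 1)[[1]], p)
  expect_error(coarse_grain(p, 5), "exceeds")

  set.seed(53)
  x <- rpois(101, 3)
  for (k in c(2, 3, 7)) {
    ens <- coarse_grain(x, k)
    expect_length(ens, k)
    for (j in seq_len(k)) {
      expect_lte(sum(ens[[j]]), sum(x))
      if ((length(x) - (j - 1)) %% k == 0)
        expect_equal(sum(ens[[j]]), sum(x) - sum(head(x, j - 1)))
    }
  }
})

test_that("epoch extraction matches an independent one-pass oracle", {
  expect_equal(nrow(extract_avalanches(rep(0, 50))), 0L)
  av <- extract_avalanches(c(0, 2, 3, 0))
  expect_equal(av$size, 5)
  expect_equal(av$duration_bins, 2L)

  set.seed(54)
  x <- rpois(10000, 0.4) * rbinom(10000, 1, 0.5)
  got <- extract_avalanches(x)
  ref <- oracle_runs(x)
  expect_equal(nrow(got), nrow(ref))
  expect_equal(sort(got$size), sort(ref$S))
  expect_equal(sort(got$duration_bins), sort(ref$L))
})

test_that("epochs touching the recording boundary are discarded", {
  x <- c(2, 1, 0, 3, 0, 0, 4, 4)
  av <- extract_avalanches(x)
  expect_equal(nrow(av), 1L)
  expect_equal(av$size, 3)
})

test_that("interior suprathreshold mass is conserved by extraction", {
  set.seed(55)
  x <- c(0, rpois(2000, 0.7), 0)  # zero-padded: no boundary losses
  av <- extract_avalanches(x)
  expect_equal(sum(av$size), sum(x))
})

test_that("duration follows the bracketing-zeros formula", {
  # zeros at tau1 = 0 and tau2 = 3 bracket a run of length tau2 - tau1 - 1
  x <- c(0, 2, 3, 0)
  expect_equal(extract_avalanches(x)$duration_bins, 3L - 0L - 1L)
})

test_that("two epochs split by one subthreshold bin merge at k = 2", {
  p <- c(0, 0, 0, 3, 4, 0, 5, 2, 0, 0, 0, 0)
  before <- extract_avalanches(as.numeric(apply_threshold(p, 0)))
  expect_equal(nrow(before), 2L)
  merged <- vapply(coarse_grain(apply_threshold(p, 0), 2), function(s) {
    nrow(extract_avalanches(s)) == 1L &&
      all(extract_avalanches(s)$size == sum(p))
  }, logical(1))
  expect_true(all(merged))
})

test_that("detection pools all offsets and is deterministic", {
  r <- make_toy_raster(10, 60, background_rate = 0,
                       planted_epochs = data.frame(start_bin = 20,
                                                   duration = 6,
                                                   amplitude = 40),
                       seed = 56)
  p <- population_activity(r)
  av <- detect_avalanches(p, k = 2, theta = 0)
  expect_equal(nrow(av), 2L)          # one epoch per offset
  # the aligned offset splits the 6-bin epoch into 3 windows; the other
  # covers it with 4 (two edge windows are partially filled)
  expect_setequal(av$duration_bins, c(3L, 4L))
  expect_equal(av$size[1], av$size[2])
  expect_identical(detect_avalanches(p, k = 2, theta = 0), av)
  # k = 1 has a single offset
  expect_equal(unique(detect_avalanches(p, k = 1, theta = 0)$offset), 0L)
})

test_that("avalanche count decreases with threshold beyond the count peak", {
  # N(theta) is unimodal (log-normal shaped): raising theta on the
  # descending limb can only remove epochs
  set.seed(57)
  x <- rpois(5000, 2)
  counts <- vapply(c(3, 4, 6, 8), function(th)
    nrow(detect_avalanches(x, k = 1, theta = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[4], counts[1])
})

test_that("threshold selection recovers planted log-normal shape", {
  # N(theta) generated exactly from a scaled log-normal density + 1% noise
  set.seed(58)
  grid <- exp(seq(log(0.5), log(60), length.out = 80))
  mu <- 2; sigma <- 0.5
  n_ep <- 5000 * dlnorm(grid, mu, sigma)
  n_ep <- n_ep * (1 + 0.01 * rnorm(length(grid)))
  fit <- avalanchr:::fit_lognormal_curve(
    tibble::tibble(theta = grid, n_epochs = n_ep))
  expect_equal(unname(fit[["mu"]]), mu, tolerance = 0.05)
  expect_equal(unname(fit[["sigma"]]), sigma, tolerance = 0.05)
})

test_that("threshold grid endpoints behave as specified", {
  set.seed(59)
  r <- make_toy_raster(30, 3000, background_rate = 0.2, correlation = 1,
                       seed = 59)
  p <- population_activity(r)
  sel <- select_threshold(p, k = 1)
  expect_s3_class(sel, "threshold_selection")
  n0 <- nrow(detect_avalanches(p, k = 1, theta = 0))
  expect_equal(sel$curve$n_epochs[1], n0)
  expect_equal(sel$curve$n_epochs[nrow(sel$curve)], 0)
  expect_gt(sel$theta_star, 0)
})

test_that("selected threshold scales with the activity scale", {
  set.seed(60)
  r <- make_toy_raster(30, 4000, background_rate = 0.3, correlation = 1,
                       seed = 61)
  p <- population_activity(r)$activity
  t1 <- select_threshold(p, k = 1)$theta_star
  t3 <- select_threshold(3 * p, k = 1)$theta_star
  expect_equal(t3 / t1, 3, tolerance = 0.25)
})
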