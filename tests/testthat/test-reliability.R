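test_that("kernel smoothing matches a brute-force Gaussian oracle", {
  t <- sort(runif(40, 100, 900))
  tr <- kernel_smooth(t, 4, 1000, 2500)
  grid <- (0:2499) / 2500 * 1000
  oracle <- numeric(2500)
  for (s in t) oracle <- oracle + dnorm(grid - s, 0, 4)
  expect_lt(max(abs(tr - oracle)), 1e-8)
  # single spike: argmax at the spike, integral equals the count
  one <- kernel_smooth(500, 4, 1000, 2500)
  expect_equal(grid[which.max(one)], 500, tolerance = 0.4)
  expect_lt(abs(sum(tr) * (1000 / 2500) / length(t) - 1), 1e-6)
  expect_identical(kernel_smooth(numeric(0), 4, 1000), numeric(2500))
})

test_that("clone trials give a flat unit profile with the smallest-sigma tie rule", {
  t <- sort(runif(30, 50, 950))
  st <- spike_trains(rep(list(t), 6), 1000, unit_id = "clone")
  rel <- reliability_profile(st, focused = FALSE)
  expect_true(all(abs(rel$profile$r_mean - 1) < 1e-9))
  expect_identical(rel$Rp, 0.4)
  expect_identical(rel$coder_class, "rate")
  expect_lt(rel$consistency_p, 0.05)
})

test_that("pair bookkeeping counts all trial pairs and skips empty trials", {
  st <- locked_unit(seed = 12)
  rel <- reliability_profile(st, focused = FALSE)
  expect_true(all(rel$profile$n_pairs == choose(st$n_trials, 2)))
  # with an empty trial, its pairs are skipped and counted
  trials <- st$trials; trials[[3]] <- numeric(0)
  st2 <- spike_trains(trials, 1000)
  rel2 <- reliability_profile(st2, focused = FALSE)
  expect_true(all(rel2$profile$n_skipped == st$n_trials - 1))
  expect_true(all(rel2$profile$n_pairs == choose(st$n_trials, 2) -
                    (st$n_trials - 1)))
})

test_that("profile value at a coarse sigma equals the direct pairwise oracle", {
  st <- locked_unit(seed = 13)
  rel <- reliability_profile(st, focused = FALSE)
  sig <- 102.4
  M <- sapply(st$trials, function(t) kernel_smooth(t, sig, 1000, 2500,
                                                   edge_correct = TRUE))
  cc <- cor(apply(M, 2, rank))
  oracle <- mean(cc[upper.tri(cc)])
  expect_equal(rel$profile$r_mean[rel$profile$sigma_ms == sig], oracle,
               tolerance = 1e-10)
})

test_that("canonical regimes classify as expected", {
  x <- fixture_signal()
  # shared slow background noise: monotonically increasing profile
  stI <- simulate_unit(quadrant_config("I", seed = 5), x)
  relI <- reliability_profile(stI)
  expect_identical(relI$coder_class, "rate")
  # sparse jittered signal with heavy add/remove: interior peak
  stF <- simulate_unit(quadrant_config("F", seed = 5), x)
  relF <- reliability_profile(stF)
  expect_identical(relF$coder_class, "temporal")
  expect_lt(relF$timescale_ms, relI$timescale_ms)
})

test_that("the coder decision table follows the consistency rules", {
  make_profile <- function(r_means, noise_sd = 0.02, n_pairs = 45,
                           seed = 1) {
    set.seed(seed)
    res <- lapply(r_means, function(m) {
      v <- pmin(pmax(rnorm(n_pairs, m, noise_sd), -1), 1)
      list(r_pairs = v, r_mean = mean(v),
           r_sem = sd(v) / sqrt(n_pairs), n_pairs = n_pairs,
           n_skipped = 0L)
    })
    sig <- coarse_deltas()[seq_along(r_means)]
    profile <- tibble::tibble(
      sigma_ms = sig,
      r_mean = vapply(res, function(p) p$r_mean, numeric(1)),
      r_sem = vapply(res, function(p) p$r_sem, numeric(1)),
      n_pairs = n_pairs, n_skipped = 0L, stage = "coarse")
    structure(list(unit_id = "synthetic", profile = profile,
                   sigma_grid = sig,
                   r_pairs = lapply(res, function(p) p$r_pairs)),
              class = "reliability_profile")
  }
  # strictly increasing: rate
  expect_identical(
    classify_coder(make_profile(seq(0.1, 0.9, length.out = 9))), "rate")
  # strong interior peak: temporal, even with a higher end value
  expect_identical(
    classify_coder(make_profile(c(0.1, 0.3, 0.7, 0.3, 0.2, 0.2, 0.3, 0.5,
                                  0.9))), "temporal")
  # monotonically decreasing: reliability is maximal at the finest
  # timescale, i.e. a temporal coder
  expect_identical(
    classify_coder(make_profile(c(0.5, 0.45, 0.4, 0.35, 0.3, 0.25, 0.2,
                                  0.15, 0.1))), "temporal")
  # an initial consistent drop, then a rise to the global maximum at the
  # largest sigma: neither monotone-rate nor interior-peaked
  expect_identical(
    classify_coder(make_profile(c(0.5, 0.3, 0.35, 0.4, 0.45, 0.5, 0.55,
                                  0.6, 0.65), noise_sd = 0.005)),
    "undefined")
  # interior wiggle within noise, max at the end: rate
  expect_identical(
    classify_coder(make_profile(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8,
                                  0.9) + c(0, 0, 0.001, -0.001, 0, 0, 0, 0, 0),
                                noise_sd = 0.2, seed = 3)), "rate")
  expect_error(classify_coder(make_profile(c(0.1, 0.2))),
               class = "spikecoder_invalid_parameter")
})
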