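test_that("rate profiles follow the kernel-filtered stimulus", {
  z <- spikecoder:::analysis_signal(fixture_signal(), 2500)
  expect_error(rate_from_signal(fixture_signal()),
               class = "spikecoder_invalid_parameter")  # not standardized
  zero <- z; zero$samples <- rep(0, 2500)
  zero$samples <- zero$samples  # constant zero: mean 0, scaling skipped
  expect_true(all(rate_from_signal(zero, 100, 50) == 0))
  r <- rate_from_signal(z, 100, 40)
  expect_true(all(r >= 0))
  expect_equal(mean(r), 40, tolerance = 1e-9)
  # kernel length: one full cycle of 100 Hz at 2500 Hz is 25 samples
  expect_equal(max(2L, round(2500 / 100)), 25)
})

test_that("rate convolution matches an explicit loop oracle on a sinusoid", {
  fs <- 2500
  t <- (0:(fs - 1)) / fs
  s <- sin(2 * pi * 100 * t)
  x <- spikecoder:::new_wn_signal(s / stats::sd(s), fs, 1, 3, 1,
                                  standardized = TRUE)
  x$samples <- x$samples - mean(x$samples)
  r <- rate_from_signal(x, 100, 10)
  # oracle: direct "same" convolution with the single-cycle sine kernel
  len <- 25
  kern <- sin(2 * pi * (0:(len - 1)) / len)
  n <- length(x$samples)
  oracle <- numeric(n)
  centre <- (len + 1) %/% 2
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(len)) {
      idx <- i + centre - j
      if (idx >= 1 && idx <= n) acc <- acc + kern[j] * x$samples[idx]
    }
    oracle[i] <- acc
  }
  oracle[oracle < 0] <- 0
  oracle <- oracle * 10 / mean(oracle)
  expect_equal(r, oracle, tolerance = 1e-10)
})

test_that("Bernoulli sampling respects rate and refractoriness", {
  expect_identical(sample_poisson_train(rep(0, 1000), 2500), numeric(0))
  lam <- 20; T_s <- 100
  tr <- sample_poisson_train(rep(lam, 2500 * T_s), 2500, min_isi_ms = 0,
                             seed = 5)
  expect_lt(abs(length(tr) - lam * T_s), 4 * sqrt(lam * T_s))
  tr2 <- sample_poisson_train(rep(200, 2500), 2500, min_isi_ms = 2, seed = 5)
  expect_gte(min(diff(tr2)), 2)
  expect_warning(sample_poisson_train(rep(5000, 100), 2500), "clipped")
})

test_that("daughter trains are modified copies with bounded counts", {
  mother <- sort(runif(40, 100, 900))
  # identity when nothing is perturbed
  d0 <- make_daughter_trains(mother, 5, 0, 0, 0, 1000, seed = 1)
  for (d in d0) expect_identical(d, mother)
  # count bookkeeping over many seeds
  counts <- unlist(lapply(1:200, function(sd) {
    lengths(make_daughter_trains(mother, 5, 0, 3, 3, 1000, seed = sd))
  }))
  expect_true(all(counts >= length(mother) - 3 & counts <= length(mother) + 3))
  # half-normal displacement oracle for Gaussian jitter; mother spikes
  # spaced far beyond the jitter scale so sorting cannot re-pair them
  m2 <- seq(50, 950, by = 20)
  d2 <- unlist(lapply(1:30, function(sd) {
    make_daughter_trains(m2, 1, 3, 0, 0, 1000, seed = sd)[[1]] - m2
  }))
  expect_equal(mean(abs(d2)), 3 * sqrt(2 / pi), tolerance = 0.1)
  expect_error(make_daughter_trains(mother, 2, -1, 0, 0, 1000),
               class = "spikecoder_invalid_parameter")
})

test_that("simulated units combine signal and noise daughters correctly", {
  x <- fixture_signal()
  # zero jitter, zero add/remove: all trials identical
  st <- simulate_unit(sim_config(lambda1 = 50, sigma1 = 0, lambda2 = 0,
                                 n_add = 0, seed = 4), x)
  for (i in 2:st$n_trials) expect_identical(st$trials[[i]], st$trials[[1]])
  # silent unit
  st0 <- simulate_unit(sim_config(lambda1 = 0, lambda2 = 0, seed = 4), x)
  expect_true(all(lengths(st0$trials) == 0))
  # per-trial counts reflect the refractory-adjusted mother rates
  cfg <- sim_config(lambda1 = 100, sigma1 = 10, lambda2 = 200, sigma2 = 60,
                    n_add = 0, seed = 6)
  st2 <- simulate_unit(cfg, x)
  z <- spikecoder:::analysis_signal(x, cfg$fs)
  rate <- rate_from_signal(z, cfg$kernel_freq, cfg$lambda1)
  m_sig <- sample_poisson_train(rate, cfg$fs, cfg$min_isi_ms,
                                seed = spikecoder:::derive_seed(cfg$seed, 1))
  m_noi <- sample_poisson_train(rep(cfg$lambda2, length(rate)), cfg$fs,
                                cfg$min_isi_ms,
                                seed = spikecoder:::derive_seed(cfg$seed, 2))
  expected <- length(m_sig) + length(m_noi)
  expect_lt(abs(mean(lengths(st2$trials)) - expected), 4 * sqrt(expected))
  # determinism end to end
  st3 <- simulate_unit(cfg, x)
  expect_identical(st2$trials, st3$trials)
})

test_that("spike containers validate and tidy round trip", {
  st <- locked_unit(seed = 2)
  tb <- tidy(st)
  st2 <- spike_trains(tb, duration_ms = 1000, n_trials = st$n_trials)
  expect_identical(st2$trials, st$trials)
  expect_error(spike_trains(list(c(5, 5)), 10), "duplicated")
  expect_error(spike_trains(list(c(-1, 5)), 10), "outside")
  g <- glance(st)
  expect_identical(g$n_spikes, sum(lengths(st$trials)))
})
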