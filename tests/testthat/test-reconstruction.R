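test_that("the STA averages signal segments around spikes", {
  x <- fixture_signal()
  z <- spikecoder:::analysis_signal(x, 2500)
  # a single spike: the filter is exactly the signal segment around it
  st1 <- spike_trains(list(c(400)), 1000, unit_id = "one")
  fm <- compute_sta(x, st1)
  i0 <- floor(400 * 2500 / 1000) + 1
  expect_equal(as.vector(fm$coefficients),
               z$samples[(i0 - 125):(i0 + 125)], tolerance = 1e-12)
  expect_identical(ncol(fm$coefficients), 251L)
  # spikes at the maxima of a standardized sinusoid recover the sinusoid
  fs <- 2500
  t <- (0:(fs - 1)) / fs
  s <- sqrt(2) * sin(2 * pi * 20 * t)   # unit variance
  xs <- spikecoder:::new_wn_signal(s, fs, 1, 3, 1, standardized = FALSE)
  peaks <- (which(diff(sign(diff(s))) < 0) + 1)
  peaks <- peaks[peaks > 130 & peaks < fs - 130]
  stp <- spike_trains(list((peaks - 1) / fs * 1000), 1000)
  fmp <- compute_sta(xs, stp)
  mid <- 126
  expect_equal(fmp$coefficients[1, mid], sqrt(2), tolerance = 0.05)
  # the periodic signal has equal maxima at every multiple of its period;
  # lag zero attains the maximum
  expect_gte(fmp$coefficients[1, mid], max(fmp$coefficients) - 1e-6)
  expect_error(compute_sta(x, spike_trains(list(numeric(0)), 1000)),
               class = "spikecoder_insufficient_data")
})

test_that("STA equals a brute-force per-spike loop oracle", {
  x <- fixture_signal()
  st <- locked_unit(seed = 3)
  fm <- compute_sta(x, st)
  z <- spikecoder:::analysis_signal(x, 2500)$samples
  acc <- numeric(251); n <- 0
  for (tr in st$trials) for (t in tr) {
    i0 <- floor(t * 2500 / 1000) + 1
    seg <- numeric(251)
    for (l in -125:125) {
      idx <- i0 + l
      if (idx >= 1 && idx <= length(z)) seg[l + 126] <- z[idx]
    }
    acc <- acc + seg; n <- n + 1
  }
  expect_equal(as.vector(fm$coefficients), acc / n, tolerance = 1e-12)
})

test_that("causal restriction zeroes positive lags exactly", {
  fm <- compute_sta(fixture_signal(), locked_unit(seed = 4))
  cf <- make_causal(fm)
  expect_true(all(cf$coefficients[, cf$lags_ms > 0] == 0))
  expect_identical(cf$coefficients[, cf$lags_ms <= 0],
                   fm$coefficients[, fm$lags_ms <= 0])
  expect_identical(make_causal(cf)$coefficients, cf$coefficients)
  sym <- fm
  sym$coefficients <- matrix(rev(seq(-1, 1, length.out = 251)), 1)
  sym$coefficients <- matrix(abs(seq(-1, 1, length.out = 251)), 1)
  half_energy <- sum(make_causal(sym)$coefficients^2) /
    sum(sym$coefficients^2)
  expect_equal(half_energy, 0.5, tolerance = 0.01)
})

test_that("conditional banks partition spikes by ISI decile", {
  x <- fixture_signal()
  # tie pathology: identical ISIs make deciles degenerate
  reg <- spike_trains(list(seq(10, 990, by = 10)), 1000)
  expect_error(conditional_filter_bank(x, reg),
               class = "spikecoder_insufficient_data")
  # two balanced, separated ISI clusters: bank rows match
  # cluster-restricted STAs
  isi_seq <- as.vector(rbind(3 + (1:15) * 1e-3, 30 + (1:15) * 1e-3))
  t <- cumsum(c(5, isi_seq))
  st <- spike_trains(list(t), 1000)
  bank <- conditional_filter_bank(x, st, n_bins = 2)
  expect_identical(nrow(bank$coefficients), 2L)
  isis <- c(NA, diff(t))
  z <- spikecoder:::analysis_signal(x, 2500)
  short <- which(!is.na(isis) & isis < 15)
  sta_short <- spikecoder:::cpp_sta(t[short], z$samples, 2500, 125)
  expect_equal(bank$coefficients[1, ], as.vector(sta_short),
               tolerance = 1e-10)
  full <- conditional_filter_bank(x, locked_unit(seed = 5), n_bins = 10)
  expect_identical(nrow(full$coefficients), 10L)
  expect_length(full$isi_bin_edges, 11L)
})

test_that("whitening flattens the lag-window covariance", {
  # white input: operator close to identity (up to scale)
  set.seed(2)
  w <- spikecoder:::new_wn_signal(rnorm(2500), 2500, 1, 0, 2,
                                  standardized = FALSE)
  ww <- whiten_signal(w, var_fraction = 1)
  expect_gt(cor(spikecoder:::analysis_signal(w, 2500)$samples, ww$samples),
            0.98)
  # alpha-filtered input: the output covariance restricted to the
  # retained eigenvector subspace is near diagonal (oracle recomputes the
  # covariance of the output and projects it)
  x <- fixture_signal()
  wh <- whiten_signal(x, var_fraction = 0.9)
  z <- spikecoder:::analysis_signal(x, 2500)
  acv_in <- drop(stats::acf(z$samples, lag.max = 500, type = "covariance",
                            plot = FALSE)$acf)
  eig <- eigen(stats::toeplitz(acv_in[1:251]), symmetric = TRUE)
  k <- which(cumsum(eig$values) / sum(eig$values) >= 0.9)[1]
  V <- eig$vectors[, 1:k]
  acv_out <- drop(stats::acf(wh$samples, lag.max = 250, type = "covariance",
                             plot = FALSE)$acf)
  B <- t(V) %*% stats::toeplitz(acv_out) %*% V
  # the FIR application of the subspace whitener is approximate; its
  # contract is diagonal dominance, not exact whiteness
  offdiag <- max(abs(B[row(B) != col(B)]))
  expect_lt(offdiag, 0.25 * mean(diag(B)))
  expect_true(attr(wh, "n_retained") < 251)
})

test_that("modified Wiener deconvolution inverts the output autocorrelation", {
  x <- fixture_signal()
  # near-Poisson train: flat ACH, w proportional to s
  pu <- poisson_unit(seed = 7, rate = 60)
  sta <- compute_sta(x, pu)
  mw <- modified_wiener(sta, pu)
  cosim <- sum(sta$coefficients * mw$coefficients) /
    sqrt(sum(sta$coefficients^2) * sum(mw$coefficients^2))
  expect_gt(cosim, 0.99)
  # forward-model identity on the retained subspace for a bursty train
  bursty <- lapply(1:20, function(i) {
    base <- sort(runif(40, 20, 960))
    sort(c(base, base + 4.8))
  })
  bu <- spike_trains(bursty, 1000, unit_id = "bursty")
  sb <- compute_sta(x, bu)
  mb <- modified_wiener(sb, bu)
  expect_lt(mb$residual, 1e-6)
  expect_gt(max(abs(mb$coefficients - sb$coefficients)), 0)
})

test_that("cross-validated decoding recovers a deterministic encoder", {
  x <- fixture_signal()
  st <- locked_unit(seed = 9, sigma1 = 1)
  dec <- crossval_decode(x, st, kind = "mwiener", n_shuffles = 40, seed = 1)
  expect_gt(dec$Q, 0.5)
  expect_lt(dec$p_overall, 0.05)
  expect_equal(dec$Q, mean(dec$q_trials), tolerance = 1e-12)
  expect_equal(dec$p_overall, exp(mean(log(dec$p_trials))),
               tolerance = 1e-12)
  expect_true(all(dec$q_trials >= -1 & dec$q_trials <= 1))
  expect_true(all(dec$p_trials > 0 & dec$p_trials <= 1))
  # null calibration: a stimulus-blind unit (independent Poisson trials)
  # shows no decodable structure
  pu <- poisson_unit(seed = 55, rate = 60)
  dec0 <- crossval_decode(x, pu, kind = "sta", n_shuffles = 40, seed = 1)
  expect_lt(abs(dec0$Q), 0.1)
  expect_gt(dec0$p_overall, 0.05)
})

test_that("fold partition covers every trial exactly once", {
  fold_of <- sort(rep_len(1:10, 20))
  expect_identical(as.vector(table(fold_of)), rep(2L, 10))
  st <- simulate_unit(sim_config(lambda1 = 80, sigma1 = 2, n_trials = 20,
                                 seed = 3), fixture_signal())
  fit <- spikecoder:::crossval_fit(fixture_signal(), st, "sta", FALSE, 10)
  expect_identical(sort(unique(fit$fold_of)), 1:10)
  expect_true(all(table(fit$fold_of) == 2))
})

test_that("rank correlation is invariant to monotone transforms of the reconstruction", {
  z <- rnorm(2500)
  zr <- spikecoder:::cpp_rank(z)
  recon <- rnorm(2500)
  q1 <- spikecoder:::cpp_spearman(zr, recon)
  q2 <- spikecoder:::cpp_spearman(zr, exp(2 * recon))
  q3 <- spikecoder:::cpp_spearman(zr, rank(recon)^3)
  expect_equal(q1, q2, tolerance = 1e-12)
  expect_equal(q1, q3, tolerance = 1e-12)
  expect_equal(q1, cor(z, recon, method = "spearman"), tolerance = 1e-12)
})

test_that("all twelve filter models agree on the sign of a strong effect", {
  # reduced robustness check: a sharply locked unit decodes better than a
  # stimulus-blind one under every filter model
  x <- fixture_signal()
  good <- locked_unit(seed = 21, sigma1 = 1)
  bad <- poisson_unit(seed = 22, rate = 60)
  kinds <- filter_kinds()
  for (i in seq_len(nrow(kinds))) {
    qg <- crossval_decode(x, good, kinds$kind[i], kinds$causal[i],
                          n_shuffles = 0)$Q
    qb <- crossval_decode(x, bad, kinds$kind[i], kinds$causal[i],
                          n_shuffles = 0)$Q
    expect_gt(qg, qb)
  }
})
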