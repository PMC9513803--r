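test_that("CCH counting is exact on hand-computed cases", {
  # a pure delay pair puts all mass in the +1.6 ms bin
  pre <- sort(runif(500, 0, 60000))
  cch <- compute_cch(pre, pre + 1.6)
  expect_identical(sum(cch$counts[cch$lags_ms != 1.6]),
                   sum(cch$counts) - max(cch$counts))
  expect_identical(cch$lags_ms[which.max(cch$counts)], 1.6)
  # two spikes each: enumerate all four differences by hand
  c2 <- compute_cch(c(10, 30), c(11, 30.1), bin_ms = 0.4,
                    half_range_ms = 50)
  diffs <- as.vector(outer(c(11, 30.1), c(10, 30), "-"))
  # half-open bins [c - 0.2, c + 0.2): left edges belong to the bin above
  expected <- table(floor(diffs[abs(diffs) <= 50.2] / 0.4 + 0.5))
  for (k in names(expected)) {
    expect_identical(c2$counts[c2$lags_ms == as.numeric(k) * 0.4],
                     as.integer(expected[[k]]))
  }
  expect_identical(sum(c2$counts), length(diffs[abs(diffs) <= 50.2]))
  expect_error(compute_cch(numeric(0), pre),
               class = "spikecoder_insufficient_data")
})

test_that("CCH count conservation and time-reversal identity hold", {
  set.seed(4)
  a <- sort(runif(300, 0, 30000))
  b <- sort(runif(400, 0, 30000))
  ab <- compute_cch(a, b)
  # brute force conservation
  n_pairs <- sum(abs(outer(b, a, "-")) < 50.2)
  expect_identical(sum(ab$counts), n_pairs)
  ba <- compute_cch(b, a)
  expect_identical(as.integer(ab$counts), rev(as.integer(ba$counts)))
})

test_that("independent Poisson pairs produce a flat CCH at the analytic level", {
  set.seed(9)
  T_s <- 200; la <- 8; lb <- 15
  a <- sort(runif(rpois(1, la * T_s), 0, T_s * 1000))
  b <- sort(runif(rpois(1, lb * T_s), 0, T_s * 1000))
  cch <- compute_cch(a, b)
  expected <- la * lb * T_s * 0.4e-3
  expect_true(all(abs(cch$counts - expected) < 4 * sqrt(expected) + 1))
})

test_that("the Poisson peak test flags injected connections and calibrates on nulls", {
  pp <- injected_pair(0.2, seed = 5)
  cch <- compute_cch(pp$pre, pp$post)
  tst <- test_monosynaptic(cch)
  expect_true(tst$significant)
  expect_lt(abs(tst$peak_lag_ms - 1.6), 0.5)
  # counts equal to baseline: not significant
  flat <- cch
  flat$counts <- as.integer(round(flat$baseline))
  flat$baseline <- pmax(flat$baseline, 1)
  flat$counts <- as.integer(round(flat$baseline))
  expect_false(test_monosynaptic(flat)$significant)
  zero <- cch; zero$baseline <- rep(0, length(zero$baseline))
  expect_error(test_monosynaptic(zero),
               class = "spikecoder_undefined_test")
})

test_that("transmission curves recover injected gain and lag", {
  gains <- sapply(1:5, function(sd) {
    pp <- injected_pair(0.2, seed = sd)
    cch <- compute_cch(pp$pre, pp$post)
    ach <- compute_cch(pp$pre, pp$pre, half_range_ms = 100)$counts
    tc <- transmission_curve(cch, pre_ach = ach)
    expect_true(tc$significant)
    expect_gte(tc$peak_lag_ms, 1.2)
    expect_lte(tc$peak_lag_ms, 2.0)
    tc$gain
  })
  expect_gte(median(gains), 0.15)
  expect_lte(median(gains), 0.25)
})

test_that("null pairs give near-zero gain and Poisson deconvolution is identity-like", {
  set.seed(11)
  pre <- sort(runif(3000, 0, 300000))
  post <- sort(runif(6000, 0, 300000))
  cch <- compute_cch(pre, post)
  tc <- transmission_curve(cch)
  expect_false(tc$significant)
  expect_lt(abs(tc$gain), 0.01)
  # deconvolving by a near-flat ACH barely changes the curve
  ach <- compute_cch(pre, pre, half_range_ms = 100)$counts
  tc2 <- transmission_curve(cch, pre_ach = ach)
  cosim <- sum(tc$excess_rate * tc2$excess_rate) /
    sqrt(sum(tc$excess_rate^2) * sum(tc2$excess_rate^2))
  expect_gt(cosim, 0.99)
})

test_that("connection probability uses the distance-filtered candidate pool", {
  units <- tibble::tibble(
    unit_id = c("int", paste0("p", 1:25)),
    x_um = c(0, rep(c(0, 200, 400, 800, 1200), 5)),
    y_um = c(0, rep(c(0, 100, 300, 200, 50), each = 5)),
    is_candidate = c(FALSE, rep(TRUE, 25)))
  res <- connection_probability(units, "int", presyn_ids = c("p1", "p2", "p3"),
                                range_um = 600)
  # oracle: brute-force distance scan
  d <- sqrt((units$x_um - 0)^2 + (units$y_um - 0)^2)
  in_range <- units$unit_id[units$is_candidate & d <= 600]
  expect_identical(res$n_in_range, length(in_range))
  expect_identical(res$n_presyn, sum(c("p1", "p2", "p3") %in% in_range))
  expect_equal(res$probability, res$n_presyn / res$n_in_range)
  # all candidates out of range: missing, not zero
  far <- units; far$x_um[-1] <- 5000
  expect_true(is.na(connection_probability(far, "int", "p1")$probability))
  # simple arithmetic case
  u2 <- tibble::tibble(unit_id = c("int", paste0("p", 1:20)),
                       x_um = 0, y_um = 0,
                       is_candidate = c(FALSE, rep(TRUE, 20)))
  expect_equal(connection_probability(u2, "int", paste0("p", 1:3))$probability,
               0.15)
})
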