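#' DC-gain test for stimulus-driven rate increase
#'
#' DC gain is the mean firing rate during stimulation trials divided by
#' the spontaneous (no-stimulus) rate; consistency is an upper-tail
#' Poisson test of the pooled stimulation spike count against the
#' expectation under the spontaneous rate.
#'
#' @param wn_spike_count Total spikes during stimulation.
#' @param wn_duration_s Total stimulation time (s).
#' @param baseline_rate_hz Spontaneous rate (spikes/s).
#' @return A tibble with `dc_gain` and `p` (`NA` when the baseline rate is
#'   zero: the gain is undefined, not infinite).
#' @export
dc_gain_test <- function(wn_spike_count, wn_duration_s, baseline_rate_hz) {
  stopifnot_positive(wn_duration_s, "wn_duration_s")
  stopifnot_nonneg(wn_spike_count, "wn_spike_count")
  if (is.na(baseline_rate_hz) || baseline_rate_hz <= 0) {
    return(tibble(dc_gain = NA_real_, p = NA_real_))
  }
  gain <- (wn_spike_count / wn_duration_s) / baseline_rate_hz
  lambda <- baseline_rate_hz * wn_duration_s
  p <- ppois(wn_spike_count - 1, lambda, lower.tail = FALSE)
  tibble(dc_gain = gain, p = p)
}

#' Spearman correlation with a permutation test
#'
#' Spearman rank correlation between `x` and `y` with an empirical
#' two-sided permutation p value, `(1 + #(|cc_perm| >= |cc|)) /
#' (n_perm + 1)`. With a covariate, the partial rank correlation is used:
#' the correlation of the rank residuals after regressing the ranks of
#' `x` and `y` on the ranks of the covariate (the covariate is permuted
#' together with `x`).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @param partial_on Optional covariate vector.
#' @return A tibble with `estimate` and `p.value`.
#' @export
rank_corr_perm_test <- function(x, y, n_perm = 1000, seed = 1,
                                partial_on = NULL) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.",
          class = "spikecoder_invalid_parameter")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined for a constant vector.",
          class = "spikecoder_invalid_parameter")
  }
  cc_of <- function(xr, yr, cr) {
    if (is.null(cr)) return(suppressWarnings(cor(xr, yr)))
    rx <- stats::residuals(stats::lm.fit(cbind(1, cr), xr))
    ry <- stats::residuals(stats::lm.fit(cbind(1, cr), yr))
    # a covariate that explains a variable completely leaves numerical
    # dust, not signal
    if (sd(rx) < 1e-8 * (1 + sd(xr)) || sd(ry) < 1e-8 * (1 + sd(yr))) {
      return(0)
    }
    suppressWarnings(cor(rx, ry))
  }
  xr <- rank(x); yr <- rank(y)
  cr <- if (is.null(partial_on)) NULL else rank(partial_on)
  cc <- cc_of(xr, yr, cr)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(xr))
      cc_of(xr[idx], yr, if (is.null(cr)) NULL else cr[idx])
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(cc) - 1e-12)) / (n_perm + 1)
  tibble(estimate = cc, p.value = p)
}

#' Shared nonparametric tests
#'
#' Thin wrappers with the package's conventions (one-tailed by default,
#' normal approximation with continuity correction for moderate samples,
#' never a zero p value where empirical):
#'
#' * `u_test()` -- one-tailed Mann-Whitney U for unpaired samples.
#' * `signed_rank_test()` -- one-tailed paired Wilcoxon signed-rank
#'   (errors on all-zero differences, where the test is undefined).
#' * `g_test()` -- G test (log-likelihood ratio) of independence on a
#'   contingency table.
#' * `binom_test()` -- exact one-tailed binomial test.
#'
#' @param x,y Numeric samples (for `g_test`, `x` is a matrix/table).
#' @param alternative Direction of the one-tailed test.
#' @param n,k,p For `binom_test`: trials, successes, null probability.
#' @return A tibble with `statistic` and `p.value`.
#' @name nonparam_suite
NULL

#' @rdname nonparam_suite
#' @export
u_test <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) {
    abort("Both groups must be non-empty.",
          class = "spikecoder_invalid_parameter")
  }
  ht <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = NULL, correct = TRUE))
  tibble(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' @rdname nonparam_suite
#' @export
signed_rank_test <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y) || length(x) == 0) {
    abort("Paired samples must be non-empty and of equal length.",
          class = "spikecoder_invalid_parameter")
  }
  d <- x - y
  if (all(d == 0)) {
    abort("All paired differences are zero; the signed-rank test is undefined.",
          class = "spikecoder_invalid_parameter")
  }
  ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                     alternative = alternative,
                                     exact = NULL, correct = TRUE))
  tibble(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' @rdname nonparam_suite
#' @export
g_test <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0) || sum(x) == 0) {
    abort("`x` must be a non-negative contingency table.",
          class = "spikecoder_invalid_parameter")
  }
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  nz <- x > 0
  G <- 2 * sum(x[nz] * log(x[nz] / expected[nz]))
  df <- (nrow(x) - 1) * (ncol(x) - 1)
  tibble(statistic = G, p.value = pchisq(G, df, lower.tail = FALSE))
}

#' @rdname nonparam_suite
#' @export
binom_test <- function(k, n, p = 0.5, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  ht <- stats::binom.test(k, n, p, alternative = alternative)
  tibble(statistic = k, p.value = ht$p.value)
}

#' Unit-inclusion screening
#'
#' Applies the sequential inclusion gates: (1) at least `min_trials`
#' trials and `min_spikes_per_trial` mean spikes per trial with a
#' consistent DC response (rate during stimulation above the spontaneous
#' rate, Poisson test); (2) an AC response, i.e. consistent cross-validated
#' decoding quality; (3) reliable spike trains, i.e. pairwise reliability
#' consistently above zero. Screening stops at the first failed gate.
#'
#' @param spikes The unit's stimulation-epoch spike trains.
#' @param baseline_rate_hz Spontaneous rate from no-stimulus epochs.
#' @param decoding A [crossval_decode()] result (or `NULL` if not yet
#'   computed; the unit then fails the AC gate only if reached).
#' @param reliability A [reliability_profile()] result (or `NULL`).
#' @param alpha Significance level for all gates.
#' @param min_trials,min_spikes_per_trial Data-quantity gates.
#' @return A one-row tibble (`unit_id`, gate values, `passed`,
#'   `failure_stage` in `trials`/`dc`/`ac`/`reliability`/`none`).
#' @export
screen_unit <- function(spikes, baseline_rate_hz, decoding = NULL,
                        reliability = NULL, alpha = 0.05, min_trials = 5,
                        min_spikes_per_trial = 2) {
  spikes <- as_spike_trains(spikes)
  n <- lengths(spikes$trials)
  mspt <- mean(n)
  dur_s <- spikes$n_trials * spikes$duration_ms / 1000
  dc <- dc_gain_test(sum(n), dur_s, baseline_rate_hz)
  ac_p <- if (!is.null(decoding)) decoding$p_overall else NA_real_
  rel_p <- if (!is.null(reliability)) reliability$consistency_p else NA_real_
  stage <- "none"
  if (spikes$n_trials < min_trials || mspt < min_spikes_per_trial) {
    stage <- "trials"
  } else if (is.na(dc$p) || dc$p >= alpha) {
    stage <- "dc"
  } else if (is.na(ac_p) || ac_p >= alpha) {
    stage <- "ac"
  } else if (is.na(rel_p) || rel_p >= alpha) {
    stage <- "reliability"
  }
  tibble(unit_id = spikes$unit_id, n_trials = spikes$n_trials,
         mean_spikes_per_trial = mspt, dc_gain = dc$dc_gain, dc_p = dc$p,
         ac_p = ac_p, rel_p = rel_p, passed = stage == "none",
         failure_stage = stage)
}
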