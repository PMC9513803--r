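#' Presynaptic rate function from spikes and a transmission curve
#'
#' Convolves each trial's presynaptic spike train with the causal,
#' rectified part of a spike-transmission curve (lags > 0; negative excess
#' clipped to 0), giving the postsynaptic drive contributed by that input
#' in spikes/s on the analysis grid.
#'
#' @param spikes A [spike_trains()] object or tidy spike table (the
#'   presynaptic unit during stimulation).
#' @param curve A `transmission_curve`.
#' @param fs_analysis Grid rate (Hz); must match the curve's bin width
#'   (`1000 / bin_ms`).
#' @return A `rate_function`: samples-by-trials matrix of rates with
#'   attributes `fs` and `duration_ms`.
#' @export
presyn_rate <- function(spikes, curve, fs_analysis = 2500) {
  stopifnot(inherits(curve, "transmission_curve"))
  spikes <- as_spike_trains(spikes)
  if (abs(1000 / curve$bin_ms - fs_analysis) > 1e-9) {
    abort("Curve bin width does not match the analysis grid.",
          class = "spikecoder_alignment_error")
  }
  causal <- curve$lags_ms > 0
  resp <- pmax(curve$excess_rate[causal], 0)
  lag_idx <- round(curve$lags_ms[causal] / curve$bin_ms)  # samples ahead
  n <- round(fs_analysis * spikes$duration_ms / 1000)
  # one padded row: response placed at spike sample + lag
  coefs <- numeric(2L * max(lag_idx) + 1L)
  coefs[max(lag_idx) + 1L + lag_idx] <- resp
  M <- vapply(spikes$trials, function(t) {
    if (length(t) == 0L) numeric(n)
    else cpp_recon(as.numeric(t), matrix(coefs, 1), 1L, fs_analysis, n)
  }, numeric(n))
  new_rate_function(M, fs_analysis, spikes$duration_ms,
                    provenance = list(model = "presyn",
                                      pre_id = curve$pre_id))
}

new_rate_function <- function(M, fs, duration_ms, provenance = list()) {
  if (any(M < 0)) abort("Rate function must be non-negative.")
  structure(M, fs = fs, duration_ms = duration_ms,
            provenance = provenance, class = c("rate_function", "matrix"))
}

#' @export
print.rate_function <- function(x, ...) {
  cat(sprintf("<rate_function> %d samples x %d trials @ %g Hz, mean %.2f spikes/s\n",
              nrow(x), ncol(x), attr(x, "fs"), mean(x)))
  invisible(x)
}

check_common_grid <- function(xs) {
  if (length(xs) == 0L) abort("Need at least one rate function.")
  fs <- attr(xs[[1]], "fs"); d <- dim(xs[[1]])
  for (x in xs) {
    if (!inherits(x, "rate_function") || !identical(dim(x), d) ||
        attr(x, "fs") != fs) {
      abort("Rate functions are not on a common grid.",
            class = "spikecoder_alignment_error")
    }
  }
  invisible(xs)
}

#' Synaptic transmission combination rules
#'
#' Combine the per-input rate functions `x_i(t)` of candidate presynaptic
#' units into a single postsynaptic rate `y(t)`:
#'
#' * `combine_ll()` -- labelled line: the single input passes through
#'   unchanged (errors when more than one input is supplied).
#' * `combine_sp()` -- summed population: elementwise linear sum.
#' * `combine_cd1()` -- coincidence detection, multiplicative form: with
#'   `n(t)` active inputs (`x_i(t) > 0`), `y = prod(x_i + gamma) - gamma^n`
#'   over the active inputs for `n > 1`; the single active input for
#'   `n = 1`; 0 for `n = 0`. `gamma >= 0` is the non-linearity factor (in
#'   rate units here).
#' * `combine_cd2()` -- coincidence detection, non-linear summation:
#'   `y = sum(x_i) * gamma^(n - 1)` over active inputs (`gamma`
#'   dimensionless); identical to `combine_sp()` at `gamma = 1`, and both
#'   CD rules reduce to the labelled line with a single input, so isolated
#'   spikes are never amplified while coincident input is supralinear for
#'   `gamma` large enough.
#'
#' @param xs A list of `rate_function`s on a common grid (or a single one
#'   for `combine_ll()`).
#' @param gamma Non-negative non-linearity factor.
#' @return A `rate_function`.
#' @name transmission_rules
NULL

#' @rdname transmission_rules
#' @export
combine_ll <- function(xs) {
  if (inherits(xs, "rate_function")) xs <- list(xs)
  if (length(xs) != 1L) {
    abort("The labelled-line model takes exactly one presynaptic input.",
          class = "spikecoder_model_mismatch")
  }
  check_common_grid(xs)
  new_rate_function(unclass(xs[[1]]), attr(xs[[1]], "fs"),
                    attr(xs[[1]], "duration_ms"),
                    provenance = list(model = "LL"))
}

#' @rdname transmission_rules
#' @export
combine_sp <- function(xs) {
  if (inherits(xs, "rate_function")) xs <- list(xs)
  check_common_grid(xs)
  out <- Reduce(`+`, lapply(xs, unclass))
  new_rate_function(out, attr(xs[[1]], "fs"), attr(xs[[1]], "duration_ms"),
                    provenance = list(model = "SP"))
}

#' @rdname transmission_rules
#' @export
combine_cd1 <- function(xs, gamma) {
  if (inherits(xs, "rate_function")) xs <- list(xs)
  check_common_grid(xs)
  stopifnot_nonneg(gamma, "gamma")
  act <- lapply(xs, function(x) unclass(x) > 0)
  n_act <- Reduce(`+`, act)
  # product of (x_i + gamma) over ACTIVE inputs only
  prod_act <- 1
  sum_single <- 0
  for (k in seq_along(xs)) {
    xi <- unclass(xs[[k]])
    prod_act <- prod_act * ifelse(act[[k]], xi + gamma, 1)
    sum_single <- sum_single + ifelse(act[[k]], xi, 0)
  }
  y <- prod_act - gamma^n_act
  y[n_act == 1L] <- sum_single[n_act == 1L]
  y[n_act == 0L] <- 0
  y[y < 0] <- 0
  new_rate_function(y, attr(xs[[1]], "fs"), attr(xs[[1]], "duration_ms"),
                    provenance = list(model = "CD1", gamma = gamma))
}

#' @rdname transmission_rules
#' @export
combine_cd2 <- function(xs, gamma) {
  if (inherits(xs, "rate_function")) xs <- list(xs)
  check_common_grid(xs)
  stopifnot_nonneg(gamma, "gamma")
  act <- lapply(xs, function(x) unclass(x) > 0)
  n_act <- Reduce(`+`, act)
  s <- Reduce(`+`, lapply(xs, unclass))
  y <- s * gamma^pmax(n_act - 1L, 0L)
  y[n_act == 0L] <- 0
  new_rate_function(y, attr(xs[[1]], "fs"), attr(xs[[1]], "duration_ms"),
                    provenance = list(model = "CD2", gamma = gamma))
}

#' Generate a synthetic postsynaptic spike train from a rate function
#'
#' Samples one spike train per trial from the combined rate function
#' (per-sample Bernoulli draws, no minimum-ISI constraint by default),
#' measures the realized mean rate `FR_1`, and -- unless `noiseless` --
#' adds an independent homogeneous Poisson background per trial so the
#' total mean rate matches the target `fr_wn` (`FR_1 + FR_2 = FR_WN`; no
#' background is added when `FR_1 >= FR_WN`).
#'
#' @param rate A `rate_function` (samples x trials).
#' @param fr_wn Target mean rate during stimulation (spikes/s).
#' @param noiseless Skip the rate-equalizing background.
#' @param min_isi_ms Optional minimum ISI imposed on the driven train.
#' @param seed Seed.
#' @param unit_id Label of the synthetic unit.
#' @return A [spike_trains()] object with attributes `fr1` (realized
#'   driven rate) and `fr2` (background rate added).
#' @export
generate_sint <- function(rate, fr_wn = NULL, noiseless = FALSE,
                          min_isi_ms = 0, seed = 1, unit_id = "sINT") {
  stopifnot(inherits(rate, "rate_function"))
  if (!noiseless) stopifnot_positive(fr_wn, "fr_wn")
  fs <- attr(rate, "fs")
  dur_ms <- attr(rate, "duration_ms")
  n_trials <- ncol(rate)
  st1 <- lapply(seq_len(n_trials), function(i) {
    sample_poisson_train(rate[, i], fs, min_isi_ms,
                         seed = derive_seed(seed, 21, i))
  })
  fr1 <- sum(lengths(st1)) / (n_trials * dur_ms / 1000)
  fr2 <- 0
  trials <- st1
  if (!noiseless && fr1 < fr_wn) {
    fr2 <- fr_wn - fr1
    trials <- lapply(seq_len(n_trials), function(i) {
      bg <- sample_poisson_train(rep(fr2, nrow(rate)), fs, 0,
                                 seed = derive_seed(seed, 22, i))
      dedup_times(c(st1[[i]], bg), 0.5 * 1000 / fs, dur_ms)
    })
  }
  out <- spike_trains(trials, duration_ms = dur_ms, unit_id = unit_id)
  attr(out, "fr1") <- fr1
  attr(out, "fr2") <- fr2
  attr(out, "provenance") <- attr(rate, "provenance")
  out
}

#' A synthetic transmission curve with a single causal lobe
#'
#' Builds a half-sine excess-rate lobe centred at `peak_lag_ms` with the
#' requested gain (area in expected postsynaptic spikes per presynaptic
#' spike), labelled synthetic. Useful for wiring simulated populations.
#'
#' @param gain Expected extra postsynaptic spikes per presynaptic spike.
#' @param peak_lag_ms Lobe centre (ms).
#' @param width_ms Lobe full width (ms).
#' @param bin_ms Lag grid (ms).
#' @param half_range_ms Lag range (ms).
#' @param pre_id,post_id Labels.
#' @export
synthetic_curve <- function(gain = 0.02, peak_lag_ms = 1.6, width_ms = 1.2,
                            bin_ms = 0.4, half_range_ms = 50,
                            pre_id = "pre", post_id = "post") {
  nb <- round(half_range_ms / bin_ms)
  lags <- (-nb:nb) * bin_ms
  lobe <- pmax(cos(pi * (lags - peak_lag_ms) / width_ms), 0)
  lobe[abs(lags - peak_lag_ms) > width_ms / 2] <- 0
  area <- sum(lobe) * bin_ms / 1000
  excess <- lobe * gain / area
  structure(list(pre_id = pre_id, post_id = post_id, lags_ms = lags,
                 excess_rate = excess, gain = gain,
                 peak_lag_ms = peak_lag_ms,
                 support_ms = peak_lag_ms + c(-1, 1) * width_ms / 2,
                 roi_ms = c(0, 5.2), significant = TRUE, p = NA_real_,
                 bin_ms = bin_ms),
            class = "transmission_curve")
}
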