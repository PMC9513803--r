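#' Point-process simulation configuration
#'
#' Parameters of the white-noise point-process simulator used to generate
#' synthetic units with controlled signal locking and noise. Defaults match
#' the validation simulation: 2500 Hz grid, 25 trials of 1 s, a 100 Hz
#' single-cycle sinusoid as the STA-like rate kernel, and a 2 ms minimum
#' inter-spike interval imposed on the mother trains.
#'
#' @param lambda1 Signal firing rate (spikes/s) driving the rate profile.
#' @param sigma1 Signal jitter SD (ms) applied to signal-train daughters.
#' @param lambda2 Background (noise) firing rate (spikes/s), homogeneous.
#' @param sigma2 Noise jitter SD (ms) applied to noise-train daughters.
#' @param n_add Maximum number of spikes added per daughter train; the
#'   number removed is drawn with the same maximum (`n_remove == n_add`).
#' @param fs Simulation sampling rate (Hz).
#' @param n_trials Number of trials.
#' @param duration_s Trial duration (s).
#' @param min_isi_ms Minimum ISI imposed on mother trains (ms).
#' @param kernel_freq Frequency (Hz) of the single-cycle sinusoid kernel.
#' @param seed Master seed; per-role and per-trial streams are derived from
#'   it so adding units never perturbs existing ones.
#' @return A `sim_config` list.
#' @export
sim_config <- function(lambda1 = 100, sigma1 = 3, lambda2 = 0, sigma2 = 0,
                       n_add = 0, fs = 2500, n_trials = 25, duration_s = 1,
                       min_isi_ms = 2, kernel_freq = 100, seed = 1) {
  stopifnot_nonneg(lambda1, "lambda1"); stopifnot_nonneg(lambda2, "lambda2")
  stopifnot_nonneg(sigma1, "sigma1"); stopifnot_nonneg(sigma2, "sigma2")
  stopifnot_nonneg(n_add, "n_add"); stopifnot_nonneg(min_isi_ms, "min_isi_ms")
  stopifnot_positive(fs, "fs"); stopifnot_positive(duration_s, "duration_s")
  if (n_trials < 1) abort("`n_trials` must be >= 1.",
                          class = "spikecoder_invalid_parameter")
  structure(list(lambda1 = lambda1, sigma1 = sigma1, lambda2 = lambda2,
                 sigma2 = sigma2, n_add = n_add, n_remove = n_add,
                 fs = fs, n_trials = as.integer(n_trials),
                 duration_s = duration_s, min_isi_ms = min_isi_ms,
                 kernel_freq = kernel_freq, seed = as.integer(seed)),
            class = "sim_config")
}

#' Parameter sets of the four canonical example units
#'
#' Returns the simulator configuration of one of the four published example
#' regimes: `"F"` (low-rate, 3 ms signal jitter, heavy add/remove),
#' `"G"` (high rate, 10 ms jitter), `"H"` (high rate, 1 ms jitter, light
#' add/remove) and `"I"` (10 ms signal jitter plus strong 60 ms-jittered
#' shared background).
#'
#' @param which One of `"F"`, `"G"`, `"H"`, `"I"`.
#' @param seed Master seed.
#' @export
quadrant_config <- function(which = c("F", "G", "H", "I"), seed = 1) {
  which <- match.arg(which)
  pars <- switch(which,
    F = list(lambda1 = 25,  sigma1 = 3,  lambda2 = 0,   sigma2 = 0,  n_add = 25),
    G = list(lambda1 = 100, sigma1 = 10, lambda2 = 0,   sigma2 = 0,  n_add = 0),
    H = list(lambda1 = 100, sigma1 = 1,  lambda2 = 0,   sigma2 = 0,  n_add = 10),
    I = list(lambda1 = 100, sigma1 = 10, lambda2 = 200, sigma2 = 60, n_add = 0))
  do.call(sim_config, c(pars, list(seed = seed)))
}

#' Firing-rate profile from a standardized stimulus
#'
#' Convolves the standardized signal with a template kernel (one full cycle
#' of a sinusoid at `kernel_freq`), rectifies (negative rate clipped to 0),
#' and scales the result so its time average equals `lambda1`.
#'
#' @param x A standardized `wn_signal` on the simulation grid.
#' @inheritParams sim_config
#' @return Numeric vector of rates (spikes/s), one per sample.
#' @export
rate_from_signal <- function(x, kernel_freq = 100, lambda1 = 100) {
  stopifnot(inherits(x, "wn_signal"))
  stopifnot_positive(kernel_freq, "kernel_freq")
  stopifnot_nonneg(lambda1, "lambda1")
  if (!x$standardized) abort("`x` must be standardized first.",
                             class = "spikecoder_invalid_parameter")
  len <- max(2L, round(x$fs / kernel_freq))
  kern <- sin(2 * pi * (seq_len(len) - 1L) / len)
  r <- conv_same(x$samples, kern)
  r[r < 0] <- 0
  m <- mean(r)
  if (m > 0) r <- r * (lambda1 / m)
  r
}

#' Sample a spike train from a rate profile
#'
#' Per-sample Bernoulli draws with probability `rate/fs` (clipped at 1),
#' followed by causal minimum-ISI pruning: any spike closer than
#' `min_isi_ms` to the last retained spike is deleted.
#'
#' @param rate Numeric vector of rates (spikes/s), one per sample.
#' @param fs Sampling rate (Hz).
#' @param min_isi_ms Minimum ISI (ms); 0 disables pruning.
#' @param seed Seed.
#' @return Sorted spike times (ms). Spike time is the left edge of the
#'   winning sample.
#' @export
sample_poisson_train <- function(rate, fs, min_isi_ms = 0, seed = 1) {
  p <- rate / fs
  n_clip <- sum(p > 1)
  if (n_clip > 0) {
    warn(sprintf("%d sample(s) had rate/fs > 1; clipped.", n_clip))
    p[p > 1] <- 1
  }
  hit <- with_seed(seed, runif(length(p)) < p)
  t_ms <- (which(hit) - 1L) * 1000 / fs
  if (min_isi_ms > 0 && length(t_ms) > 1L) {
    keep <- prune_min_isi(t_ms, min_isi_ms)
    t_ms <- t_ms[keep]
  }
  t_ms
}

prune_min_isi <- function(t_ms, min_isi_ms) {
  keep <- logical(length(t_ms))
  last <- -Inf
  for (i in seq_along(t_ms)) {
    if (t_ms[i] - last >= min_isi_ms) {
      keep[i] <- TRUE
      last <- t_ms[i]
    }
  }
  keep
}

#' Replicate a mother train into modified daughter trains
#'
#' Each daughter is the mother with (1) every spike independently jittered
#' by a Gaussian of SD `jitter_sd` (clipped to the trial), (2) a uniform
#' 0..`n_remove` random spikes deleted, (3) a uniform 0..`n_add` spikes
#' added at uniform times. Duplicated times are perturbed by `tie_eps_ms`.
#'
#' @param mother Sorted spike times (ms).
#' @param n_trials Number of daughters.
#' @param jitter_sd Gaussian jitter SD (ms).
#' @param n_remove,n_add Maximum removed/added spikes per daughter.
#' @param duration_ms Trial duration (ms).
#' @param seed Seed.
#' @param tie_eps_ms Perturbation used to break exact ties (half an
#'   analysis sample by default).
#' @return List of `n_trials` sorted spike-time vectors.
#' @export
make_daughter_trains <- function(mother, n_trials, jitter_sd, n_remove,
                                 n_add, duration_ms, seed = 1,
                                 tie_eps_ms = 0.2) {
  stopifnot_nonneg(jitter_sd, "jitter_sd")
  stopifnot_nonneg(n_remove, "n_remove"); stopifnot_nonneg(n_add, "n_add")
  lapply(seq_len(n_trials), function(i) {
    with_seed(derive_seed(seed, i), {
      t <- mother + rnorm(length(mother), 0, jitter_sd)
      t <- pmin(pmax(t, 0), duration_ms - 1e-9)
      if (n_remove > 0 && length(t) > 0) {
        k_rm <- sample.int(n_remove + 1L, 1L) - 1L
        k_rm <- min(k_rm, length(t))
        if (k_rm > 0) t <- t[-sample.int(length(t), k_rm)]
      }
      if (n_add > 0) {
        k_ad <- sample.int(n_add + 1L, 1L) - 1L
        if (k_ad > 0) t <- c(t, runif(k_ad, 0, duration_ms))
      }
      if (tie_eps_ms > 0) dedup_times(t, tie_eps_ms, duration_ms)
      else sort(t)
    })
  })
}

#' Simulate one unit under the white-noise point-process model
#'
#' A "mother" signal train is sampled from the kernel-filtered stimulus
#' rate and a "mother" noise train from a homogeneous Poisson process (both
#' with the minimum-ISI constraint); each is replicated into `n_trials`
#' daughters modified with the respective jitter SD and the shared
#' add/remove maximum, and the final train of each trial merges the signal
#' and noise daughters.
#'
#' @param cfg A [sim_config()].
#' @param x The stimulus as a `wn_signal` (any rate; resampled to `cfg$fs`
#'   and standardized internally).
#' @return A [spike_trains()] object.
#' @export
simulate_unit <- function(cfg, x) {
  stopifnot(inherits(cfg, "sim_config"), inherits(x, "wn_signal"))
  z <- analysis_signal(x, cfg$fs)
  dur_ms <- cfg$duration_s * 1000
  tie <- 0.5 * 1000 / cfg$fs
  rate <- rate_from_signal(z, cfg$kernel_freq, cfg$lambda1)
  sig_mother <- sample_poisson_train(rate, cfg$fs, cfg$min_isi_ms,
                                     seed = derive_seed(cfg$seed, 1))
  noise_mother <- sample_poisson_train(rep(cfg$lambda2, length(rate)),
                                       cfg$fs, cfg$min_isi_ms,
                                       seed = derive_seed(cfg$seed, 2))
  sig_d <- make_daughter_trains(sig_mother, cfg$n_trials, cfg$sigma1,
                                cfg$n_remove, cfg$n_add, dur_ms,
                                seed = derive_seed(cfg$seed, 3),
                                tie_eps_ms = tie)
  noi_d <- make_daughter_trains(noise_mother, cfg$n_trials, cfg$sigma2,
                                cfg$n_remove, cfg$n_add, dur_ms,
                                seed = derive_seed(cfg$seed, 4),
                                tie_eps_ms = tie)
  trials <- lapply(seq_len(cfg$n_trials), function(i) {
    dedup_times(c(sig_d[[i]], noi_d[[i]]), tie, dur_ms)
  })
  spike_trains(trials, duration_ms = dur_ms,
               unit_id = sprintf("sim_s%d", cfg$seed))
}

#' Homogeneous Poisson baseline epoch
#'
#' Spontaneous-activity stand-in used for DC-gain screening: a single
#' homogeneous Poisson train over a no-stimulus epoch.
#'
#' @param rate_hz Spontaneous rate (spikes/s).
#' @param duration_s Epoch duration (s).
#' @param seed Seed.
#' @return Sorted spike times (ms).
#' @export
simulate_baseline <- function(rate_hz, duration_s, seed = 1) {
  stopifnot_nonneg(rate_hz, "rate_hz")
  stopifnot_positive(duration_s, "duration_s")
  n <- with_seed(derive_seed(seed, 99), rpois(1, rate_hz * duration_s))
  sort(with_seed(derive_seed(seed, 100), runif(n, 0, duration_s * 1000)))
}
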