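#' Generate an alpha-filtered Gaussian white-noise stimulus
#'
#' Draws zero-mean Gaussian white noise at `fs` and convolves it with an
#' alpha function \eqn{t \exp(-t/\tau)} (support truncated at \eqn{10\tau},
#' which captures essentially all kernel mass), then rescales the result to
#' the closed interval \[0, 1\]. This is the waveform used to drive the
#' optogenetic stimulus: low-passed noise with correlation time set by
#' `tau_ms`, scaled so a light-power command `mu + x(t) * sigma` stays
#' positive for suitable `mu`.
#'
#' @param duration_s Signal duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param tau_ms Alpha-function time constant in milliseconds. As
#'   `tau_ms` approaches zero the kernel degenerates to a delta and the
#'   output is a rescaling of the raw Gaussian draw.
#' @param seed Integer seed; the same seed and parameters give
#'   bit-identical samples (R's default Mersenne-Twister stream, scoped so
#'   the caller's RNG state is untouched).
#' @return A `wn_signal` object: list with `samples`, `fs`, `duration_s`,
#'   `tau_ms`, `seed`, `standardized`.
#' @examples
#' x <- wn_signal(1, 6000, 3, seed = 7)
#' range(x$samples)
#' @export
wn_signal <- function(duration_s, fs = 6000, tau_ms = 3, seed = 1) {
  stopifnot_positive(duration_s, "duration_s")
  stopifnot_positive(fs, "fs")
  stopifnot_nonneg(tau_ms, "tau_ms")
  n <- round(fs * duration_s)
  raw <- with_seed(seed, rnorm(n))
  nk <- floor(10 * tau_ms * fs / 1000) + 1L
  if (nk < 2L) {
    y <- raw  # delta-kernel limit
  } else {
    t_ms <- (seq_len(nk) - 1L) * 1000 / fs
    kern <- t_ms * exp(-t_ms / tau_ms)
    y <- conv_same(raw, kern)
  }
  rng <- range(y)
  if (rng[2] == rng[1]) {
    abort("Filtered signal is constant; cannot rescale to [0, 1].",
          class = "spikecoder_degenerate_signal")
  }
  samples <- (y - rng[1]) / (rng[2] - rng[1])
  new_wn_signal(samples, fs, duration_s, tau_ms, seed, standardized = FALSE)
}

new_wn_signal <- function(samples, fs, duration_s, tau_ms, seed,
                          standardized) {
  structure(
    list(samples = samples, fs = fs, duration_s = duration_s,
         tau_ms = tau_ms, seed = seed, standardized = standardized),
    class = "wn_signal"
  )
}

#' @export
print.wn_signal <- function(x, ...) {
  cat(sprintf(
    "<wn_signal> %d samples @ %g Hz (%.3g s), tau = %g ms, seed = %s, %s\n",
    length(x$samples), x$fs, x$duration_s, x$tau_ms,
    format(x$seed), if (x$standardized) "standardized" else "scaled [0, 1]"))
  invisible(x)
}

#' @export
as_tibble.wn_signal <- function(x, ...) {
  tibble(t_ms = (seq_along(x$samples) - 1) * 1000 / x$fs,
         value = x$samples)
}

#' @rdname wn_signal
#' @param x A `wn_signal`.
#' @export
standardize_signal <- function(x) {
  stopifnot(inherits(x, "wn_signal"))
  v <- var(x$samples)
  if (!is.finite(v) || v <= 0) {
    abort("Cannot standardize a constant signal.",
          class = "spikecoder_degenerate_signal")
  }
  s <- (x$samples - mean(x$samples)) / sqrt(v)
  new_wn_signal(s, x$fs, x$duration_s, x$tau_ms, x$seed, standardized = TRUE)
}

#' Scale a 0-1 stimulus to light power
#'
#' Maps the scaled waveform to instantaneous light power
#' `P(t) = mu + x(t) * sigma_power` (microwatts). Any non-positive output
#' sample is an error: the offset must be chosen so the commanded power is
#' strictly positive throughout.
#'
#' @param x A `wn_signal`.
#' @param mu Power offset (uW).
#' @param sigma_power Power scale (uW).
#' @return A `power_trace`: list with `samples` (uW), `mu`, `sigma_power`,
#'   and the source `wn_signal`.
#' @export
scale_power <- function(x, mu, sigma_power) {
  stopifnot(inherits(x, "wn_signal"))
  p <- mu + x$samples * sigma_power
  if (any(p <= 0)) {
    abort(sprintf(
      "Power trace has %d non-positive sample(s); increase `mu`.",
      sum(p <= 0)), class = "spikecoder_invalid_power")
  }
  structure(list(samples = p, mu = mu, sigma_power = sigma_power,
                 source_trace = x),
            class = "power_trace")
}

#' @export
print.power_trace <- function(x, ...) {
  cat(sprintf("<power_trace> mu = %g uW, sigma = %g uW, range [%.3g, %.3g] uW\n",
              x$mu, x$sigma_power, min(x$samples), max(x$samples)))
  invisible(x)
}

# Resample a signal to a new rate by linear interpolation on the time grid.
# Used to move the 6 kHz stimulus onto the analysis/simulation grid.
resample_signal <- function(x, fs_new) {
  stopifnot(inherits(x, "wn_signal"))
  if (fs_new == x$fs) return(x)
  n_new <- round(fs_new * x$duration_s)
  t_old <- (seq_along(x$samples) - 1) / x$fs
  t_new <- (seq_len(n_new) - 1) / fs_new
  s <- approx(t_old, x$samples, xout = t_new, rule = 2)$y
  new_wn_signal(s, fs_new, x$duration_s, x$tau_ms, x$seed, x$standardized)
}

# Standardized copy of `x` on the analysis grid.
analysis_signal <- function(x, fs_analysis = 2500) {
  standardize_signal(resample_signal(x, fs_analysis))
}

#' Read and write stimulus traces
#'
#' Two-column TSV `t_ms<TAB>value` with a header comment line carrying
#' `fs_hz`, `tau_ms`, `seed` and `standardized`. The round trip is lossless
#' to better than 1e-9 (values written with 17 significant digits).
#'
#' @param x A `wn_signal`.
#' @param path File path.
#' @export
write_signal_tsv <- function(x, path) {
  stopifnot(inherits(x, "wn_signal"))
  hdr <- sprintf("# fs_hz=%d tau_ms=%.17g seed=%d standardized=%d",
                 as.integer(x$fs), x$tau_ms, as.integer(x$seed),
                 as.integer(x$standardized))
  t_ms <- (seq_along(x$samples) - 1) * 1000 / x$fs
  lines <- c(hdr, "t_ms\tvalue",
             sprintf("%.17g\t%.17g", t_ms, x$samples))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @export
read_signal_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  get_num <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-0-9.eE+]+"), hdr))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  fs <- get_num("fs_hz")
  tau <- get_num("tau_ms")
  seed <- get_num("seed")
  std <- get_num("standardized") == 1
  body <- utils::read.delim(text = lines[-1], sep = "\t")
  samples <- body$value
  new_wn_signal(samples, fs, length(samples) / fs, tau, as.integer(seed),
                standardized = std)
}
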