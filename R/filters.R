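#' Reconstruction filter models
#'
#' A `filter_model` holds a lag axis spanning `[-window, +window]` ms, a
#' coefficient matrix (one row for simple filters, `n_bins` rows for
#' ISI-conditional banks), the causality flag and the analysis rate. Six
#' structural kinds are supported -- `"sta"`, `"csta"` (ISI-conditional
#' STA), `"wiener"` / `"cwiener"` (STA on the whitened signal),
#' `"mwiener"` / `"cmwiener"` (STA deconvolved by the spike-train
#' autocorrelogram) -- each in a causal and an acausal variant, giving the
#' twelve filter models, plus `"pwsta"` / `"cpwsta"` which share the Wiener
#' filter but gauge reconstructions against the whitened signal.
#'
#' @name filter_model
NULL

FILTER_KINDS <- c("sta", "csta", "wiener", "cwiener", "mwiener", "cmwiener",
                  "pwsta", "cpwsta")

#' Enumerate the twelve filter models
#'
#' @return A tibble with columns `kind` and `causal`, one row per model.
#' @export
filter_kinds <- function() {
  tidyr_expand <- expand.grid(
    kind = c("sta", "csta", "wiener", "cwiener", "mwiener", "cmwiener"),
    causal = c(FALSE, TRUE), stringsAsFactors = FALSE)
  as_tibble(tidyr_expand[order(tidyr_expand$kind), ])
}

new_filter_model <- function(kind, causal, lags_ms, coefficients,
                             isi_bin_edges = NULL, fs_analysis = 2500,
                             residual = NA_real_, bin_weights = NULL) {
  if (is.null(dim(coefficients))) {
    coefficients <- matrix(coefficients, nrow = 1)
  }
  structure(list(kind = kind, causal = causal, lags_ms = lags_ms,
                 coefficients = coefficients, isi_bin_edges = isi_bin_edges,
                 fs_analysis = fs_analysis, residual = residual,
                 bin_weights = bin_weights),
            class = "filter_model")
}

#' @export
print.filter_model <- function(x, ...) {
  cat(sprintf("<filter_model> %s (%s), %d lag(s) in [%g, %g] ms, %d row(s)\n",
              x$kind, if (x$causal) "causal" else "acausal",
              length(x$lags_ms), min(x$lags_ms), max(x$lags_ms),
              nrow(x$coefficients)))
  invisible(x)
}

#' @export
tidy.filter_model <- function(x, ...) {
  nb <- nrow(x$coefficients)
  tibble(bin = rep(seq_len(nb), each = length(x$lags_ms)),
         lag_ms = rep(x$lags_ms, nb),
         coefficient = as.vector(t(x$coefficients)))
}

#' @export
autoplot.filter_model <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(.data$lag_ms, .data$coefficient,
                                   group = .data$bin,
                                   colour = factor(.data$bin))) +
    ggplot2::geom_line(show.legend = nrow(object$coefficients) > 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "lag (ms)", y = "coefficient", colour = "ISI bin") +
    ggplot2::theme_minimal()
}

lag_axis <- function(fs, window_ms) {
  half <- round(window_ms * fs / 1000)
  (seq_len(2L * half + 1L) - half - 1L) * 1000 / fs
}

# Pooled spikes of a set of trials (times stay trial-relative; every trial
# sees the same stimulus, so segments are drawn from the shared signal).
pool_spikes <- function(trials) unlist(trials, use.names = FALSE) %||% numeric(0)

#' Spike-triggered average filter
#'
#' Averages standardized-signal segments in a `window_ms` window around
#' every spike (segments exceeding the trial edge are zero-padded).
#'
#' @param x The stimulus (`wn_signal`); standardized and resampled to
#'   `fs_analysis` internally.
#' @param spikes A [spike_trains()] object or tidy spike table.
#' @param window_ms Half-window (ms); lags span `[-window_ms, window_ms]`.
#' @param fs_analysis Analysis sampling rate (Hz).
#' @return A `filter_model` of kind `"sta"` (acausal).
#' @export
compute_sta <- function(x, spikes, window_ms = 50, fs_analysis = 2500) {
  spikes <- as_spike_trains(spikes)
  z <- analysis_signal(x, fs_analysis)
  half <- round(window_ms * fs_analysis / 1000)
  ts <- pool_spikes(spikes$trials)
  if (length(ts) == 0L) {
    abort("No spikes available for the STA.",
          class = "spikecoder_insufficient_data")
  }
  coefs <- cpp_sta(ts, z$samples, fs_analysis, half)
  new_filter_model("sta", FALSE, lag_axis(fs_analysis, window_ms), coefs,
                   fs_analysis = fs_analysis)
}

#' Causal restriction of a filter
#'
#' Zeroes every coefficient at positive lags (signal after the spike),
#' leaving non-positive lags untouched.
#'
#' @param filter A `filter_model`.
#' @export
make_causal <- function(filter) {
  stopifnot(inherits(filter, "filter_model"))
  filter$coefficients[, filter$lags_ms > 0] <- 0
  filter$causal <- TRUE
  filter
}

# Per-trial ISI vectors aligned with spike times. The first spike of a
# trial inherits the interval to the last spike of the previous trial
# (wrapped across the inter-trial gap of zero); if unavailable it is NA and
# later assigned to the top decile.
trial_isis <- function(trials, duration_ms) {
  prev_last <- NA_real_
  out <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    t <- trials[[i]]
    if (length(t) == 0L) { out[[i]] <- numeric(0); next }
    first <- if (is.na(prev_last)) NA_real_ else t[1] + duration_ms - prev_last
    out[[i]] <- c(first, diff(t))
    prev_last <- t[length(t)]
  }
  out
}

isi_bin_edges <- function(isis, n_bins = 10) {
  v <- isis[!is.na(isis)]
  if (length(v) < n_bins) {
    abort("Too few ISIs to form equally-populated bins.",
          class = "spikecoder_insufficient_data")
  }
  edges <- unname(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
  if (any(diff(edges) <= 0)) {
    bad <- which(diff(edges) <= 0)[1]
    abort(sprintf("ISI decile %d is empty (tied interval values).", bad),
          class = "spikecoder_insufficient_data")
  }
  edges
}

assign_isi_bins <- function(isis, edges) {
  n_bins <- length(edges) - 1L
  b <- findInterval(isis, edges, rightmost.closed = TRUE, all.inside = TRUE)
  b[is.na(isis)] <- n_bins
  b
}

#' ISI-conditional STA filter bank
#'
#' Tags every spike by the decile of its preceding inter-spike interval
#' (ten equally-populated bins) and computes one STA per bin.
#'
#' @inheritParams compute_sta
#' @param n_bins Number of equally-populated ISI bins.
#' @return A `filter_model` of kind `"csta"` with an `n_bins`-row bank and
#'   the ISI bin edges.
#' @export
conditional_filter_bank <- function(x, spikes, n_bins = 10, window_ms = 50,
                                    fs_analysis = 2500) {
  spikes <- as_spike_trains(spikes)
  z <- analysis_signal(x, fs_analysis)
  half <- round(window_ms * fs_analysis / 1000)
  isis <- trial_isis(spikes$trials, spikes$duration_ms)
  ts <- pool_spikes(spikes$trials)
  iv <- unlist(isis, use.names = FALSE) %||% numeric(0)
  edges <- isi_bin_edges(iv, n_bins)
  bins <- assign_isi_bins(iv, edges)
  coefs <- matrix(0, n_bins, 2L * half + 1L)
  wts <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    sel <- bins == b
    wts[b] <- sum(sel)
    if (wts[b] == 0L) {
      abort(sprintf("ISI bin %d has no spikes.", b),
            class = "spikecoder_insufficient_data")
    }
    coefs[b, ] <- cpp_sta(ts[sel], z$samples, fs_analysis, half)
  }
  new_filter_model("csta", FALSE, lag_axis(fs_analysis, window_ms), coefs,
                   isi_bin_edges = edges, fs_analysis = fs_analysis,
                   bin_weights = wts)
}

#' Whiten a stimulus by its lag-window covariance
#'
#' Builds the Toeplitz autocovariance matrix over the filter lag window,
#' eigendecomposes it, retains the smallest leading set of eigenvalues
#' whose cumulative share reaches `var_fraction`, and filters the signal
#' with the centre row of the pseudo square-root-inverse projection
#' (eigenvalues below zero are floored at zero with a warning). For white
#' input the operator is close to the identity.
#'
#' @param x A `wn_signal` (standardized internally).
#' @param var_fraction Minimum cumulative variance share retained.
#' @param window_ms Half-window (ms) defining the covariance dimension.
#' @param fs_analysis Analysis rate (Hz).
#' @return A standardized `wn_signal` carrying attributes `n_retained` and
#'   `whitened = TRUE`.
#' @export
whiten_signal <- function(x, var_fraction = 0.9, window_ms = 50,
                          fs_analysis = 2500) {
  z <- analysis_signal(x, fs_analysis)
  half <- round(window_ms * fs_analysis / 1000)
  acv <- drop(stats::acf(z$samples, lag.max = 2L * half, type = "covariance",
                         plot = FALSE, demean = TRUE)$acf)
  C <- toeplitz(acv[seq_len(2L * half + 1L)])
  eig <- eigen(C, symmetric = TRUE)
  lam <- eig$values
  if (any(lam < 0)) {
    warn("Covariance matrix is numerically non-PSD; negative eigenvalues floored at 0.")
    lam[lam < 0] <- 0
  }
  share <- cumsum(lam) / sum(lam)
  k <- which(share >= var_fraction)[1]
  keep <- seq_len(k)
  Vk <- eig$vectors[, keep, drop = FALSE]
  M <- Vk %*% (t(Vk) / sqrt(lam[keep]))
  kern <- M[half + 1L, ]
  wh <- conv_same(z$samples, kern)
  out <- new_wn_signal(wh, fs_analysis, z$duration_s, z$tau_ms, z$seed,
                       standardized = TRUE)
  out$samples <- (out$samples - mean(out$samples)) / sd(out$samples)
  attr(out, "whitened") <- TRUE
  attr(out, "n_retained") <- k
  out
}

# Spike-train autocovariance-style correlogram on the analysis grid over
# the filter lag window, per trial (differences never cross trial
# boundaries). The zero-lag bin carries the self-coincidence mass (one
# count per spike) and the flat chance level n^2 * bin / T is subtracted
# per trial, so the Toeplitz operator of a Poisson train is close to a
# scaled identity and the deconvolution leaves its STA untouched.
ach_counts <- function(trials, fs, window_ms, duration_ms = NULL) {
  bin <- 1000 / fs
  nb <- round(window_ms / bin)
  total <- numeric(2L * nb + 1L)
  chance <- 0
  for (t in trials) {
    if (length(t) > 0) {
      total <- total + cpp_cch(t, t, bin, window_ms)
      if (!is.null(duration_ms)) {
        chance <- chance + length(t)^2 * bin / duration_ms
      }
    }
  }
  total <- total - chance
  # enforce exact symmetry
  (total + rev(total)) / 2
}

# Regularized symmetric solve: eigenvalues below floor_frac * max dropped.
reg_solve <- function(A, b, floor_frac = 1e-6) {
  eig <- eigen(A, symmetric = TRUE)
  lam <- eig$values
  thr <- floor_frac * max(lam)
  keep <- lam > thr
  if (!any(keep)) {
    abort("Autocorrelation matrix is singular after regularization.",
          class = "spikecoder_numeric_error")
  }
  Vk <- eig$vectors[, keep, drop = FALSE]
  x <- Vk %*% ((t(Vk) %*% b) / lam[keep])
  drop(x)
}

#' Modified Wiener filter
#'
#' Deconvolves the spike-train autocorrelogram from the STA: the ACH over
#' the same lag range is arranged as a symmetric Toeplitz matrix `A` and
#' the filter solves `A w = s` by a regularized pseudo-inverse (eigenvalue
#' floor at `1e-6` of the leading eigenvalue). This corrects the STA for
#' temporal structure in the unit's own output (bursts, refractoriness).
#'
#' @param sta A `filter_model` (kind `"sta"` or `"csta"`); each bank row is
#'   deconvolved by the same ACH operator.
#' @param spikes The spike trains whose ACH is used (the trains recorded
#'   during the stimulus).
#' @return A `filter_model` of kind `"mwiener"` (or `"cmwiener"`), with the
#'   relative residual of the solve in `$residual`.
#' @export
modified_wiener <- function(sta, spikes) {
  stopifnot(inherits(sta, "filter_model"))
  spikes <- as_spike_trains(spikes)
  fs <- sta$fs_analysis
  window_ms <- max(sta$lags_ms)
  # the Toeplitz operator over 2*half+1 lags needs the ACH out to twice
  # the filter window
  ach <- ach_counts(spikes$trials, fs, 2 * window_ms,
                    duration_ms = spikes$duration_ms)
  centre <- (length(ach) + 1L) %/% 2L
  half <- round(window_ms * fs / 1000)
  a0 <- ach[centre]
  A <- toeplitz(ach[centre:(centre + 2L * half)] / a0)
  W <- sta$coefficients
  resid <- 0
  for (r in seq_len(nrow(W))) {
    s <- sta$coefficients[r, ]
    w <- reg_solve(A, s)
    W[r, ] <- w
    num <- sqrt(sum((A %*% w - s)^2))
    den <- sqrt(sum(s^2))
    resid <- max(resid, if (den > 0) num / den else 0)
  }
  kind <- if (nrow(W) > 1) "cmwiener" else "mwiener"
  new_filter_model(kind, sta$causal, sta$lags_ms, W,
                   isi_bin_edges = sta$isi_bin_edges, fs_analysis = fs,
                   residual = resid, bin_weights = sta$bin_weights)
}
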