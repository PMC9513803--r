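# Cross-validated stimulus reconstruction and decoding quality.

# Fit one filter model from a set of training trials. `zs` is the
# standardized signal, `zw` its whitened version (NULL unless needed).
fit_fold_filter <- function(kind, causal, zs, zw, trials, isis, fs,
                            window_ms, n_bins = 10) {
  half <- round(window_ms * fs / 1000)
  zbase <- if (kind %in% c("wiener", "cwiener", "pwsta", "cpwsta"))
    zw$samples else zs$samples
  conditional <- kind %in% c("csta", "cwiener", "cmwiener", "cpwsta")
  ts <- pool_spikes(trials)
  if (length(ts) == 0L) {
    abort("Training set has no spikes.",
          class = "spikecoder_insufficient_data")
  }
  if (conditional) {
    iv <- unlist(isis, use.names = FALSE)
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
      coefs[b, ] <- cpp_sta(ts[sel], zbase, fs, half)
    }
  } else {
    edges <- NULL
    wts <- length(ts)
    coefs <- matrix(cpp_sta(ts, zbase, fs, half), nrow = 1)
  }
  fm <- new_filter_model(kind, FALSE, lag_axis(fs, window_ms), coefs,
                         isi_bin_edges = edges, fs_analysis = fs,
                         bin_weights = wts)
  if (kind %in% c("mwiener", "cmwiener")) {
    fm <- modified_wiener(fm, structure(
      list(unit_id = "train", trials = trials, n_trials = length(trials),
           duration_ms = zs$duration_s * 1000), class = "spike_trains"))
    fm$kind <- kind
  }
  if (causal) fm <- make_causal(fm)
  fm
}

# Prepare everything needed to decode (and re-decode) each trial:
# per-trial training filter + the rank vector of the gauge signal.
crossval_fit <- function(x, spikes, kind = "mwiener", causal = FALSE,
                         n_folds = 10, fs_analysis = 2500, window_ms = 50,
                         var_fraction = 0.9, n_bins = 10) {
  kind <- match.arg(kind, FILTER_KINDS)
  spikes <- as_spike_trains(spikes)
  n_trials <- spikes$n_trials
  if (n_trials < n_folds || n_folds < 2) {
    abort("Need `n_trials` >= `n_folds` >= 2.",
          class = "spikecoder_invalid_parameter")
  }
  zs <- analysis_signal(x, fs_analysis)
  needs_wh <- kind %in% c("wiener", "cwiener", "pwsta", "cpwsta")
  zw <- if (needs_wh) whiten_signal(x, var_fraction, window_ms, fs_analysis)
        else NULL
  # gauge: the signal the reconstruction is compared against. Wiener
  # filters are gauged against the plain standardized signal (their use of
  # a whitened filter is deliberately penalized); the pre-whitened STA
  # variants gauge against the whitened signal.
  zg <- if (kind %in% c("pwsta", "cpwsta")) zw else zs
  isis <- trial_isis(spikes$trials, spikes$duration_ms)
  fold_of <- sort(rep_len(seq_len(n_folds), n_trials))
  filters <- vector("list", n_trials)
  for (f in seq_len(n_folds)) {
    train_idx <- which(fold_of != f)
    fm <- fit_fold_filter(kind, causal, zs, zw, spikes$trials[train_idx],
                          isis[train_idx], fs_analysis, window_ms, n_bins)
    for (i in which(fold_of == f)) filters[[i]] <- fm
  }
  structure(list(spikes = spikes, kind = kind, causal = causal,
                 n_folds = n_folds, fs = fs_analysis,
                 window_ms = window_ms, n = length(zs$samples),
                 zg_rank = cpp_rank(zg$samples), filters = filters,
                 isis = isis, fold_of = fold_of),
            class = "crossval_fit")
}

rows_for <- function(fm, times, prev_last, duration_ms) {
  if (is.null(fm$isi_bin_edges)) return(1L)
  isi <- c(if (is.na(prev_last)) NA_real_ else
             times[1] + duration_ms - prev_last,
           diff(times))
  as.integer(assign_isi_bins(isi, fm$isi_bin_edges))
}

# Decode arbitrary spike times for trial `i` with its held-out filter.
decode_trial_q <- function(fit, i, times, prev_last = NA_real_) {
  fm <- fit$filters[[i]]
  if (length(times) == 0L) return(NA_real_)
  rows <- rows_for(fm, times, prev_last, fit$spikes$duration_ms)
  recon <- cpp_recon(times, fm$coefficients, rows, fit$fs, fit$n)
  cpp_spearman(fit$zg_rank, recon)
}

# Decode a full list of per-trial spike trains (one q per trial), batched
# per fold so every trial uses its held-out training filter.
decode_trials_q <- function(fit, trains) {
  n_trials <- length(trains)
  q <- rep(NA_real_, n_trials)
  dur <- fit$spikes$duration_ms
  for (f in unique(fit$fold_of)) {
    idx <- which(fit$fold_of == f)
    fm <- fit$filters[[idx[1]]]
    rows <- lapply(idx, function(i) {
      if (length(trains[[i]]) == 0L) return(1L)
      rows_for(fm, trains[[i]], prev_trial_last(trains, i), dur)
    })
    q[idx] <- cpp_decode_many(trains[idx], rows, fm$coefficients, fit$fs,
                              fit$n, fit$zg_rank)
  }
  q
}

prev_trial_last <- function(trials, i) {
  if (i <= 1L || length(trials[[i - 1L]]) == 0L) NA_real_
  else trials[[i - 1L]][length(trials[[i - 1L]])]
}

#' Cross-validated stimulus reconstruction and decoding quality
#'
#' Partitions trials into folds, fits the chosen filter model on the
#' training trials of each fold, reconstructs the stimulus of every test
#' trial by convolving its spike train with the training filter (each
#' spike of a conditional model uses its ISI-bin row), and scores each
#' trial by the Spearman rank correlation between the (standardized)
#' stimulus and the reconstruction. Per-trial significance comes from
#' redrawing the test-trial spike times uniformly within the trial and
#' recomputing the correlation; the empirical p value is
#' `(1 + #(shuffled q >= q)) / (n_shuffles + 1)` so that it is never zero.
#' The overall quality `Q` is the mean of the per-trial `q`, and the
#' overall p value the geometric mean of the per-trial p values.
#'
#' @inheritParams compute_sta
#' @param kind Filter model kind; see [filter_kinds()].
#' @param causal Zero the filter at positive lags before decoding.
#' @param n_folds Number of cross-validation folds.
#' @param n_shuffles Within-trial spike-time shuffles per trial for the
#'   empirical p value (0 skips significance testing).
#' @param var_fraction Variance share retained when whitening (Wiener
#'   kinds).
#' @param seed Seed for the shuffles.
#' @return A `decoding` object; see [tidy.decoding()] / `glance()`.
#' @export
crossval_decode <- function(x, spikes, kind = "mwiener", causal = FALSE,
                            n_folds = 10, n_shuffles = 100,
                            fs_analysis = 2500, window_ms = 50,
                            var_fraction = 0.9, seed = 1) {
  fit <- crossval_fit(x, spikes, kind, causal, n_folds, fs_analysis,
                      window_ms, var_fraction)
  trials <- fit$spikes$trials
  n_trials <- fit$spikes$n_trials
  dur <- fit$spikes$duration_ms
  q <- rep(NA_real_, n_trials)
  p <- rep(NA_real_, n_trials)
  for (i in seq_len(n_trials)) {
    prev <- prev_trial_last(trials, i)
    q[i] <- decode_trial_q(fit, i, trials[[i]], prev)
    if (!is.na(q[i]) && n_shuffles > 0) {
      m <- length(trials[[i]])
      qs <- with_seed(derive_seed(seed, 7, i), {
        vapply(seq_len(n_shuffles), function(s) {
          decode_trial_q(fit, i, sort(runif(m, 0, dur)), prev)
        }, numeric(1))
      })
      p[i] <- (1 + sum(qs >= q[i])) / (n_shuffles + 1)
    }
  }
  ok <- !is.na(q)
  mean_filter <- pooled_filter(fit)
  peak_lag <- mean_filter$lags_ms[which.max(mean_filter$coefs)]
  structure(list(
    unit_id = fit$spikes$unit_id, kind = kind, causal = causal,
    n_folds = n_folds,
    q_trials = q, Q = mean(q[ok]),
    p_trials = p,
    p_overall = if (n_shuffles > 0 && any(ok)) exp(mean(log(p[ok]))) else NA_real_,
    time_lag_ms = -peak_lag,
    n_excluded = sum(!ok),
    residual = {
      vals <- vapply(fit$filters, function(f) f$residual, numeric(1))
      if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
    },
    fit = fit),
    class = "decoding")
}

# Spike-count-weighted mean filter across folds and bank rows, used for
# the time-lag readout.
pooled_filter <- function(fit) {
  acc <- 0
  for (i in seq_along(fit$filters)) {
    fm <- fit$filters[[i]]
    w <- fm$bin_weights / sum(fm$bin_weights)
    acc <- acc + colSums(fm$coefficients * w)
  }
  list(lags_ms = fit$filters[[1]]$lags_ms, coefs = acc / length(fit$filters))
}

#' @export
print.decoding <- function(x, ...) {
  cat(sprintf(
    "<decoding> unit %s, %s%s: Q = %.3f (p = %.3g), time lag = %.1f ms, %d-fold\n",
    x$unit_id, if (x$causal) "causal " else "", x$kind, x$Q,
    x$p_overall, x$time_lag_ms, x$n_folds))
  invisible(x)
}

#' Tidy a decoding result
#'
#' @param x A `decoding` object.
#' @param ... Unused.
#' @return `tidy()`: per-trial tibble (`trial`, `q`, `p`); `glance()`:
#'   one-row summary (`Q`, `p_overall`, `time_lag_ms`, ...).
#' @export
tidy.decoding <- function(x, ...) {
  tibble(unit_id = x$unit_id, trial = seq_along(x$q_trials),
         q = x$q_trials, p = x$p_trials)
}

#' @rdname tidy.decoding
#' @export
glance.decoding <- function(x, ...) {
  tibble(unit_id = x$unit_id, kind = x$kind, causal = x$causal,
         Q = x$Q, p_overall = x$p_overall, time_lag_ms = x$time_lag_ms,
         n_folds = x$n_folds, n_excluded = x$n_excluded,
         residual = x$residual)
}

#' @export
autoplot.decoding <- function(object, ...) {
  pf <- pooled_filter(object$fit)
  tb <- tibble(lag_ms = pf$lags_ms, coefficient = pf$coefs)
  ggplot2::ggplot(tb, ggplot2::aes(.data$lag_ms, .data$coefficient)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "lag (ms)", y = "mean filter coefficient",
      title = sprintf("unit %s: Q = %.3f, lag %.1f ms", object$unit_id,
                      object$Q, object$time_lag_ms)) +
    ggplot2::theme_minimal()
}

#' Serialize a decoding result to JSON
#'
#' @param x A `decoding` object.
#' @param path Output path.
#' @export
write_decoding_json <- function(x, path) {
  obj <- list(unit_id = x$unit_id, kind = x$kind, causal = x$causal,
              Q = x$Q, p = x$p_overall, time_lag_ms = x$time_lag_ms,
              q_trials = x$q_trials, residual = x$residual)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
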