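#' Count cross-correlation histogram between two units
#'
#' Counts spike-time differences `post - pre` in bins of `bin_ms`
#' (default 0.4 ms) centred on multiples of the bin width and spanning
#' `+/- half_range_ms`; bin membership is half-open `[c - bin/2, c + bin/2)`.
#' The baseline is a centred running median of the counts (reflected
#' edges), the null expectation for the Poisson peak test.
#'
#' @param pre,post Sorted spike times (ms) of the putative pre- and
#'   postsynaptic unit, taken from no-stimulus epochs.
#' @param bin_ms Bin width (ms).
#' @param half_range_ms Half range (ms).
#' @param median_window Baseline running-median window, in bins (odd).
#' @param pre_id,post_id Unit labels.
#' @return A `cch` object with integer `counts`, `lags_ms`, `baseline`.
#' @export
compute_cch <- function(pre, post, bin_ms = 0.4, half_range_ms = 50,
                        median_window = 25, pre_id = "pre",
                        post_id = "post") {
  if (length(pre) == 0L) {
    abort("Presynaptic train is empty.",
          class = "spikecoder_insufficient_data")
  }
  pre <- sort(as.numeric(pre)); post <- sort(as.numeric(post))
  counts <- cpp_cch(pre, post, bin_ms, half_range_ms)
  nb <- (length(counts) - 1L) %/% 2L
  lags <- (-nb:nb) * bin_ms
  baseline <- running_median_reflect(as.numeric(counts), median_window)
  structure(list(pre_id = pre_id, post_id = post_id, bin_ms = bin_ms,
                 lags_ms = lags, counts = counts, baseline = baseline,
                 n_pre_spikes = length(pre), median_window = median_window),
            class = "cch")
}

running_median_reflect <- function(x, window) {
  stopifnot(window %% 2 == 1)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  pad <- c(rev(x[2:(h + 1L)]), x, rev(x[(n - h):(n - 1L)]))
  vapply(seq_len(n), function(i) median(pad[i:(i + window - 1L)]),
         numeric(1))
}

#' @export
print.cch <- function(x, ...) {
  cat(sprintf("<cch> %s -> %s: %d bins of %g ms, %d pre spikes, %d pairs\n",
              x$pre_id, x$post_id, length(x$counts), x$bin_ms,
              x$n_pre_spikes, sum(x$counts)))
  invisible(x)
}

#' @export
tidy.cch <- function(x, ...) {
  tibble(pre_id = x$pre_id, post_id = x$post_id, lag_ms = x$lags_ms,
         count = as.integer(x$counts), baseline = x$baseline)
}

#' @export
autoplot.cch <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(.data$lag_ms, .data$count)) +
    ggplot2::geom_col(width = object$bin_ms) +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline), colour = "red") +
    ggplot2::labs(x = "lag (ms)", y = "count",
                  title = sprintf("%s → %s", object$pre_id,
                                  object$post_id)) +
    ggplot2::theme_minimal()
}

roi_bins <- function(cch, roi_ms = c(0, 5.2)) {
  which(cch$lags_ms > roi_ms[1] & cch$lags_ms <= roi_ms[2])
}

#' Poisson test for a monosynaptic CCH peak
#'
#' Tests each bin of the monosynaptic region of interest (lags in
#' `(0, 5.2]` ms, i.e. 13 bins of 0.4 ms) against the running-median
#' baseline with an upper-tail Poisson test, Bonferroni-corrected by the
#' number of ROI bins. The pair is flagged significant when the smallest
#' corrected p value is below `alpha`.
#'
#' @param cch A [compute_cch()] result.
#' @param alpha Detection level (0.001 by default, stricter than the
#'   package-wide 0.05).
#' @param roi_ms ROI lag limits (ms), half-open on the left.
#' @return A list with `significant`, `p` (min corrected p), `p_bins`,
#'   `peak_lag_ms`.
#' @export
test_monosynaptic <- function(cch, alpha = 0.001, roi_ms = c(0, 5.2)) {
  stopifnot(inherits(cch, "cch"))
  roi <- roi_bins(cch, roi_ms)
  lam <- cch$baseline[roi]
  if (all(lam <= 0)) {
    abort("Baseline is zero throughout the ROI; Poisson test undefined.",
          class = "spikecoder_undefined_test")
  }
  obs <- as.numeric(cch$counts[roi])
  p_raw <- ppois(obs - 1, pmax(lam, .Machine$double.eps),
                 lower.tail = FALSE)
  p_adj <- pmin(p_raw * length(roi), 1)
  best <- which.min(p_adj)
  list(significant = min(p_adj) < alpha, p = min(p_adj), p_bins = p_adj,
       peak_lag_ms = cch$lags_ms[roi][best], alpha = alpha)
}

#' Spike-transmission curve and gain from a CCH
#'
#' Deconvolves the count CCH (and its running-median baseline) by the
#' presynaptic spike-train autocorrelogram -- arranged as a normalized
#' symmetric Toeplitz matrix and inverted with the shared regularized
#' solver -- and converts the difference to an excess postsynaptic rate in
#' spikes/s (dividing by the presynaptic spike count and the bin width).
#' The transmission gain is the area under the excess-rate peak inside the
#' monosynaptic region of interest, extended to the nearest zero
#' crossings, and reads as the expected number of extra postsynaptic
#' spikes per presynaptic spike.
#'
#' @param cch A [compute_cch()] result.
#' @param pre_ach Optional autocorrelogram counts of the presynaptic
#'   train, covering twice the CCH lag range (i.e.
#'   `compute_cch(pre, pre, bin_ms, 2 * half_range_ms)$counts`, which
#'   keeps the self-coincidence mass at zero lag). When `NULL` the
#'   presynaptic train is treated as Poisson (identity deconvolution).
#' @param alpha Detection level passed to [test_monosynaptic()].
#' @param roi_ms Monosynaptic ROI (ms).
#' @return A `transmission_curve` object with `excess_rate` (spikes/s per
#'   lag), `gain`, `peak_lag_ms`, `support_ms`, `significant`, `p`.
#' @export
transmission_curve <- function(cch, pre_ach = NULL, alpha = 0.001,
                               roi_ms = c(0, 5.2)) {
  stopifnot(inherits(cch, "cch"))
  nb <- (length(cch$counts) - 1L) %/% 2L
  if (is.null(pre_ach)) {
    dc <- as.numeric(cch$counts) / cch$n_pre_spikes
    db <- cch$baseline / cch$n_pre_spikes
  } else {
    # the Toeplitz operator over the CCH lag grid needs ACH lags out to
    # twice the half range: pre_ach must come from
    # compute_cch(pre, pre, bin_ms, 2 * half_range_ms)
    if (length(pre_ach) != 2L * length(cch$counts) - 1L) {
      abort("`pre_ach` must cover twice the CCH lag range (4 * nb + 1 bins).",
            class = "spikecoder_invalid_parameter")
    }
    ach <- (as.numeric(pre_ach) + rev(as.numeric(pre_ach))) / 2
    centre <- 2L * nb + 1L
    A <- toeplitz(ach[centre:(centre + 2L * nb)] / ach[centre])
    dc <- reg_solve(A, as.numeric(cch$counts)) / cch$n_pre_spikes
    db <- reg_solve(A, cch$baseline) / cch$n_pre_spikes
  }
  bin_s <- cch$bin_ms / 1000
  excess <- (dc - db) / bin_s
  test <- test_monosynaptic(cch, alpha, roi_ms)
  roi <- roi_bins(cch, roi_ms)
  peak <- roi[which.max(excess[roi])]
  # causal support: extend from the peak to the nearest non-positive
  # excess on each side
  left <- peak
  while (left > 1 && excess[left - 1L] > 0) left <- left - 1L
  right <- peak
  while (right < length(excess) && excess[right + 1L] > 0)
    right <- right + 1L
  support <- left:right
  gain <- sum(excess[support]) * bin_s
  structure(list(pre_id = cch$pre_id, post_id = cch$post_id,
                 lags_ms = cch$lags_ms, excess_rate = excess, gain = gain,
                 peak_lag_ms = cch$lags_ms[peak],
                 support_ms = cch$lags_ms[c(left, right)],
                 roi_ms = roi_ms, significant = test$significant,
                 p = test$p, bin_ms = cch$bin_ms),
            class = "transmission_curve")
}

#' @export
print.transmission_curve <- function(x, ...) {
  cat(sprintf(
    "<transmission_curve> %s -> %s: gain = %.4f, peak %.1f ms, p = %.3g%s\n",
    x$pre_id, x$post_id, x$gain, x$peak_lag_ms, x$p,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' @export
tidy.transmission_curve <- function(x, ...) {
  tibble(pre_id = x$pre_id, post_id = x$post_id, lag_ms = x$lags_ms,
         excess_rate = x$excess_rate)
}

#' @export
glance.transmission_curve <- function(x, ...) {
  tibble(pre_id = x$pre_id, post_id = x$post_id, gain = x$gain,
         peak_lag_ms = x$peak_lag_ms, p = x$p,
         significant = x$significant,
         support_left_ms = x$support_ms[1],
         support_right_ms = x$support_ms[2])
}

#' @export
autoplot.transmission_curve <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(.data$lag_ms, .data$excess_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$roi_ms, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "lag (ms)", y = "excess rate (spikes/s)",
                  title = sprintf("%s → %s: gain %.4f", object$pre_id,
                                  object$post_id, object$gain)) +
    ggplot2::theme_minimal()
}

#' Connection probability of a postsynaptic unit
#'
#' Fraction of simultaneously recorded candidate presynaptic units within
#' a distance range that are connected: the number of presynaptic partners
#' divided by the number of candidates within `range_um` (Euclidean
#' distance over probe coordinates).
#'
#' @param units A data frame with columns `unit_id`, `x_um`, `y_um` and a
#'   logical `is_candidate` marking candidate presynaptic units (e.g.
#'   pyramidal cells).
#' @param post_id The postsynaptic unit.
#' @param presyn_ids Unit ids with a detected connection onto `post_id`.
#' @param range_um Inclusion radius (micrometres).
#' @return A one-row tibble with `n_presyn`, `n_in_range`, `probability`
#'   (`NA` when no candidate lies in range).
#' @export
connection_probability <- function(units, post_id, presyn_ids,
                                   range_um = 600) {
  stopifnot(all(c("unit_id", "x_um", "y_um") %in% names(units)))
  post <- units[units$unit_id == post_id, , drop = FALSE]
  if (nrow(post) != 1) abort("`post_id` must match exactly one unit.")
  cand <- units[units$unit_id != post_id, , drop = FALSE]
  if ("is_candidate" %in% names(units)) {
    cand <- cand[cand$is_candidate, , drop = FALSE]
  }
  d <- sqrt((cand$x_um - post$x_um)^2 + (cand$y_um - post$y_um)^2)
  in_range <- cand$unit_id[d <= range_um]
  n_in <- length(in_range)
  n_pre <- sum(presyn_ids %in% in_range)
  tibble(post_id = post_id, n_presyn = n_pre, n_in_range = n_in,
         probability = if (n_in > 0) n_pre / n_in else NA_real_)
}

#' Write a pair table as TSV
#'
#' Columns `pre_id`, `post_id`, `gain`, `peak_lag_ms`, `p`, `significant`.
#'
#' @param curves A list of `transmission_curve` objects.
#' @param path Output path.
#' @export
write_pairs_tsv <- function(curves, path) {
  tb <- bind_rows(lapply(curves, glance))
  lines <- c("pre_id\tpost_id\tgain\tpeak_lag_ms\tp\tsignificant",
             sprintf("%s\t%s\t%.17g\t%.17g\t%.17g\t%d", tb$pre_id,
                     tb$post_id, tb$gain, tb$peak_lag_ms, tb$p,
                     as.integer(tb$significant)))
  writeLines(lines, path)
  invisible(path)
}
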