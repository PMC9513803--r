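#' Interval jitter of a spike train
#'
#' Partitions the trial `[0, duration)` into consecutive fixed windows of
#' width `2 * delta_ms` anchored at 0 and redraws every spike uniformly
#' within its own window (truncated at the trial end). Spike count is
#' preserved exactly and the coarse rate structure of the train is kept at
#' resolutions above `2 * delta_ms`.
#'
#' @param times Sorted spike times (ms).
#' @param delta_ms Jitter half-window (ms); each window is `2 * delta_ms`
#'   wide.
#' @param duration_ms Trial duration (ms).
#' @param seed Seed.
#' @return Sorted jittered spike times (ms), same length as `times`.
#' @export
interval_jitter <- function(times, delta_ms, duration_ms, seed = 1) {
  stopifnot_positive(delta_ms, "delta_ms")
  if (length(times) == 0L) return(numeric(0))
  w <- 2 * delta_ms
  win <- floor(times / w)
  lo <- win * w
  hi <- pmin(lo + w, duration_ms)
  sort(with_seed(seed, lo + runif(length(times)) * (hi - lo)))
}

coarse_deltas <- function() 0.4 * 2^(0:8)

#' Spike-timing precision by interval jitter
#'
#' Precision `P` is the smallest jitter half-window whose application
#' consistently deteriorates the cross-validated decoding quality. The
#' coarse sweep covers half-windows log2-spaced from 0.4 ms to 102.4 ms;
#' at each value all test-set spikes are jittered (`n_jitter_reps`
#' independent realizations, averaged per trial; training filters are
#' reused from the unjittered fit) and the jittered per-trial `q` values
#' are compared with the originals by a one-tailed Mann-Whitney U test of
#' the group medians (`test = "u"`, the default: deterioration counts once
#' it is commensurate with the across-trial variability of `q`, which is
#' what makes the estimate track the generative jitter scale;
#' `test = "wilcoxon"` selects the paired signed-rank variant, which flags
#' arbitrarily small systematic degradation and therefore bounds `P` from
#' below). The interval between the last coarse value without consistent
#' deterioration and the first with it is then divided into 10 log-spaced
#' values for a focused sweep, and `P` is the smallest focused value with
#' consistent deterioration (falling back to the coarse detection).
#'
#' Units are gated on a consistent stimulus-locked (AC) response first:
#' the unjittered decoding must be significant (`p_overall < alpha`).
#'
#' @inheritParams crossval_decode
#' @param decoding Optionally, a precomputed [crossval_decode()] result for
#'   the same data (avoids refitting; must carry its `fit`).
#' @param n_jitter_reps Jitter realizations averaged per trial and delta.
#' @param alpha Consistency level for the deterioration test and the
#'   AC-response gate.
#' @param test Deterioration test: `"u"` (one-tailed Mann-Whitney on the
#'   per-trial `q` groups) or `"wilcoxon"` (one-tailed paired
#'   signed-rank).
#' @param screen If `TRUE` (default), error when the unit has no
#'   consistent decoding quality.
#' @return A `precision_sweep` object with `P_ms` (`Inf` when no
#'   deterioration is detected up to 102.4 ms), `detected`, and the coarse
#'   and focused sweep tables.
#' @export
precision_sweep <- function(x, spikes, kind = "mwiener", causal = FALSE,
                            decoding = NULL, n_folds = 10, n_shuffles = 100,
                            n_jitter_reps = 10, alpha = 0.05,
                            fs_analysis = 2500, window_ms = 50,
                            screen = TRUE, test = c("u", "wilcoxon"),
                            seed = 1) {
  test <- match.arg(test)
  if (is.null(decoding)) {
    decoding <- crossval_decode(x, spikes, kind, causal, n_folds,
                                n_shuffles, fs_analysis, window_ms,
                                seed = seed)
  }
  if (screen) {
    if (is.na(decoding$p_overall) || decoding$p_overall >= alpha) {
      abort(sprintf(
        "Unit %s has no consistent decoding quality (p = %.3g); precision is undefined.",
        decoding$unit_id, decoding$p_overall),
        class = "spikecoder_screening_failure")
    }
  }
  fit <- decoding$fit
  q0 <- decoding$q_trials
  ok <- !is.na(q0)
  sweep_at <- function(deltas, tag) {
    res <- lapply(seq_along(deltas), function(k) {
      d <- deltas[k]
      qbar <- jittered_q(fit, d, n_jitter_reps,
                         seed = derive_seed(seed, tag, k))
      p <- if (test == "u") {
        suppressWarnings(wilcox.test(q0[ok], qbar[ok],
                                     alternative = "greater",
                                     exact = FALSE,
                                     correct = TRUE)$p.value)
      } else {
        paired_wilcoxon_p(q0[ok], qbar[ok])
      }
      tibble(delta_ms = d, Q = mean(qbar[ok]), p = p)
    })
    bind_rows(res)
  }
  coarse <- sweep_at(coarse_deltas(), 11)
  hit <- which(coarse$p < alpha)
  if (length(hit) == 0L) {
    P <- Inf
    detected <- FALSE
    focused <- tibble(delta_ms = numeric(0), Q = numeric(0), p = numeric(0))
  } else {
    detected <- TRUE
    d_star <- coarse$delta_ms[hit[1]]
    d_lo <- if (hit[1] == 1L) d_star / 2 else coarse$delta_ms[hit[1] - 1L]
    grid <- log_spaced(d_lo, d_star, 12)[2:11]
    focused <- sweep_at(grid, 13)
    fhit <- which(focused$p < alpha)
    P <- if (length(fhit) > 0) focused$delta_ms[fhit[1]] else d_star
  }
  structure(list(unit_id = decoding$unit_id, P_ms = P, detected = detected,
                 coarse = coarse, focused = focused,
                 n_jitter_reps = n_jitter_reps, alpha = alpha,
                 Q0 = decoding$Q, kind = decoding$kind),
            class = "precision_sweep")
}

# Mean per-trial q over jitter realizations at one half-window.
jittered_q <- function(fit, delta_ms, n_reps, seed) {
  trials <- fit$spikes$trials
  dur <- fit$spikes$duration_ms
  n_trials <- fit$spikes$n_trials
  acc <- matrix(NA_real_, n_trials, n_reps)
  for (r in seq_len(n_reps)) {
    jt <- lapply(seq_len(n_trials), function(i) {
      interval_jitter(trials[[i]], delta_ms, dur,
                      seed = derive_seed(seed, r, i))
    })
    acc[, r] <- decode_trials_q(fit, jt)
  }
  rowMeans(acc)
}

#' @export
print.precision_sweep <- function(x, ...) {
  cat(sprintf("<precision_sweep> unit %s (%s): P = %s ms (%s), Q0 = %.3f\n",
              x$unit_id, x$kind,
              if (is.finite(x$P_ms)) sprintf("%.3g", x$P_ms) else "Inf",
              if (x$detected) "detected" else "not detected <= 102.4 ms",
              x$Q0))
  invisible(x)
}

#' @export
tidy.precision_sweep <- function(x, ...) {
  bind_rows(mutate(x$coarse, stage = "coarse"),
            mutate(x$focused, stage = "focused"))
}

#' @export
glance.precision_sweep <- function(x, ...) {
  tibble(unit_id = x$unit_id, P_ms = x$P_ms, detected = x$detected,
         Q0 = x$Q0, n_jitter_reps = x$n_jitter_reps, alpha = x$alpha)
}

#' @export
autoplot.precision_sweep <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(.data$delta_ms, .data$Q,
                                   colour = .data$stage)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$Q0, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(delta ~ "(ms)"), y = "jittered Q",
                  title = sprintf("unit %s: P = %.3g ms", object$unit_id,
                                  object$P_ms)) +
    ggplot2::theme_minimal()
}

#' @export
write_precision_json <- function(x, path) {
  obj <- list(unit_id = x$unit_id, P_ms = x$P_ms, detected = x$detected,
              coarse = x$coarse, focused = x$focused)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}
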