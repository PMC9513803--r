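#' Trial-aligned spike trains for one unit
#'
#' The canonical container for a unit's spikes across repeated identical
#' trials: a list of strictly-increasing spike-time vectors (trial-relative
#' milliseconds in `[0, duration_ms)`), one per trial. Most analysis
#' functions accept either a `spike_trains` object or a tidy spike table
#' (columns `trial`, `t_ms`, optionally `unit_id`).
#'
#' @param x A list of numeric vectors, or a data frame with columns
#'   `trial` (integer, 1-based) and `t_ms`.
#' @param duration_ms Trial duration in ms.
#' @param n_trials Number of trials; defaults to `length(x)` for lists or
#'   `max(trial)` for tables (pass explicitly if trailing trials are empty).
#' @param unit_id Unit label.
#' @return A `spike_trains` object.
#' @export
spike_trains <- function(x, duration_ms, n_trials = NULL, unit_id = "u1") {
  if (is.data.frame(x)) {
    n_trials <- n_trials %||% max(x$trial, 1L)
    trials <- lapply(seq_len(n_trials), function(i) {
      sort(as.numeric(x$t_ms[x$trial == i]))
    })
  } else if (is.list(x)) {
    trials <- lapply(x, function(t) sort(as.numeric(t)))
    n_trials <- n_trials %||% length(trials)
  } else {
    abort("`x` must be a list of spike-time vectors or a spike table.")
  }
  for (i in seq_along(trials)) {
    ti <- trials[[i]]
    if (any(ti < 0 | ti >= duration_ms)) {
      abort(sprintf("Trial %d has spike times outside [0, duration).", i))
    }
    if (anyDuplicated(ti)) {
      abort(sprintf("Trial %d has duplicated spike times.", i))
    }
  }
  structure(list(unit_id = unit_id, trials = trials,
                 n_trials = length(trials), duration_ms = duration_ms),
            class = "spike_trains")
}

as_spike_trains <- function(x, duration_ms = NULL, n_trials = NULL,
                            unit_id = NULL) {
  if (inherits(x, "spike_trains")) return(x)
  if (is.data.frame(x)) {
    if (is.null(duration_ms)) {
      duration_ms <- attr(x, "duration_ms") %||%
        abort("`duration_ms` is required for spike tables.")
    }
    if (!is.null(unit_id) && "unit_id" %in% names(x)) {
      x <- x[x$unit_id == unit_id, , drop = FALSE]
    }
    uid <- unit_id %||% (if ("unit_id" %in% names(x))
      as.character(x$unit_id[1]) else "u1")
    return(spike_trains(x, duration_ms,
                        n_trials = n_trials %||% attr(x, "n_trials"),
                        unit_id = uid))
  }
  abort("Cannot interpret `x` as spike trains.")
}

#' @export
print.spike_trains <- function(x, ...) {
  n <- lengths(x$trials)
  cat(sprintf("<spike_trains> unit %s: %d trials x %g ms, %.1f spikes/trial (%d total)\n",
              x$unit_id, x$n_trials, x$duration_ms, mean(n), sum(n)))
  invisible(x)
}

#' @export
as_tibble.spike_trains <- function(x, ...) {
  out <- tibble(
    unit_id = x$unit_id,
    trial = rep(seq_len(x$n_trials), lengths(x$trials)),
    t_ms = unlist(x$trials, use.names = FALSE) %||% numeric(0)
  )
  attr(out, "duration_ms") <- x$duration_ms
  attr(out, "n_trials") <- x$n_trials
  out
}

#' @export
tidy.spike_trains <- function(x, ...) as_tibble(x)

#' @export
glance.spike_trains <- function(x, ...) {
  n <- lengths(x$trials)
  tibble(unit_id = x$unit_id, n_trials = x$n_trials,
         duration_ms = x$duration_ms, n_spikes = sum(n),
         mean_spikes_per_trial = mean(n),
         rate_hz = sum(n) / (x$n_trials * x$duration_ms / 1000))
}

#' Read/write tidy spike tables
#'
#' TSV with columns `unit_id`, `trial_id` (0-based on disk), `t_ms`.
#'
#' @param spikes A `spike_trains` object or tidy spike table.
#' @param path File path.
#' @export
write_spikes_tsv <- function(spikes, path) {
  tb <- if (inherits(spikes, "spike_trains")) as_tibble(spikes) else spikes
  lines <- c("unit_id\ttrial_id\tt_ms",
             sprintf("%s\t%d\t%.17g", tb$unit_id, as.integer(tb$trial) - 1L,
                     tb$t_ms))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spikes_tsv
#' @param duration_ms Trial duration carried as an attribute on the result.
#' @export
read_spikes_tsv <- function(path, duration_ms = NULL) {
  df <- utils::read.delim(path, sep = "\t",
                          colClasses = c("character", "integer", "numeric"))
  out <- tibble(unit_id = df$unit_id, trial = df$trial_id + 1L, t_ms = df$t_ms)
  if (!is.null(duration_ms)) attr(out, "duration_ms") <- duration_ms
  out
}

#' Raster plot of a spike-train set
#'
#' @param object A `spike_trains` object.
#' @param ... Unused.
#' @export
autoplot.spike_trains <- function(object, ...) {
  tb <- as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$t_ms, y = .data$trial)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (ms)", y = "trial",
                  title = paste("unit", object$unit_id)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
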