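#' Experiment configuration for end-to-end synthetic runs
#'
#' Bundles the stimulus, population, wiring and analysis settings of a
#' fully synthetic experiment. Two scenarios are built in:
#'
#' * `"quadrants"` -- the four canonical example units (see
#'   [quadrant_config()]), decoded, precision-swept, profiled and
#'   classified.
#' * `"cd_pool"` -- a pool of signal-locked presynaptic units converging
#'   through synthetic transmission curves onto labelled-line, summed-
#'   population and coincidence-detection targets with rate-equalized
#'   background, each analysed like a recorded unit.
#'
#' @param scenario `"quadrants"` or `"cd_pool"`.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param kind,causal Filter model used for all decoding.
#' @param n_folds,n_shuffles,n_jitter_reps Analysis settings.
#' @param n_pre Presynaptic pool size (`cd_pool`).
#' @param gamma Coincidence-detection non-linearity factor (`cd_pool`).
#' @param fr_wn Target postsynaptic rate during stimulation, spikes/s
#'   (`cd_pool`).
#' @param baseline_rate_hz Spontaneous rate used for DC screening.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(scenario = c("quadrants", "cd_pool"),
                              seed = 1, kind = "mwiener", causal = FALSE,
                              n_folds = 10, n_shuffles = 100,
                              n_jitter_reps = 10, n_pre = 8, gamma = 14,
                              fr_wn = 30, baseline_rate_hz = 5) {
  scenario <- match.arg(scenario)
  structure(list(scenario = scenario, seed = as.integer(seed), kind = kind,
                 causal = causal, n_folds = n_folds,
                 n_shuffles = n_shuffles, n_jitter_reps = n_jitter_reps,
                 n_pre = n_pre, gamma = gamma, fr_wn = fr_wn,
                 baseline_rate_hz = baseline_rate_hz),
            class = "experiment_config")
}

# Full single-unit analysis: screening, decoding, precision, reliability.
analyse_unit <- function(x, spikes, cfg, seed) {
  dec <- crossval_decode(x, spikes, cfg$kind, cfg$causal, cfg$n_folds,
                         cfg$n_shuffles, seed = seed)
  rel <- reliability_profile(spikes)
  scr <- screen_unit(spikes, cfg$baseline_rate_hz, dec, rel)
  P <- NA_real_
  if (!is.na(dec$p_overall) && dec$p_overall < 0.05) {
    ps <- precision_sweep(x, spikes, decoding = dec,
                          n_jitter_reps = cfg$n_jitter_reps, seed = seed)
    P <- ps$P_ms
  }
  tibble(unit_id = spikes$unit_id, n_trials = spikes$n_trials,
         Q = dec$Q, p_decoding = dec$p_overall,
         time_lag_ms = dec$time_lag_ms, P_ms = P, Rp_ms = rel$Rp,
         coder_class = rel$coder_class, rel_p = rel$consistency_p,
         passed_screening = scr$passed, failure_stage = scr$failure_stage)
}

#' Run a synthetic experiment end to end
#'
#' Generates the stimulus and the configured population, analyses every
#' unit (decoding quality, precision, reliability timescale, coder class,
#' screening), and optionally writes the spike tables and reports to
#' `out_dir` (spikes.tsv, units.json, summary.json; pairs.tsv for wired
#' scenarios). Fully reproducible from the configuration seed.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional output directory.
#' @return A list with `units` (per-unit report tibble), `pairs` (wiring
#'   table or `NULL`) and `summary` (named list).
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  x <- wn_signal(1, 6000, 3, seed = derive_seed(cfg$seed, 500))
  if (cfg$scenario == "quadrants") {
    out <- run_quadrants(cfg, x)
  } else {
    out <- run_cd_pool(cfg, x)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_spikes_tsv(out$spikes, file.path(out_dir, "spikes.tsv"))
    jsonlite::write_json(out$units, file.path(out_dir, "units.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
    jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    if (!is.null(out$pairs)) {
      tb <- out$pairs
      lines <- c("pre_id\tpost_id\tgain\tpeak_lag_ms",
                 sprintf("%s\t%s\t%.17g\t%.17g", tb$pre_id, tb$post_id,
                         tb$gain, tb$peak_lag_ms))
      writeLines(lines, file.path(out_dir, "pairs.tsv"))
    }
  }
  out[c("units", "pairs", "summary")]
}

run_quadrants <- function(cfg, x) {
  letters4 <- c("F", "G", "H", "I")
  units <- list()
  reports <- list()
  for (k in seq_along(letters4)) {
    qc <- quadrant_config(letters4[k], seed = derive_seed(cfg$seed, 30, k))
    st <- simulate_unit(qc, x)
    st$unit_id <- paste0("unit_", letters4[k])
    units[[k]] <- st
    reports[[k]] <- analyse_unit(x, st, cfg,
                                 seed = derive_seed(cfg$seed, 31, k))
  }
  all_spikes <- bind_rows(lapply(units, as_tibble))
  units_tb <- bind_rows(reports)
  list(units = units_tb, pairs = NULL,
       summary = list(scenario = "quadrants", seed = cfg$seed,
                      n_units = nrow(units_tb)),
       spikes = all_spikes)
}

#' Simulate a convergent presynaptic pool and its synthetic targets
#'
#' Builds `n_pre` signal-locked presynaptic units -- a heterogeneous pool
#' with signal drives spread over 15-55 spikes/s, 3 ms signal jitter,
#' 10 spikes/s background and up to 10 added/removed spikes per trial --
#' wires them through synthetic single-lobe transmission curves with
#' gains spread over 0.01-0.03 and peak lags over 1.2-2.4 ms, and
#' generates three synthetic postsynaptic trains with rate-equalized
#' background and a 2 ms refractory period: labelled line (first input),
#' summed population, and coincidence detection (`combine_cd2()` with the
#' configured `gamma`).
#'
#' @inheritParams run_experiment
#' @param x The stimulus (`wn_signal`).
#' @return A list with `pre` (list of `spike_trains`), `targets` (named
#'   list of `spike_trains`), `curves`, `pairs` tibble.
#' @export
build_cd_pool <- function(cfg, x) {
  n_pre <- cfg$n_pre
  gains <- seq(0.01, 0.03, length.out = n_pre)
  lags <- seq(1.2, 2.4, length.out = n_pre)
  drives <- seq(15, 55, length.out = n_pre)
  pre <- vector("list", n_pre)
  rates <- vector("list", n_pre)
  curves <- vector("list", n_pre)
  for (k in seq_len(n_pre)) {
    sc <- sim_config(lambda1 = drives[k], sigma1 = 3, lambda2 = 10,
                     sigma2 = 0, n_add = 10,
                     seed = derive_seed(cfg$seed, 40, k))
    st <- simulate_unit(sc, x)
    st$unit_id <- sprintf("pyr_%02d", k)
    pre[[k]] <- st
    curves[[k]] <- synthetic_curve(gain = gains[k], peak_lag_ms = lags[k],
                                   pre_id = st$unit_id, post_id = "sint")
    rates[[k]] <- presyn_rate(st, curves[[k]])
  }
  sint <- function(rate, tag, id) {
    suppressWarnings(generate_sint(rate, cfg$fr_wn, min_isi_ms = 2,
                                   seed = derive_seed(cfg$seed, tag),
                                   unit_id = id))
  }
  targets <- list(
    LL = sint(combine_ll(rates[[1]]), 41, "sint_ll"),
    SP = sint(combine_sp(rates), 42, "sint_sp"),
    CD = sint(combine_cd2(rates, cfg$gamma), 43, "sint_cd"))
  pairs <- tibble(pre_id = vapply(curves, function(c) c$pre_id, ""),
                  post_id = "sint",
                  gain = gains, peak_lag_ms = lags)
  list(pre = pre, targets = targets, curves = curves, pairs = pairs)
}

run_cd_pool <- function(cfg, x) {
  pool <- build_cd_pool(cfg, x)
  reports <- list()
  for (k in seq_along(pool$pre)) {
    reports[[length(reports) + 1L]] <-
      analyse_unit(x, pool$pre[[k]], cfg, seed = derive_seed(cfg$seed, 44, k))
  }
  for (nm in names(pool$targets)) {
    reports[[length(reports) + 1L]] <-
      analyse_unit(x, pool$targets[[nm]], cfg,
                   seed = derive_seed(cfg$seed, 45, match(nm, names(pool$targets))))
  }
  units_tb <- bind_rows(reports)
  pre_tb <- units_tb[grepl("^pyr", units_tb$unit_id), ]
  cd_tb <- units_tb[units_tb$unit_id == "sint_cd", ]
  summary <- list(
    scenario = "cd_pool", seed = cfg$seed, gamma = cfg$gamma,
    fr_wn = cfg$fr_wn,
    delta_Q = cd_tb$Q - median(pre_tb$Q),
    delta_P = median(pre_tb$P_ms, na.rm = TRUE) - cd_tb$P_ms)
  all_spikes <- bind_rows(c(lapply(pool$pre, as_tibble),
                            lapply(pool$targets, as_tibble)))
  list(units = units_tb, pairs = pool$pairs, summary = summary,
       spikes = all_spikes)
}
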