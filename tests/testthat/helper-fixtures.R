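# Shared fixtures built in code. The stimulus is generated once per test
# session; simulated units are cheap enough to build per test.

fixture_signal <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- wn_signal(1, 6000, 3, seed = 11)
    cache
  }
})

# A strongly signal-locked unit: high drive, small jitter, no background.
locked_unit <- function(seed = 1, sigma1 = 2, lambda1 = 100) {
  simulate_unit(sim_config(lambda1 = lambda1, sigma1 = sigma1, lambda2 = 0,
                           seed = seed), fixture_signal())
}

# A stimulus-blind unit: homogeneous Poisson at a matched rate.
poisson_unit <- function(seed = 1, rate = 50, n_trials = 25) {
  trials <- lapply(seq_len(n_trials), function(i) {
    sort(with_seed_test(seed * 131 + i, stats::runif(stats::rpois(1, rate), 0, 1000)))
  })
  spike_trains(trials, duration_ms = 1000, unit_id = "poisson")
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Injected monosynaptic pair: Poisson pre, Poisson post background plus
# transmitted spikes at `lag_ms` with probability `p_trans`.
injected_pair <- function(p_trans, seed = 1, T_s = 300, pre_rate = 10,
                          post_rate = 20, lag_ms = 1.6, jitter_ms = 0.3) {
  with_seed_test(seed, {
    pre <- sort(stats::runif(stats::rpois(1, pre_rate * T_s), 0, T_s * 1000))
    sel <- stats::runif(length(pre)) < p_trans
    hits <- pre[sel] + lag_ms + stats::rnorm(sum(sel), 0, jitter_ms)
    bg <- sort(stats::runif(stats::rpois(1, post_rate * T_s), 0, T_s * 1000))
    list(pre = pre, post = sort(c(bg, hits)))
  })
}
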