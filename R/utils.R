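# Internal helpers: seed derivation, scoped RNG, convolution alignment.

# Derive a child seed from a master seed and integer tags. Multiplicative
# congruential mix kept below 2^31 so it is always a valid R seed; doubles
# represent all intermediates exactly (< 2^53).
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) {
    h <- (h * 69069 + as.double(t) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Linear ("same") convolution: output has length(x); kernel centre index
# (length + 1) %/% 2 is aligned with each x sample. FFT-based.
conv_same <- function(x, k) {
  nx <- length(x)
  nk <- length(k)
  n <- nx + nk - 1L
  nfft <- stats::nextn(n, 2)
  full <- Re(fft(fft(c(x, numeric(nfft - nx))) *
                 fft(c(k, numeric(nfft - nk))), inverse = TRUE)) / nfft
  centre <- (nk + 1L) %/% 2L
  full[centre:(centre + nx - 1L)]
}

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "spikecoder_invalid_parameter")
  }
}

stopifnot_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number.", name),
          class = "spikecoder_invalid_parameter")
  }
}

# One-tailed paired Wilcoxon signed-rank p value that `a` exceeds `b`,
# robust to zero-difference pairs (dropped, as wilcox.test does).
paired_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[!is.na(d)]
  if (length(d) == 0L || all(d == 0)) return(1)
  suppressWarnings(
    wilcox.test(d, alternative = "greater", mu = 0, exact = FALSE,
                correct = TRUE)$p.value
  )
}

log_spaced <- function(from, to, n) {
  exp(seq(log(from), log(to), length.out = n))
}

# Sort spike times and break exact ties by spacing duplicates `eps_ms`
# apart, walking back from the trial end when a run of clipped spikes
# piles up at the boundary. Guarantees strictly increasing output within
# [0, duration).
dedup_times <- function(t, eps_ms, duration_ms) {
  t <- sort(t)
  n <- length(t)
  if (n < 2L) return(t)
  for (i in 2:n) if (t[i] <= t[i - 1L]) t[i] <- t[i - 1L] + eps_ms
  if (t[n] >= duration_ms) {
    t[n] <- duration_ms - 1e-9
    for (i in (n - 1L):1L) {
      if (t[i] >= t[i + 1L]) t[i] <- t[i + 1L] - eps_ms else break
    }
  }
  t
}
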