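---
title: "Decoding precision, reliability timescales, and synaptic transmission: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding precision, reliability timescales, and synaptic transmission: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(spikecoder)
```

spikecoder analyses spike trains recorded under repeated presentations of
an identical low-passed white-noise (WN) stimulus. This vignette explains
the models and estimators, the choices made where a method admits more
than one reasonable operationalization, and what the synthetic-data
generator does and does not emulate.

## The stimulus

`wn_signal()` draws Gaussian white noise at 6 kHz and convolves it with an
alpha function $t\,e^{-t/\tau}$ ($\tau$ = 3 ms by default, kernel support
truncated at $10\tau$, which carries essentially the whole kernel mass),
then rescales to $[0, 1]$. The kernel normalization before rescaling is
irrelevant because of the rescaling; the convolution uses zero-padded
("same") alignment, a choice that only affects a few edge samples.
`scale_power()` maps the scaled waveform to a light-power command
$P(t) = \mu + x(t)\,\sigma$ and refuses any non-positive output sample.
All analyses use the standardized signal $z(t)$ (zero mean, unit
variance) resampled by linear interpolation to the 2500 Hz analysis grid
— the grid on which the point-process simulation operates; mixing the 6
kHz stimulus grid with the coarser spike grid would otherwise leave the
filter lag axis ambiguous.

```{r signal}
x <- wn_signal(1, 6000, 3, seed = 7)
x
```

## The point-process simulator

`simulate_unit()` implements the validation simulation that anchors every
estimator in the package. A firing-rate profile is the standardized
signal convolved with a template kernel (one cycle of a 100 Hz sinusoid),
rectified, and scaled so its time average equals the signal rate
$\lambda_1$; the rectify-then-scale order makes $\lambda_1$ the realized
mean drive, a convention we adopt because no scaling rule is implied by
the construction itself. A "mother" spike train is sampled by per-sample
Bernoulli draws $B(1, f(t)/F_s)$ with a causal minimum-ISI prune (2 ms by
default, the middle of the plausible 1–5 ms range). The mother is
replicated into $N = 25$ daughters; each daughter's spikes are jittered
by a Gaussian of SD $\sigma_1$, then up to $N_{remove}$ spikes are
deleted and up to $N_{add} = N_{remove}$ added ("up to" is read as a
uniform draw on $\{0..N\}$ per daughter). A background train at rate
$\lambda_2$ goes through the same pipeline with its own jitter
$\sigma_2$, and the final trial merges the two daughters. Noise daughters
receive the same add/remove maximum as signal daughters — the two trains
are "modified in the same manner".

Two conventions worth noting: jittered spikes falling outside the trial
are clipped to the boundary (not wrapped), and exact ties are separated
by half an analysis sample with a deterministic walk that never leaves
the trial. The minimum ISI constrains the mothers only; daughters may
violate it after jitter, which is documented behaviour, not an error.
Independent RNG streams are derived per role and per trial from the
master seed, so enlarging a simulated population never perturbs existing
units.

```{r sim}
st <- simulate_unit(sim_config(lambda1 = 100, sigma1 = 2, seed = 1), x)
st
```

## Filter models and cross-validated decoding

The spike-triggered average (STA) is the mean standardized-signal segment
in a ±50 ms window around each spike (segments at trial edges are
zero-padded; an exclusion variant would discard usable spikes for no
measurable benefit at these window sizes). Twelve filter models are
built from it: `sta`, the ISI-conditional `csta` (spikes tagged by the
decile of their preceding ISI, ten equally-populated bins; a trial's
first spike inherits the interval across the trial gap when the previous
trial has spikes, otherwise it joins the top decile), `wiener` /
`cwiener` (STA computed on the whitened signal), and `mwiener` /
`cmwiener` (STA deconvolved by the spike-train autocorrelogram), each
causal or acausal. The acausal modified Wiener filter is the package
default.

Whitening multiplies the signal by the pseudo square-root inverse of its
lag-window Toeplitz autocovariance (biased estimator), retaining the
smallest leading eigenvalue set that accounts for at least 90% of the
variance. The operator is applied as an FIR filter taken from the centre
row of the projection matrix. The modified Wiener solve $A w = s$
arranges the autocorrelogram as a symmetric Toeplitz matrix over the
same lag range (so the ACH is measured out to twice the filter window)
and inverts it by an eigenvalue-floored pseudo-inverse (floor at
$10^{-6}$ of the leading eigenvalue); the zero-lag ACH bin carries the
spike count — the self-coincidence mass of the point-process
autocorrelation — which makes $A$ close to a scaled identity for
Poisson-like trains and the deconvolution a no-op in that limit, exactly
the behaviour a deconvolution should have.

Decoding is 10-fold cross-validated: filters are fitted on the training
trials and every test trial is reconstructed by placing the filter at
its spikes (per-spike bank row for conditional models). The single-trial
quality $q_i$ is the Spearman rank correlation between $z$ and the
reconstruction — rank correlation makes the measure invariant to any
monotone distortion of the reconstruction amplitude, so filter scaling
conventions cannot affect it. $Q$ is the mean of the $q_i$ and the
overall p value the geometric mean of per-trial empirical p values
obtained by redrawing test-trial spike times uniformly within the trial
(`(1 + k)/(n_shuffles + 1)`, never zero). Wiener-filter reconstructions
are gauged against the plain standardized signal (deliberately
penalized); the pre-whitened STA variants (`pwsta`) gauge against the
whitened signal instead. Trials with no spikes are excluded from $Q$
with a reported count.

```{r decode}
dec <- crossval_decode(x, st, kind = "mwiener", n_shuffles = 50, seed = 1)
glance(dec)
```

## Precision by interval jitter

`interval_jitter()` partitions the trial into fixed consecutive windows
of width $2\delta$ anchored at zero and redraws each spike uniformly
within its window — a fixed partition (rather than spike-centred
windows) preserves coarse rate structure exactly, which is the point of
interval jitter. Precision $P$ is the smallest $\delta$ whose
application consistently deteriorates $Q$: a coarse sweep over
$\delta \in \{0.4, 0.8, \ldots, 102.4\}$ ms (10 jitter realizations
averaged per trial; filters are *not* refitted — jitter is applied to the
test spikes and the unjittered training filters are reused), then a
focused sweep of 10 log-spaced values between the last coarse $\delta$
without consistent deterioration and the first with it, so that $P$
estimates the infimum of the deterioration region. When deterioration is
first detected at the smallest coarse value, the focused bracket extends
one octave below it.

The deterioration test deserves its own paragraph. A paired signed-rank
comparison of jittered versus original per-trial $q$ detects *any*
systematic degradation, however small: measured on simulated units, it
flags $\Delta Q \approx -0.005$ at $\delta$ an order of magnitude below
the generative jitter, which pins $P$ at the grid floor for every unit
and destroys the interpretability of $P$ as a timescale. The package
therefore defaults to the one-tailed Mann–Whitney U comparison of the
two groups of per-trial $q$ values: deterioration counts once it is
commensurate with the across-trial variability of $q$. Under this
definition $P$ recovers the generative signal jitter near the identity
line on simulated units (the acceptance suite measures this), which is
the behaviour that makes the statistic scientifically meaningful. The
paired variant remains available (`test = "wilcoxon"`) for sensitivity
analyses. Units without a significant stimulus-locked (AC) response are
gated out before precision quantification.

```{r precision}
ps <- precision_sweep(x, st, decoding = dec, seed = 1)
glance(ps)
```

## Reliability profiles and coder classes

For each kernel SD $\sigma$ on the same log grid, trials are smoothed
with unit-mass Gaussians and reliability $r(\sigma)$ is the mean Spearman
correlation over all trial pairs. Two estimator details matter:

* **Edge correction.** A Gaussian centred near a trial boundary loses
  mass outside the trial, so every smoothed trace shares a deterministic
  roll-off near the edges. At wide kernels this shared component
  dominates the traces and inflates $r$ toward 1 for *any* unit, masking
  interior structure. Traces are therefore divided by the retained-mass
  profile $\Phi((T-t)/\sigma) - \Phi(-t/\sigma)$ before correlating.
* **Timescale readout.** The reliability timescale `Rp` is the $\sigma$
  of the global profile maximum (smallest $\sigma$ on ties — conservative
  toward temporal coding). Profiles of sharply-locked units whose
  trial-to-trial noise is mostly shared often carry a consistent interior
  peak *and* a slightly higher second maximum at the largest tested
  $\sigma$; the classification below treats such units as temporal
  coders, and their characteristic timescale (`timescale_ms`) is the
  refined interior-peak location rather than the railed global maximum.
  Both values are reported.

Classification applies ordered rules to the coarse profile. A unit is a
*temporal* coder when the profile has an interior local maximum whose
trial-pair correlations consistently exceed those at the flanking local
minima (one-tailed paired Wilcoxon, $p < 0.05$ on both sides); a *rate*
coder when the profile is non-decreasing within tolerance (no drop
between consecutive coarse $\sigma$ beyond twice the combined standard
error of the pairwise mean) with its global maximum at the largest
$\sigma$; *temporal* also when the profile, having failed the monotone
rate test, peaks at a $\sigma$ other than the largest tested — the
geometric signature of a preferred finite timescale. (The consistency
requirement alone is underpowered for weakly reliable units: with 25
trials the per-pair correlation noise approaches 0.5, so genuine
interior peaks of a few hundredths would be missed almost half the
time.) Everything else is *undefined*.
Focused refinement (10 log-spaced $\sigma$ between the grid neighbours of
the peak, extended to both neighbours) is applied around the consistent
interior peak and around an interior global maximum.

```{r reliability}
rel <- reliability_profile(st)
glance(rel)
```

## Monosynaptic connectivity

`compute_cch()` counts spike-time differences in 0.4 ms bins centred on
multiples of the bin width over ±50 ms (membership half-open). The
baseline is a centred 25-bin (10 ms) running median with reflected edges
— wide enough to span a monosynaptic peak, narrow enough to track slow
CCH structure; the window is configurable and the suite exercises the
detector's calibration under it. Candidate connections are tested per
bin of the monosynaptic region of interest (lags in $(0, 5.2]$ ms — 13
whole bins respecting the nominal 0–5 ms window on a 0.4 ms grid) with
an upper-tail Poisson test against the baseline, Bonferroni-corrected by
the 13 ROI bins, at $\alpha = 0.001$.

The spike-transmission curve deconvolves the count CCH by the
presynaptic autocorrelogram (the same regularized Toeplitz solver as the
modified Wiener filter), subtracts the identically-deconvolved baseline,
and scales to spikes/s by the presynaptic spike count and bin width. The
baseline is median-filtered on the *count* CCH and then deconvolved —
the alternative order (filter after deconvolution) changes results only
through the solver's high-frequency response and is not exposed. The
transmission gain integrates the excess rate over the ROI peak extended
to its zero crossings; it reads as expected extra postsynaptic spikes
per presynaptic spike, and the acceptance suite verifies that injected
connections with transmission probabilities 0.05–0.4 are recovered
within 25%. `connection_probability()` divides detected presynaptic
partners by candidates within 600 µm.

## Transmission models

Given per-pair transmission curves, `presyn_rate()` convolves each
presynaptic trial with the causal, rectified part of its curve. The
combination rules are `combine_ll()` (labelled line — identity on a
single input), `combine_sp()` (linear sum), and two coincidence-detection
forms over the *active* inputs ($x_i(t) > 0$ at the sample — activity has
no other natural definition on a rate grid, and restricting products and
sums to active inputs is required for the $n = 0$ and $n = 1$ special
cases to be continuous):

$$\mathrm{CD}_1:\; y = \prod_{i\,\in\,\mathrm{active}} (x_i + \gamma)
  \;-\; \gamma^{n},\qquad
  \mathrm{CD}_2:\; y = \gamma^{\,n-1} \sum_{i\,\in\,\mathrm{active}} x_i,$$

with $y = x_i$ for $n = 1$ and $y = 0$ for $n = 0$: isolated spikes are
never amplified, coincident input is supralinear. In CD$_1$ the
non-linearity factor $\gamma$ carries rate units (a natural sweep is a
multiple of the median peak rate); in CD$_2$ it is dimensionless.
CD$_2$ at $\gamma = 1$ is exactly the summed-population rule, and both
CD forms reduce to the labelled line for a single input — identities the
tests assert. `generate_sint()` samples the postsynaptic train from the
combined rate (per-sample Bernoulli draws) and, unless `noiseless`, adds
an independent homogeneous Poisson background so the total mean rate
reaches the target stimulation rate FR\(_{WN}\) (no background when the
driven rate already exceeds it).

### The convergent-pool scenario

`build_cd_pool()` fixes the synthetic conditions for the
error-correction demonstration: 8 presynaptic units with heterogeneous
signal drives (15–55 spikes/s; real pools are heterogeneous, and the
postsynaptic readout leans on its strongest inputs), 3 ms signal jitter,
10 spikes/s background plus up to 10 added/removed spikes per trial
(independent across units — the noise the coincidence readout can
correct), transmission gains spread over the empirically realistic
0.01–0.03 with monosynaptic lags 1.2–2.4 ms, a CD$_2$ target with
$\gamma = 14$ (strong enough supralinearity that coincidence drive
dominates the postsynaptic rate), FR\(_{WN}\) = 30 spikes/s, and a 2 ms
refractory period on the synthetic postsynaptic train (without it,
rate-clipped coincidence lobes emit multi-spike bursts at the grid
resolution). Two quantitative lessons from designing this scenario are
recorded here because they generalize: the precision statistic improves
with spike count, so postsynaptic and presynaptic rates must be
commensurate for a precision comparison to be meaningful; and dispersion
of monosynaptic lags across the pool blurs the coincidence code by the
same amount it spreads.

## Screening and shared statistics

Units enter analysis through sequential gates: at least 5 trials and 2
spikes per trial on average; a DC response (stimulation rate above the
spontaneous rate; upper-tail Poisson test on the pooled stimulation
count — pooling is the simpler of the two defensible readings, the
per-trial variant being strictly weaker); an AC response (significant
decoding); and consistent reliability. All tests in the package are
non-parametric: Spearman correlation with an empirical permutation p
value (partial variant via rank residuals), one-tailed Mann–Whitney U,
one-tailed paired signed-rank, the G test, and the exact binomial test.
$\alpha = 0.05$ throughout, except monosynaptic detection at
$\alpha = 0.001$. Empirical p values are never zero, which the
geometric-mean aggregation upstream requires.

## Problem sizes and what the tests show

The validation experiments in the test suite run at desk scale: 1 s
trials, 25 trials per unit, 2500 Hz grids, 10–20 seeds per condition,
10 jitter realizations per sweep point. These sizes were chosen so that
each recovered quantity (precision medians, timescale medians, gain
medians) is stable across seeds. The generator emulates stationary
signal-locked and background spiking with controlled jitter and
add/remove noise; it does not emulate bursting dynamics, adaptation,
brain-state changes, electrode drift, or spike-sorting contamination.
Passing tests therefore demonstrate that the estimators recover the
generative parameters of this model family, not that recorded data meet
the model's assumptions.

## Known limitations

* Reliability is kernel-and-correlation based; spike-distance metrics
  (van Rossum, Victor–Purpura) are out of scope.
* Inhibitory (trough-type) connections are not detected; only excess-rate
  peaks in the causal ROI are tested.
* The whitening operator is applied as a stationary FIR filter; exact
  finite-window whitening would require a full matrix application whose
  edge behaviour is worse, not better.
* Simulated mothers impose the minimum ISI, daughters may violate it
  after jitter; analyses treat spike times as exact and never re-impose
  refractoriness.
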