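---
title: "Models and methods: predictive responses in human auditory cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: predictive responses in human auditory cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogpred)
```

# The scientific problem

Early auditory cortex is thought to predict its input in two distinct ways.
First, *temporal prediction*: when sound is rhythmic, low-frequency cortical
phase aligns to the moments of rapid amplitude gain (acoustic edges) and
keeps anticipating them for about one cycle after the rhythm stops. Second,
*predictive coding of content*: a posterior region produces a short burst at
unexpected sound onsets but stays silent for self-produced speech, whose
sensory consequences are internally predicted. `ecogpred` implements the
analysis chain that separates, quantifies, and localizes these two
signatures in multichannel intracranial recordings, together with a
generative model of synthetic cohorts in which each signature is planted
with known parameters, so that every statistic in the package can be
validated by recovery.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does and
does not establish about real data.

# Spectral decomposition

All band-limited quantities come from frequency-domain bandpass Hilbert
filters. The filter's positive-frequency gain is the product of a rising and
a falling logistic flank centered on the nominal band edges:

$$ g(f) = \sigma\!\big(k\,(f - f_\mathrm{lo})\big)\,
          \sigma\!\big(k\,(f_\mathrm{hi} - f)\big), \qquad
   \sigma(x) = \frac{1}{1+e^{-x}} , $$

with $k$ set so that a flank half-width of 1 Hz means a 0.12 to 0.88
transition over 2 Hz. The gain is exactly 0.5 at each nominal edge. Negative
frequencies are zeroed and positive frequencies doubled, so the inverse FFT
yields the band-limited analytic signal; its modulus and argument are the
instantaneous amplitude and phase. Epochs are padded by reflection (0.5 s by
default) before the FFT and trimmed afterwards, which suppresses epoch-edge
ringing without fabricating periodicity; the padding choice is invisible to
all tests at the epoch interiors. For spectrally resolved analyses a bank of
filters with log-spaced centers (2–16 Hz) and log-spaced widths (1–4 Hz),
paired index-wise, is available; 50 bands is the conventional resolution,
and analyses here use 10 when only a band-averaged quantity is needed.

Two consequences of the filter algebra matter for interpretation. A narrow
band (e.g. 8–12 Hz with 1 Hz flanks) cannot reach unit gain at its center
(the two flanks overlap; gain ≈ 0.965), which is irrelevant for
amplitude-normalized statistics such as phase and ITC but visible in raw
amplitudes. And narrow low-frequency bands ring for hundreds of
milliseconds, which motivates a choice documented below.

Canonical bands: low 2–15 Hz (the ITC band), theta 4–8 Hz, beta 15–30 Hz,
high gamma 65–115 Hz. All are configurable.

# Phase statistics

Phase alignment across trials is quantified by inter-trial coherence,
$L = \lvert \tfrac1N \sum_n e^{i\theta_n} \rvert \in [0,1]$. For uniform
random phases $E[L] \approx \tfrac{\sqrt{\pi}}{2} N^{-1/2}$, which the test
suite verifies by simulation; this floor, not zero, is the reference for
"no alignment". Per-electrode significance uses a temporally jittered
bootstrap: each trial's phase series is circularly shifted by an independent
uniform offset and the statistic recomputed; the one-sided p-value carries
the +1 correction and is therefore never exactly zero. The same jitter
scheme provides the null for the Kullback–Leibler divergence of
phase-resolved amplitude profiles (18 bins of 20°; the bin count is reduced
with a warning if a bin is empty). KL is computed with the convention
$0 \log 0 = 0$, so a profile concentrated in one of $B$ bins gives exactly
$\log B$.

## Analysis intervals and the engagement measures

The rhythmic paradigm is tiled into baseline (−300…−50 ms), onset (first
modulation cycle), sustained (cycles 2 to the last), and two consecutive
prediction intervals of one cycle each after the rhythm ends. The boundaries
follow directly from the modulation frequency; nothing else is free.

Per electrode and interval, the low-frequency measure is mean ITC and the
high-gamma measure is a signed $r^2$: the sign times the square of the
Spearman correlation between the trial-mean high-gamma power series and a
cosine at the modulation frequency, phase-aligned to the (extrapolated)
stimulus envelope with peaks at phase 0. Group engagement per interval is a
paired one-sided Wilcoxon signed-rank test against the baseline measure
across electrodes.

An open implementation choice is whether interval ITC should average the
narrow filter-bank bands or use the single wide 2–15 Hz band. The package
defaults to the wide band: its impulse response is an order of magnitude
shorter than that of a 1-Hz-wide band at 3 Hz, so a reset placed late in the
early-prediction interval does not smear into the late interval and the
interval boundaries retain their meaning. `interval_engagement()` accepts a
filter bank instead, in which case per-band ITC is averaged.

# Speech features

The acoustic envelope is the modulus of the broadband analytic signal,
low-pass filtered at 10 Hz and resampled to the neural clock. Acoustic edges
are local maxima of the envelope derivative that exceed a quantile (0.9) of
the derivative distribution, with a 120 ms minimum separation resolved in
favor of the larger slope. The envelope is lightly Savitzky–Golay smoothed
(51 ms, order 2) before differentiation; without this, differentiating a
noisy envelope at 1 kHz is dominated by sample-to-sample noise. The detector
is invariant to global amplitude scaling up to one-sample quantization of
the detected times.

Neural envelope tracking is measured by the Spearman correlation between
band power and the envelope as a function of lag (positive lag = neural
after audio), on concatenated sentences with 250 ms masked around sentence
boundaries; computing on concatenated-and-masked data rather than per
sentence uses all samples while excluding spurious cross-boundary lags.
Post-edge phase organization is the mean low-frequency ITC over the 125 ms
after each edge, contrasted against syllable onsets — a deliberately
confusable annotation stream that the generator plants with different
timing, so the contrast has a known direction.

# Response classification

Trial-mean response features (high-gamma percent change; baseline-referenced
ITC change) are half-wave rectified and factorized as $A \approx WH$ with
$W, H \ge 0$ and rank $k = 2$, minimizing the Frobenius objective by
Lee–Seung multiplicative updates. The update is run from many random
non-negative starts (1000 in convention; fewer suffice at desk scale since
the rank-2 problem is benign) and the best replicate by residual is
returned; the objective is non-increasing within every replicate, which the
tests assert. Replicate seeds derive from a master seed by a counter, so the
fit is reproducible and parallelizable.

The factorization's scale degeneracy ($W$ column times $c$, $H$ row divided
by $c$) is removed by normalizing each archetype to unit maximum and folding
the scale into the weights. Only after this normalization do the derived
quantities make sense on the feature's own scale: class bias (difference of
the two weights), response magnitude (their sum), and the bias threshold of
10 — i.e. ten percent-change points — that turns biases into discrete
classes (sustained / transient by sign, mixed when two measures disagree,
unclassified below threshold). Class identity (which basis is "sustained")
is assigned by correlating each archetype with a modulation-frequency comb
template rather than by inspection.

Archetype transfer to a new condition conserves $H$ and recomputes
$W = A_\mathrm{new} H^{+}$ with the Moore–Penrose right pseudo-inverse
(negative weights rectified to zero); an exact rank-2 non-negative least
squares is available as a stricter option. Condition comparisons follow the
within-class convention: the bias of electrodes classified sustained during
listening is correlated (Spearman) with their articulation bias, and
likewise for transient electrodes — with a suppressed transient response the
former stays high while the latter is statistically indistinguishable from
zero.

The traveling wave is fit per acoustic pulse by robust linear regression
(Huber M-estimator) of high-gamma peak time — the maximum of trial-mean
power within half a cycle of the pulse peak — on mediolateral position;
velocity is the inverse slope, the mean wave averages pulses 2 onward, and
fits with $R^2 < 0.5$ are flagged undefined rather than reported.

# Behavioral and stimulation statistics

Detection accuracy on tone-present trials is the hit rate per intensity
level and temporal position (overall accuracy including correct rejections
is reported separately, since position is undefined on absent trials). The
position-2 effect is a paired Wilcoxon signed-rank test of position-2 hit
rate against each other position at the lowest level, Holm-adjusted.

Stimulation outcomes are compared with the pooled two-proportion z-test.
Sidedness is one-sided by default: the printed value 0.0246 for 10/31 vs
11/18 is exactly the lower-tail normal probability of the pooled z, whereas
the two-sided version gives 0.049; the package therefore adopts one-sided as
the default with an explicit argument to override. Printed percentages are
converted back to integer counts by rounding, with a flag when several
counts print identically.

# The synthetic-data generator

The generator is a forward model, not a fixture: it produces stimuli,
electrode geometries, continuous multichannel recordings, and behavioral
tables with known ground truth.

**Stimulus.** Wideband Gaussian noise multiplied by
$1 - d\,(1 - \cos 2\pi f t)/2$ — peak-normalized, so depth
$d = (\mathrm{peak}-\mathrm{trough})/\mathrm{peak}$; 3 Hz, $d = 0.8$, 3 s,
ending on the cosine peak into an 833 ms constant segment. Edges (ground
truth) are the maximum-derivative points of each rising slope, at
$(k + 3/4)/f$. The probe tone (1 kHz, 50 ms, 5 ms raised-cosine ramps) sits
at one of five quarter-cycle positions from the constant-segment start, at
one of three levels spanning 12 dB.

**Neural forward model.** Each electrode mixes archetype components into a
$1/f^{1.5}$ Gaussian background; each component's amplitude is `snr` times
the background RMS in that component's own band. Sustained electrodes carry
(i) high-gamma band noise whose amplitude follows the stimulus envelope at
`hg_lag_ms` (45 ms) plus a mediolateral traveling-wave term
$(x - \bar{x})/v$ with $v = 0.1$ m/s, and a low-latency high-magnitude
evoked burst at stimulus onset; (ii) theta packets (6 Hz, 125 ms Hann
window) phase-locked to each edge, continuing for
`theta_reset_persist_cycles` (default 1) extrapolated edges after the last
pulse — the planted persistence. The packet is centered on the edge
(25–50 ms lead): the planted mechanism is anticipatory alignment of
excitability to the expected edge, which also keeps the one-cycle
persistence effect inside the first prediction interval instead of bleeding
into the second through the packet tail; (iii) beta bursts resynchronized at
envelope troughs. Transient electrodes carry a single onset burst about one
pulse long with a broadband phase reset, are planted only in
dominant-hemisphere PT, and contribute nothing to articulation-aligned
epochs when `articulation_suppressed`. Null electrodes carry background
only.

**Chosen-once simulation conditions.** Defaults were fixed from design power
calculations before the recovery suites were finalized: component SNR 3;
psychometric intercept 1.0 and slope 0.25 per dB with a 1.2-logit
position-2 bonus at the lowest level and a 0.1 false-alarm rate;
interval-engagement cohorts of 16 sustained electrodes at a single
mediolateral site with 30 trials (a desk-scale stand-in for ~100 trials per
patient; a 16 mm array is used instead when the traveling wave is the
target, since wave lags of ±80 ms would otherwise rotate the reference
cosine of the high-gamma measure); neural sample rate 400–500 Hz, which
covers every analyzed band (Nyquist 200–250 Hz ≥ 115 Hz + flanks) at a
fraction of the clinical 2 kHz acquisition cost. Cohorts at the scale of
349 supratemporal electrodes are generated at the feature level
(trial-mean rectified features with shared log-normal response gains)
rather than as continuous recordings, which keeps the factorization
analyses within desk-scale memory; the recording-level model is used at
smaller cohort sizes to validate the full chain end to end.

**What passing recovery tests do and do not show.** The generator realizes
the statistical structure the analyses assume — band-limited components,
event-locked phase, planted lags and suppression — but not acoustic realism
(no formants), subcortical transformation, epileptiform artifacts,
electrode-to-electrode noise correlations, or non-stationary vigilance
effects. Recovery therefore demonstrates that the estimators are correct and
calibrated under their own assumptions, with power at realistic SNR; it does
not certify performance on any particular clinical recording.

# Numerical choices and degenerate inputs

- Time is in seconds, epoch time 0 at the alignment event, half-open sample
  windows $[t_0, t_1)$.
- Saturation for channel exclusion means samples exactly pinned at the
  channel extremum for more than 0.1% of samples; the line-noise criterion
  references the median spectrum over 50–70 Hz excluding 58–62 Hz, both
  choices ours since only the thresholds are conventional.
- Epileptiform trial rejection is an externally supplied bad-trial list
  (clinical judgment, not an algorithm); behavioral rejection drops
  incorrect or >2 s responses.
- NNMF: all-zero feature matrices are rejected; non-convergence within
  `max_iter` returns the best iterate flagged; ties between replicates go to
  the first.
- Bootstrap p-values are one-sided (ITC and KL only meaningfully exceed
  their nulls) with the +1 correction.
- Peak-electrode selection breaks ties lexicographically by electrode id.
- Zero baseline power, empty phase bins, rank-deficient archetypes, windows
  outside epochs, and Nyquist violations all fail loudly rather than
  silently.

# Known limitations

- The articulation forward model has no acoustic self-feedback; epochs are
  independent trials aligned to a separate event.
- Syllable onsets are annotations (planted or supplied), not an automatic
  syllabifier.
- The entrainment-versus-evoked debate is not adjudicated: the generator's
  edge-locked packets realize the observable (post-edge ITC rise) without
  claiming a mechanism, and any model with that observable is equally
  compatible with the analyses.
- Rank selection beyond $k = 2$ is exposed as a parameter, not automated.

# Problem sizes used in the shipped validation

Test-suite cohorts use 8–20 electrodes, 8–30 trials, 400–500 Hz, 10–50 NNMF
replicates, 99–300 bootstrap replicates, and 100–1000 simulation repeats
per claim; the 349-electrode factorization uses 50 replicates. These sizes
were chosen as the smallest at which the planted effects are recovered with
comfortable margins, and are stated here so that larger reruns are a
parameter change, not a code change.
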