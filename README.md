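# ecogpred

Analysis pipeline for intracranial electrophysiology (ECoG/sEEG) of
predictive processing in human early auditory cortex, with a synthetic-data
generator that makes every analysis testable by parameter recovery.

The scientific setting: depth electrodes along the supratemporal plane record
two distinct response types while a patient listens to rhythmic
amplitude-modulated noise or natural speech. Heschl's gyrus and the
transverse temporal sulcus (HG/TTS) show a *sustained* response — high-gamma
(65–115 Hz) power tracking the acoustic envelope at a short lag, and
low-frequency phase resetting at each acoustic edge, a reset that persists
one cycle after the rhythm stops (temporal prediction). The planum temporale
(PT) shows a *transient* onset response that vanishes during self-generated
speech (predictive coding via efference copy). `ecogpred` implements the
full analysis chain that identifies these mechanisms, and a forward model
that plants them in synthetic cohorts so they can be recovered and the
statistics calibrated.

## What is implemented

- **Preprocessing** — zero-phase Butterworth notch filters at 60 Hz and two
  harmonics, channel exclusion (>10 dB line noise, saturation), common
  average reference, event-locked epoching with a −300…−50 ms baseline.
- **Spectral decomposition** — frequency-domain bandpass Hilbert filters with
  paired sigmoid flanks (half-width 1 Hz; gain 0.5 at the nominal band edge),
  a 50-band log-spaced filter bank (centers 2–16 Hz, widths 1–4 Hz), percent
  change in power from baseline, Savitzky–Golay display smoothing (3rd
  order, 83 ms).
- **Phase statistics** — inter-trial coherence `L = |1/N Σ exp(iθₙ)|`,
  temporally jittered bootstrap nulls, phase-resolved amplitude profiles
  with Kullback–Leibler divergence from uniform, interval engagement
  (baseline / onset / sustained / early / late prediction; ITC and a signed
  r² from the Spearman correlation of high-gamma power with a
  modulation-frequency cosine), quarter-period delay embeddings, and a
  predictive-electrode screen.
- **Speech features** — envelope extraction (analytic-signal modulus,
  10 Hz low-pass), acoustic-edge detection (maxima of the envelope
  derivative above a slope quantile), lagged Spearman correlation between
  band power and the envelope, post-edge ITC with the edge-vs-syllable
  contrast, discrete pre/post-edge and peak/valley contrasts, articulation
  onset detection.
- **Response classification** — rank-2 non-negative matrix factorization
  (`‖A − WH‖²_F`, Lee–Seung multiplicative updates, best of many random
  restarts), archetype normalization, class bias (weight difference) and
  response magnitude (weight sum) with the bias threshold of 10, archetype
  transfer `W = A H⁺` to articulation epochs, anteroposterior gradient
  correlations, traveling-wave velocity fits (robust regression of
  high-gamma peak times on mediolateral position).
- **Behavior and stimulation** — tone-detection accuracy by level and
  temporal position, Wilcoxon position-2 contrasts, the one-sided pooled
  two-proportion z-test for chronometric-stimulation outcomes, and
  reconstruction of integer trial counts from printed percentages.
- **Synthetic data** — amplitude-modulated noise stimuli (3 Hz, 80% depth,
  3 s + 833 ms constant segment, optional peri-threshold 1 kHz probe tone),
  speech-like envelopes with dissociable edge and syllable annotations,
  electrode geometries, and neural recordings realizing the sustained /
  transient archetypes with planted lags, persistence, wave velocity,
  articulation suppression, and 1/f^1.5 background noise.

## Worked example

```r
library(ecogpred)

cfg <- pipeline_config(seed = 1, n_trials = 12, nnmf_replicates = 10)
summary <- run_pipeline(cfg, "demo_out")
```

This simulates a 18-electrode supratemporal cohort (8 HG/TTS sustained,
6 PT transient, 4 null), preprocesses and epochs the recording, and runs the
full analysis. The summary it printed:

```
$interval_engagement        # group Wilcoxon vs baseline, all 18 electrodes
          interval   p_itc   p_hg
             onset 0.00176 0.9553
         sustained 0.00509 0.0277
  early_prediction 0.00934 0.9723
   late_prediction 0.15825 0.5347

$classification_counts      # NNMF class bias, threshold 10
  sustained 10, transient 7, unclassified 1

$gradient_rho  0.866        # anteroposterior class gradient (Spearman)
$wave_velocity_m_per_s      0.0945   # planted: 0.1 m/s
$quarter_period_delay_ms    83
$behavior_hit_rate_by_level 0.367 0.778 0.956
$position2_min_p            0.0159   # planted position-2 detectability bonus
$stimulation_p_edge_vs_uniform 0.0246
$stimulation_p_hg_vs_pt        0.000282
```

Reading it: low-frequency phase stays engaged through the first prediction
interval after the rhythm ends but not the second (`p_itc`), the planted
0.1 m/s traveling wave and anteroposterior sustained→transient gradient are
recovered, detection improves at the second temporal position, and the
stimulation contrasts reproduce the one-sided two-proportion z-test values
computed from the reconstructed trial counts (10/31 vs 11/18 and 10/31 vs
17/21). The mixed cohort dilutes the group high-gamma measure (only 8 of 18
electrodes are envelope trackers); `tests/testthat/test-acceptance.R` runs
the same analysis on a homogeneous sustained cohort, where the full
onset/sustained/early/late pattern emerges.

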