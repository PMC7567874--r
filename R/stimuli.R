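# Stimulus construction: amplitude-modulated wideband noise with an optional
# peri-threshold probe tone, and quasi-rhythmic speech-like envelopes.

#' Specify an amplitude-modulated noise stimulus
#'
#' Describes the rhythm-listening stimulus: wideband Gaussian noise modulated
#' at `mod_freq_hz` (default 3 Hz, 80% depth) for `rhythmic_dur_s`, ending on
#' the cosine peak of the next cycle into a constant-amplitude segment of
#' `constant_dur_s`. Depth follows the peak-referenced convention
#' `depth = (peak - trough) / peak`, i.e. the modulator is
#' `1 - depth * (1 - cos(2 pi f t)) / 2` with unit peak.
#'
#' @param sample_rate_hz audio sample rate (Hz).
#' @param mod_freq_hz modulation frequency (Hz); 3 by default, 5 and 7 are the
#'   standard fast variants.
#' @param mod_depth modulation depth in `[0, 1]`.
#' @param rhythmic_dur_s duration of the rhythmic segment (s); must contain an
#'   integer number of modulation cycles.
#' @param constant_dur_s duration of the constant-amplitude segment (s).
#' @param tone optional probe-tone description, see [probe_tone()].
#' @param seed integer seed for the noise carrier.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(sample_rate_hz = 44100, mod_freq_hz = 3,
                          mod_depth = 0.8, rhythmic_dur_s = 3,
                          constant_dur_s = 0.833, tone = NULL, seed = 1L) {
  assert_scalar_pos(sample_rate_hz, "sample_rate_hz")
  assert_scalar_pos(mod_freq_hz, "mod_freq_hz")
  if (!is.numeric(mod_depth) || mod_depth < 0 || mod_depth > 1)
    stop("`mod_depth` must lie in [0, 1]")
  n_cycles <- mod_freq_hz * rhythmic_dur_s
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    stop("`rhythmic_dur_s` must contain an integer number of modulation cycles")
  if (!is.null(tone) && tone$freq_hz >= sample_rate_hz / 2)
    stop("tone frequency violates the Nyquist limit for this sample rate")
  structure(list(sample_rate_hz = sample_rate_hz, mod_freq_hz = mod_freq_hz,
                 mod_depth = mod_depth, rhythmic_dur_s = rhythmic_dur_s,
                 constant_dur_s = constant_dur_s, tone = tone,
                 seed = as.integer(seed)),
            class = "stimulus_spec")
}

#' Describe a peri-threshold probe tone
#'
#' @param freq_hz tone frequency (Hz).
#' @param dur_ms tone duration (ms).
#' @param rise_decay_ms raised-cosine rise/decay time (ms).
#' @param position_index temporal position 1-5; positions are separated by a
#'   quarter modulation cycle, beginning at the constant-amplitude segment.
#' @param level_index amplitude level 1-3; the three levels span
#'   `level_range_db` dB, centered on `base_amplitude`.
#' @param level_range_db total level range (dB).
#' @param base_amplitude linear amplitude at the middle level, relative to the
#'   unit-RMS noise carrier.
#' @export
probe_tone <- function(freq_hz = 1000, dur_ms = 50, rise_decay_ms = 5,
                       position_index = 1L, level_index = 2L,
                       level_range_db = 12, base_amplitude = 0.05) {
  stopifnot(position_index %in% 1:5, level_index %in% 1:3)
  list(freq_hz = freq_hz, dur_ms = dur_ms, rise_decay_ms = rise_decay_ms,
       position_index = as.integer(position_index),
       level_index = as.integer(level_index),
       level_range_db = level_range_db, base_amplitude = base_amplitude)
}

#' Generate the amplitude-modulated noise stimulus
#'
#' Returns the waveform together with the generating modulator and the ground
#' truth acoustic-edge times. Edges are the points of maximum envelope
#' derivative on each rising slope; with a cosine modulator starting at its
#' peak these fall at `(k + 3/4) / f` for cycles `k = 0, ..., n - 1`, one per
#' acoustic pulse.
#'
#' @param spec a [stimulus_spec()].
#' @return A list of class `am_stimulus` with elements `waveform`, `envelope`
#'   (the modulator), `t`, `sample_rate_hz`, `edge_times`, `pulse_peak_times`,
#'   `n_pulses`, `rhythmic_dur_s`, `constant_dur_s`, `mod_freq_hz`, and
#'   `tone_onset_s` (NA until a tone is embedded).
#' @export
make_am_noise_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  fs <- spec$sample_rate_hz
  total <- spec$rhythmic_dur_s + spec$constant_dur_s
  n <- round(total * fs)
  t <- (seq_len(n) - 1L) / fs
  m <- rep(1, n)
  rhythmic <- t < spec$rhythmic_dur_s
  m[rhythmic] <- 1 - spec$mod_depth *
    (1 - cos(2 * pi * spec$mod_freq_hz * t[rhythmic])) / 2
  set.seed(spec$seed)
  carrier <- stats::rnorm(n)
  n_cycles <- round(spec$mod_freq_hz * spec$rhythmic_dur_s)
  period <- 1 / spec$mod_freq_hz
  if (spec$mod_depth > 0) {
    edge_times <- (seq_len(n_cycles) - 1L + 3 / 4) * period
  } else {
    edge_times <- numeric(0)
  }
  structure(list(waveform = carrier * m, envelope = m, t = t,
                 sample_rate_hz = fs, edge_times = edge_times,
                 pulse_peak_times = seq_len(n_cycles) * period,
                 n_pulses = if (spec$mod_depth > 0) n_cycles else 0L,
                 rhythmic_dur_s = spec$rhythmic_dur_s,
                 constant_dur_s = spec$constant_dur_s,
                 mod_freq_hz = spec$mod_freq_hz,
                 tone_onset_s = NA_real_),
            class = "am_stimulus")
}

#' Embed the probe tone into a generated stimulus
#'
#' Adds a gated sinusoid at one of five quarter-cycle positions within the
#' constant-amplitude segment, at one of three levels spanning the specified
#' dB range (level 2 sits at `base_amplitude`).
#'
#' @param stim an `am_stimulus`.
#' @param spec the [stimulus_spec()] carrying a non-NULL `tone`.
#' @return The stimulus with the tone added and `tone_onset_s` set.
#' @export
embed_probe_tone <- function(stim, spec) {
  stopifnot(inherits(stim, "am_stimulus"), inherits(spec, "stimulus_spec"))
  tone <- spec$tone
  if (is.null(tone)) stop("`spec` carries no tone description")
  fs <- stim$sample_rate_hz
  quarter <- 1 / spec$mod_freq_hz / 4
  onset <- stim$rhythmic_dur_s + (tone$position_index - 1L) * quarter
  dur <- tone$dur_ms / 1000
  total <- stim$rhythmic_dur_s + stim$constant_dur_s
  if (onset + dur > total + 1e-9)
    stop("tone position falls outside the constant-amplitude segment")
  level_db <- (tone$level_index - 2L) * tone$level_range_db / 2
  amp <- tone$base_amplitude * 10^(level_db / 20)
  n_tone <- round(dur * fs)
  tt <- (seq_len(n_tone) - 1L) / fs
  gate <- rep(1, n_tone)
  n_ramp <- round(tone$rise_decay_ms / 1000 * fs)
  if (n_ramp > 0) {
    ramp <- (1 - cos(pi * seq_len(n_ramp) / n_ramp)) / 2
    gate[seq_len(n_ramp)] <- ramp
    gate[(n_tone - n_ramp + 1L):n_tone] <- rev(ramp)
  }
  i0 <- round(onset * fs) + 1L
  idx <- i0:(i0 + n_tone - 1L)
  stim$waveform[idx] <- stim$waveform[idx] + amp * sin(2 * pi * tone$freq_hz * tt) * gate
  stim$tone_onset_s <- onset
  stim
}

#' Generate quasi-rhythmic speech-like envelopes with annotated edges
#'
#' Each sentence envelope is a sum of asymmetric pulses (raised-cosine rise,
#' exponential decay) at jittered inter-pulse intervals, emulating the
#' envelope statistics of short spoken sentences (about 2 s, about 3.5 edges/s).
#' Planted acoustic edges are the maximum-derivative points of each rise;
#' syllable-onset annotations are a jittered, slightly denser event stream
#' shifted earlier than the edges, so the two annotations are dissociable.
#'
#' @param n_sentences number of sentences.
#' @param dur_s_mean,dur_s_sd sentence duration distribution (s).
#' @param edge_rate_hz mean acoustic-edge rate (Hz); the default reproduces
#'   about 6.9 edges over 1.97 s.
#' @param syllable_rate_hz mean syllable rate (Hz); default about 7.7 per
#'   sentence.
#' @param fs envelope sample rate (Hz).
#' @param rise_ms,decay_ms pulse rise time and decay constant (ms).
#' @param seed integer seed.
#' @return A list of class `speech_envelope_set`; each element has `t`,
#'   `envelope`, `fs`, `edge_times`, `syllable_times`, `duration_s`.
#' @export
make_speech_like_envelope <- function(n_sentences = 10, dur_s_mean = 1.97,
                                      dur_s_sd = 0.36,
                                      edge_rate_hz = 6.9 / 1.97,
                                      syllable_rate_hz = 7.7 / 1.97,
                                      fs = 1000, rise_ms = 60, decay_ms = 120,
                                      seed = 1L) {
  stopifnot(edge_rate_hz >= 0, syllable_rate_hz >= 0)
  set.seed(as.integer(seed))
  rise <- rise_ms / 1000
  tau <- decay_ms / 1000
  out <- vector("list", n_sentences)
  for (s in seq_len(n_sentences)) {
    dur <- max(0.8, stats::rnorm(1, dur_s_mean, dur_s_sd))
    n <- round(dur * fs)
    t <- (seq_len(n) - 1L) / fs
    env <- rep(0.02, n)
    edge_times <- numeric(0)
    syllable_times <- numeric(0)
    if (edge_rate_hz > 0) {
      mean_ipi <- 1 / edge_rate_hz
      onsets <- numeric(0)
      pos <- 0.08
      while (pos < dur - rise - 0.05) {
        onsets <- c(onsets, pos)
        pos <- pos + mean_ipi * stats::runif(1, 0.7, 1.3)
      }
      for (o in onsets) {
        a <- stats::runif(1, 0.5, 1)
        seg <- t >= o
        tl <- t[seg] - o
        pulse <- ifelse(tl < rise, (1 - cos(pi * tl / rise)) / 2,
                        exp(-(tl - rise) / tau))
        env[seg] <- env[seg] + a * pulse
        edge_times <- c(edge_times, o + rise / 2)
      }
      # syllable onsets: pulse starts jittered earlier, plus extra events to
      # reach the syllable rate
      syllable_times <- pmax(0.01, onsets - 0.05 + stats::rnorm(length(onsets), 0, 0.02))
      n_extra <- max(0L, round(syllable_rate_hz * dur) - length(onsets))
      if (n_extra > 0)
        syllable_times <- c(syllable_times, stats::runif(n_extra, 0.05, dur - 0.05))
      syllable_times <- sort(syllable_times)
    }
    out[[s]] <- list(t = t, envelope = env, fs = fs,
                     edge_times = edge_times, syllable_times = syllable_times,
                     duration_s = dur)
  }
  structure(out, class = "speech_envelope_set")
}
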