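# Synthetic electrode cohorts: geometry, planted ground truth, and the
# forward model that realizes sustained / transient response archetypes.

#' Build a synthetic supratemporal electrode table
#'
#' Lays electrodes along an anteroposterior supratemporal axis. HG/TTS
#' electrodes span the mediolateral extent (for traveling-wave fitting) at
#' anterior positions; PT electrodes sit posterior; STG electrodes lateral.
#'
#' @param n_hgtts,n_pt,n_stg electrode counts per region.
#' @param hemisphere "left" or "right".
#' @param dominant logical; whether this hemisphere is language-dominant.
#' @param ml_extent_mm mediolateral extent of the HG/TTS span (mm).
#' @param seed integer seed for coordinate jitter.
#' @return A data.frame with columns `id`, `x`, `y`, `z`, `region`,
#'   `hemisphere`, `dominant`, `mediolateral_pos_mm`, `anteroposterior_pos_mm`.
#' @export
make_electrode_table <- function(n_hgtts = 8, n_pt = 6, n_stg = 4,
                                 hemisphere = "left", dominant = TRUE,
                                 ml_extent_mm = 16, seed = 1L) {
  set.seed(as.integer(seed))
  n <- n_hgtts + n_pt + n_stg
  region <- c(rep("HG/TTS", n_hgtts), rep("PT", n_pt), rep("STG", n_stg))
  ml <- c(if (n_hgtts) seq(0, ml_extent_mm, length.out = n_hgtts) else numeric(0),
          stats::runif(n_pt, 0, max(ml_extent_mm, 1)),
          stats::runif(n_stg, max(ml_extent_mm, 1), max(ml_extent_mm, 1) + 10))
  ap <- c(stats::runif(n_hgtts, 0, 12), stats::runif(n_pt, 18, 30),
          stats::runif(n_stg, 5, 25))
  data.frame(id = sprintf("e%03d", seq_len(n)),
             x = ml, y = -ap, z = stats::rnorm(n, 0, 0.5),
             region = region, hemisphere = hemisphere, dominant = dominant,
             mediolateral_pos_mm = ml, anteroposterior_pos_mm = ap,
             stringsAsFactors = FALSE)
}

#' Plant ground-truth response parameters for a cohort
#'
#' Assigns a response archetype per electrode by region: HG/TTS electrodes are
#' sustained (envelope-locked high gamma, edge-locked theta reset,
#' traveling-wave lags), PT electrodes in the dominant hemisphere are
#' transient (onset burst, articulation-suppressed), everything else is null.
#' Transient archetypes are never planted outside dominant cortex.
#'
#' @param electrodes electrode table from [make_electrode_table()].
#' @param hg_lag_ms mean lag of high-gamma envelope tracking (ms).
#' @param theta_reset_persist_cycles number of additional expected-edge resets
#'   after the last acoustic pulse (default 1, the planted persistence).
#' @param wave_velocity_m_per_s mediolateral traveling-wave speed (m/s).
#' @param snr per-electrode signal-to-noise ratio of each planted band-limited
#'   component relative to the in-band 1/f background.
#' @param archetype optional explicit archetype vector overriding the
#'   region-based assignment (values "sustained", "transient", "mixed",
#'   "null").
#' @return A data.frame of class `ground_truth`, one row per electrode.
#' @export
make_ground_truth <- function(electrodes, hg_lag_ms = 45,
                              theta_reset_persist_cycles = 1,
                              wave_velocity_m_per_s = 0.1, snr = 3,
                              archetype = NULL) {
  if (is.null(archetype)) {
    archetype <- ifelse(electrodes$region == "HG/TTS", "sustained",
                 ifelse(electrodes$region == "PT" & electrodes$dominant,
                        "transient", "null"))
  }
  stopifnot(length(archetype) == nrow(electrodes),
            theta_reset_persist_cycles >= 0)
  if (any(archetype == "transient" & !electrodes$dominant))
    stop("transient archetypes may only be planted in dominant-hemisphere electrodes")
  out <- data.frame(id = electrodes$id, archetype = archetype,
                    hg_lag_ms = hg_lag_ms,
                    theta_reset_persist_cycles = theta_reset_persist_cycles,
                    wave_velocity_m_per_s = wave_velocity_m_per_s,
                    articulation_suppressed = archetype == "transient",
                    snr = snr, stringsAsFactors = FALSE)
  class(out) <- c("ground_truth", "data.frame")
  out
}

# Edge-locked theta bursts: each (possibly extrapolated) acoustic edge
# triggers a Hann-windowed theta packet with phase locked to the edge. The
# packet is centered on the edge (anticipatory alignment): excitability is
# organized around the expected edge, not strictly after it.
theta_burst_train <- function(t, events, f0 = 6, dur_s = 0.125,
                              lead_s = 0.05) {
  x <- numeric(length(t))
  for (ek in events) {
    t0 <- ek - lead_s
    idx <- which(t >= t0 & t < t0 + dur_s)
    if (!length(idx)) next
    u <- (t[idx] - t0) / dur_s
    x[idx] <- x[idx] + 0.5 * (1 - cos(2 * pi * u)) * cos(2 * pi * f0 * (t[idx] - ek))
  }
  x
}

# Raised-cosine bump of given duration peaking at dur/2.
onset_bump <- function(t, onset = 0, dur_s = 0.33) {
  w <- numeric(length(t))
  idx <- which(t >= onset & t < onset + dur_s)
  w[idx] <- 0.5 * (1 - cos(2 * pi * (t[idx] - onset) / dur_s))
  w
}

# In-band RMS of a signal (FFT brick-wall estimate), for SNR scaling.
band_rms <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1L)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  X[!(f >= f_lo & f <= f_hi)] <- 0
  stats::sd(Re(stats::fft(X, inverse = TRUE)) / n)
}

# Shared per-electrode synthesis of one trial segment.
# t_rel: time relative to stimulus onset; env: stimulus envelope sampled on
# t_rel (0 outside stimulus); edges: edge times (incl. extrapolated resets).
.synth_trial <- function(t_rel, env, edges, trough_times, arch, lag_s,
                         amp, fs) {
  n <- length(t_rel)
  sig <- numeric(n)
  if (arch %in% c("sustained", "mixed")) {
    sc <- if (arch == "mixed") 0.6 else 1
    env_lag <- stats::approx(t_rel, env, t_rel - lag_s, rule = 2)$y
    # low-latency high-magnitude evoked response at stimulus onset, on top
    # of the sustained envelope tracking
    hg_amp <- 0.15 + env_lag + 1.5 * onset_bump(t_rel, 0, 0.1)
    sig <- sig + sc * amp["hg"] * hg_amp * bandpass_noise(n, fs, 65, 115)
    sig <- sig + sc * amp["theta"] * theta_burst_train(t_rel, edges)
    if (length(trough_times)) {
      beta_amp <- rep(0.3, n)
      for (tt in trough_times)
        beta_amp <- beta_amp + exp(-(t_rel - tt)^2 / (2 * 0.04^2))
      sig <- sig + sc * amp["beta"] * beta_amp * bandpass_noise(n, fs, 15, 30)
    }
  }
  if (arch %in% c("transient", "mixed")) {
    sc <- if (arch == "mixed") 0.6 else 1
    w <- onset_bump(t_rel, 0, 0.33)
    sig <- sig + sc * amp["hg"] * (0.15 + 2.5 * w) * bandpass_noise(n, fs, 65, 115)
    sig <- sig + sc * amp["theta"] * theta_burst_train(t_rel, 0, f0 = 6, dur_s = 0.2)
  }
  if (arch == "null")
    sig <- sig + amp["hg"] * 0.15 * bandpass_noise(n, fs, 65, 115)
  sig
}

#' Simulate cohort recordings for the rhythmic-noise paradigm
#'
#' Forward model realizing the planted archetypes: sustained electrodes carry
#' high-gamma amplitude tracking the stimulus envelope at a per-electrode lag
#' (`hg_lag_ms` plus a mediolateral traveling-wave term centered on the
#' array), edge-locked theta phase resets that continue for
#' `theta_reset_persist_cycles` expected edges after the last pulse, and beta
#' resynchronization at envelope troughs. Transient electrodes carry a single
#' onset burst with a broadband phase reset. A 1/f^1.5 background is added;
#' planted component amplitudes are `snr` times the in-band background RMS.
#'
#' @param stim an `am_stimulus` from [make_am_noise_stimulus()].
#' @param electrodes electrode table.
#' @param truth [make_ground_truth()] output, same electrodes.
#' @param n_trials trials per condition.
#' @param fs neural sample rate (Hz).
#' @param pre_s,post_s silent padding around the stimulus in each trial (s).
#' @param seed integer seed.
#' @param articulation if TRUE also simulate an articulation-aligned
#'   recording in which `articulation_suppressed` electrodes produce no
#'   stimulus-locked response.
#' @return A list with `listening` (a [recording()]) and, if requested,
#'   `articulation`.
#' @export
simulate_neural_response <- function(stim, electrodes, truth, n_trials = 20,
                                     fs = 500, pre_s = 1, post_s = 1,
                                     seed = 1L, articulation = FALSE) {
  stopifnot(inherits(stim, "am_stimulus"))
  if (nrow(electrodes) != nrow(truth))
    stop("electrode table and ground truth have mismatched lengths")
  set.seed(as.integer(seed))
  n_el <- nrow(electrodes)
  total <- stim$rhythmic_dur_s + stim$constant_dur_s
  seg_dur <- pre_s + total + post_s
  seg_n <- round(seg_dur * fs)
  n_samp <- seg_n * n_trials
  t_rel <- (seq_len(seg_n) - 1L) / fs - pre_s
  env <- stats::approx(stim$t, stim$envelope, t_rel, rule = 1)$y
  env[is.na(env)] <- 0
  period <- 1 / stim$mod_freq_hz
  ml_center <- mean(range(electrodes$mediolateral_pos_mm))
  trough_times <- (seq_len(stim$n_pulses) - 1L/2) * period

  build <- function(mode) {
    data <- matrix(0, n_el, n_samp)
    for (e in seq_len(n_el)) {
      arch <- truth$archetype[e]
      if (mode == "articulation" && arch == "transient" &&
          truth$articulation_suppressed[e]) arch <- "null"
      wave_lag <- (electrodes$mediolateral_pos_mm[e] - ml_center) / 1000 /
        truth$wave_velocity_m_per_s[e]
      lag_s <- truth$hg_lag_ms[e] / 1000 + wave_lag
      edges <- stim$edge_times
      if (truth$theta_reset_persist_cycles[e] > 0 && length(edges))
        edges <- c(edges, max(edges) +
                     period * seq_len(round(truth$theta_reset_persist_cycles[e])))
      noise <- one_over_f_noise(n_samp, fs, 1.5)
      amp <- truth$snr[e] * c(hg = band_rms(noise[1:min(n_samp, 8L * fs)], fs, 65, 115),
                              theta = band_rms(noise[1:min(n_samp, 8L * fs)], fs, 4, 8),
                              beta = band_rms(noise[1:min(n_samp, 8L * fs)], fs, 15, 30))
      ch <- noise
      for (tr in seq_len(n_trials)) {
        i0 <- (tr - 1L) * seg_n
        if (mode == "listening") {
          ch[i0 + seq_len(seg_n)] <- ch[i0 + seq_len(seg_n)] +
            .synth_trial(t_rel, env, edges, trough_times, arch, lag_s, amp, fs)
        } else {
          # articulation epochs: sustained electrodes stay engaged for the
          # utterance; suppressed transients contribute nothing
          if (arch %in% c("sustained", "mixed")) {
            w <- as.numeric(t_rel >= 0 & t_rel < 1.5)
            ch[i0 + seq_len(seg_n)] <- ch[i0 + seq_len(seg_n)] +
              amp["hg"] * (0.15 + 0.8 * w) * bandpass_noise(seg_n, fs, 65, 115)
          } else if (arch == "transient") {
            w <- onset_bump(t_rel, 0, 0.33)
            ch[i0 + seq_len(seg_n)] <- ch[i0 + seq_len(seg_n)] +
              amp["hg"] * (0.15 + 2.5 * w) * bandpass_noise(seg_n, fs, 65, 115)
          }
        }
      }
      data[e, ] <- ch
    }
    ev_type <- if (mode == "listening") "stimulus_onset" else "articulation_onset"
    events <- data.frame(onset_s = (seq_len(n_trials) - 1L) * seg_dur + pre_s,
                         duration_s = if (mode == "listening") total else 1.5,
                         type = ev_type, trial_id = seq_len(n_trials),
                         stringsAsFactors = FALSE)
    recording(data, fs, electrodes$id, electrodes, events)
  }

  out <- list(listening = build("listening"))
  if (articulation) out$articulation <- build("articulation")
  out
}

#' Simulate cohort recordings for speech-like envelopes
#'
#' Sustained electrodes track each sentence envelope in high-gamma amplitude
#' at `hg_lag_ms` and show edge-locked theta resets; syllable onsets (a
#' dissociable annotation stream) trigger nothing, so edge-vs-syllable
#' contrasts have a planted direction.
#'
#' @param envs a `speech_envelope_set`.
#' @param electrodes,truth cohort description as in
#'   [simulate_neural_response()].
#' @param fs neural sample rate (Hz).
#' @param pre_s,post_s silent padding per sentence (s).
#' @param seed integer seed.
#' @return A [recording()] whose events table carries `stimulus_onset`,
#'   `edge`, and `syllable` rows.
#' @export
simulate_speech_response <- function(envs, electrodes, truth, fs = 500,
                                     pre_s = 0.5, post_s = 0.5, seed = 1L) {
  stopifnot(inherits(envs, "speech_envelope_set"))
  set.seed(as.integer(seed))
  n_el <- nrow(electrodes)
  seg_n <- vapply(envs, function(s) round((pre_s + s$duration_s + post_s) * fs), 0)
  offsets <- c(0, cumsum(seg_n))
  n_samp <- offsets[length(offsets)]
  env_full <- numeric(n_samp)
  ev <- list()
  for (s in seq_along(envs)) {
    sn <- envs[[s]]
    t_loc <- (seq_len(seg_n[s]) - 1L) / fs - pre_s
    env_full[offsets[s] + seq_len(seg_n[s])] <-
      stats::approx(sn$t, sn$envelope, t_loc, rule = 1)$y
    t0 <- offsets[s] / fs + pre_s
    ev[[s]] <- rbind(
      data.frame(onset_s = t0, duration_s = sn$duration_s,
                 type = "stimulus_onset", trial_id = s),
      data.frame(onset_s = t0 + sn$edge_times, duration_s = 0,
                 type = "edge", trial_id = s),
      data.frame(onset_s = t0 + sn$syllable_times, duration_s = 0,
                 type = "syllable", trial_id = s))
  }
  env_full[is.na(env_full)] <- 0
  events <- do.call(rbind, ev)
  events <- events[order(events$type, events$onset_s), ]
  t_all <- (seq_len(n_samp) - 1L) / fs
  edge_all <- events$onset_s[events$type == "edge"]
  data <- matrix(0, n_el, n_samp)
  for (e in seq_len(n_el)) {
    noise <- one_over_f_noise(n_samp, fs, 1.5)
    amp <- truth$snr[e] * c(hg = band_rms(noise[1:min(n_samp, 8L * fs)], fs, 65, 115),
                            theta = band_rms(noise[1:min(n_samp, 8L * fs)], fs, 4, 8))
    ch <- noise
    if (truth$archetype[e] %in% c("sustained", "mixed")) {
      lag_s <- truth$hg_lag_ms[e] / 1000
      env_lag <- stats::approx(t_all, env_full, t_all - lag_s, rule = 2)$y
      ch <- ch + amp["hg"] * (0.15 + env_lag) * bandpass_noise(n_samp, fs, 65, 115)
      ch <- ch + amp["theta"] * theta_burst_train(t_all, edge_all)
    } else if (truth$archetype[e] == "null") {
      ch <- ch + amp["hg"] * 0.15 * bandpass_noise(n_samp, fs, 65, 115)
    }
    data[e, ] <- ch
  }
  rec <- recording(data, fs, electrodes$id, electrodes, events)
  attr(rec, "envelope") <- env_full
  rec
}

#' Simulate the tone-detection behavior of a cohort
#'
#' Per-trial responses are drawn from a logistic psychometric function of
#' tone level (dB re threshold), with an additive detectability bonus (in
#' logits) at temporal position 2 for the lowest level only -- the planted
#' behavioral signature of rhythmic temporal prediction. Half the trials are
#' tone-absent; responses there are false alarms at `fa_rate`.
#'
#' @param n_subjects,n_trials cohort size; trials are balanced over 5
#'   positions x 3 levels on tone-present trials.
#' @param intercept,slope psychometric parameters (logit scale; slope per dB).
#' @param position2_bonus additive logit bonus at position 2, lowest level.
#' @param fa_rate false-alarm rate on tone-absent trials.
#' @param level_db the three tone levels (dB re threshold), spanning 12 dB.
#' @param seed integer seed.
#' @return A data.frame of class `detection_trial_table`.
#' @export
simulate_detection_behavior <- function(n_subjects = 37, n_trials = 100,
                                        intercept = 1.0, slope = 0.25,
                                        position2_bonus = 1.2, fa_rate = 0.1,
                                        level_db = c(-6, 0, 6), seed = 1L) {
  set.seed(as.integer(seed))
  stopifnot(n_trials %% 2 == 0, length(level_db) == 3)
  rows <- vector("list", n_subjects)
  n_present <- n_trials %/% 2
  cells <- expand.grid(position_index = 1:5, level_index = 1:3)
  for (s in seq_len(n_subjects)) {
    idx <- rep(seq_len(nrow(cells)), length.out = n_present)
    idx <- sample(idx)
    present <- cells[idx, ]
    db <- level_db[present$level_index]
    bonus <- ifelse(present$position_index == 2 & present$level_index == 1,
                    position2_bonus, 0)
    p_hit <- stats::plogis(intercept + slope * db + bonus)
    df_p <- data.frame(subject_id = s, tone_present = TRUE,
                       level_index = present$level_index,
                       position_index = present$position_index,
                       response = stats::runif(n_present) < p_hit)
    df_a <- data.frame(subject_id = s, tone_present = FALSE,
                       level_index = NA_integer_, position_index = NA_integer_,
                       response = stats::runif(n_trials - n_present) < fa_rate)
    df <- rbind(df_p, df_a)
    df <- df[sample(nrow(df)), ]
    df$trial_id <- seq_len(nrow(df))
    rows[[s]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("detection_trial_table", "data.frame")
  out
}

#' Simulate trial-averaged response features for a large cohort
#'
#' Generates the electrodes x time feature matrices that feed the
#' sustained/transient factorization directly at the feature level (trial-mean
#' high-gamma percent change and baseline-referenced ITC change), so that
#' cohorts at the scale of hundreds of electrodes stay tractable. Each
#' electrode mixes the archetype waveforms with a log-normal response gain
#' shared between listening and articulation, plus additive noise. Transient
#' electrodes are suppressed in the articulation features.
#'
#' @param n_electrodes cohort size.
#' @param prop_sustained,prop_transient,prop_mixed archetype proportions; the
#'   remainder is null. Defaults emulate a supratemporal cohort in which a
#'   large minority of electrodes respond.
#' @param mod_freq_hz,rhythmic_dur_s stimulus rhythm (3 Hz, 3 s).
#' @param feature_fs feature sample rate (Hz).
#' @param gain_log_mean,gain_log_sd log-normal response gain parameters; the
#'   default mean gain (about 50) puts class weights on the percent-change
#'   scale on which a class-bias threshold of 10 is meaningful.
#' @param noise_sd additive feature noise, as a fraction of electrode gain.
#' @param seed integer seed.
#' @return A list with `A_power`, `A_itc` (m x n matrices, listening),
#'   `A_power_artic` (articulation), `time`, `truth` (archetype labels),
#'   `gain`, and `electrodes` (positions with an anteroposterior gradient).
#' @export
simulate_feature_cohort <- function(n_electrodes = 349, prop_sustained = 0.22,
                                    prop_transient = 0.27, prop_mixed = 0.03,
                                    mod_freq_hz = 3, rhythmic_dur_s = 3,
                                    feature_fs = 50, gain_log_mean = log(50),
                                    gain_log_sd = 0.4, noise_sd = 0.12,
                                    seed = 1L) {
  set.seed(as.integer(seed))
  time <- seq(-0.3, 4.2, by = 1 / feature_fs)
  period <- 1 / mod_freq_hz
  stim_on <- time >= 0 & time < rhythmic_dur_s
  # archetypes, unit peak
  comb <- numeric(length(time))
  comb[stim_on] <- 0.35 + 0.65 * (1 + cos(2 * pi * mod_freq_hz * time[stim_on])) / 2
  comb[time >= rhythmic_dur_s & time < rhythmic_dur_s + 0.833] <- 0.6
  trans <- onset_bump(time, 0, 0.35)
  itc_sus <- numeric(length(time))
  itc_sus[time >= 0.2 & time < rhythmic_dur_s + period] <- 1
  itc_trans <- onset_bump(time, 0, 0.3)
  # articulation: the sustained response is preserved (self-produced speech
  # is quasi-rhythmic, so HG keeps tracking the envelope); transients vanish
  artic_sus <- 0.8 * comb

  n_s <- round(n_electrodes * prop_sustained)
  n_t <- round(n_electrodes * prop_transient)
  n_m <- round(n_electrodes * prop_mixed)
  n_0 <- n_electrodes - n_s - n_t - n_m
  arch <- sample(c(rep("sustained", n_s), rep("transient", n_t),
                   rep("mixed", n_m), rep("null", n_0)))
  gain <- exp(stats::rnorm(n_electrodes, gain_log_mean, gain_log_sd))
  gain[arch == "null"] <- gain[arch == "null"] * 0.02
  mix <- function(a) switch(a, sustained = c(1, 0), transient = c(0, 1),
                            mixed = c(0.5, 0.5), null = c(0, 0))
  Wt <- t(vapply(arch, mix, numeric(2)))
  noise <- function() matrix(stats::rnorm(n_electrodes * length(time), 0,
                                          noise_sd * exp(gain_log_mean)),
                             n_electrodes)
  A_power <- gain * (Wt[, 1] %o% comb + Wt[, 2] %o% trans) + noise()
  A_itc <- gain * (Wt[, 1] %o% itc_sus + Wt[, 2] %o% itc_trans) + noise()
  A_artic <- gain * (Wt[, 1] %o% artic_sus) + noise()
  # anteroposterior gradient: sustained anterior, transient posterior
  ap <- stats::runif(n_electrodes, 0, 30) +
    ifelse(arch == "sustained", -8, ifelse(arch == "transient", 8, 0))
  list(A_power = pmax(A_power, 0), A_itc = pmax(A_itc, 0),
       A_power_artic = pmax(A_artic, 0), time = time,
       truth = arch, gain = gain,
       electrodes = data.frame(id = sprintf("e%03d", seq_len(n_electrodes)),
                               anteroposterior_pos_mm = ap,
                               stringsAsFactors = FALSE))
}
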