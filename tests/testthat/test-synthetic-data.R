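# Stimulus generator, speech-like envelopes, neural forward model, behavior.

test_that("AM stimulus has one pulse and one edge per modulation cycle", {
  stim3 <- make_am_noise_stimulus(stimulus_spec(sample_rate_hz = 8000))
  expect_equal(stim3$n_pulses, 9)
  expect_length(stim3$edge_times, 9)
  stim5 <- make_am_noise_stimulus(stimulus_spec(sample_rate_hz = 8000,
                                                mod_freq_hz = 5))
  expect_equal(stim5$n_pulses, 15)
  # edges sit on the rising slope, a quarter cycle before each peak
  expect_equal(stim3$edge_times[1], 0.25)
  expect_equal(diff(stim3$edge_times), rep(1 / 3, 8), tolerance = 1e-12)
})

test_that("modulation depth follows the peak-referenced convention", {
  stim <- make_am_noise_stimulus(stimulus_spec(sample_rate_hz = 8000,
                                               mod_freq_hz = 5))
  rhythmic <- stim$envelope[stim$t < stim$rhythmic_dur_s]
  expect_equal(max(rhythmic), 1, tolerance = 1e-9)
  expect_equal((max(rhythmic) - min(rhythmic)) / max(rhythmic), 0.8,
               tolerance = 1e-6)
  # zero depth degenerates to a constant envelope with no edges
  flat <- make_am_noise_stimulus(stimulus_spec(sample_rate_hz = 8000,
                                               mod_depth = 0))
  expect_true(all(flat$envelope == 1))
  expect_length(flat$edge_times, 0)
})

test_that("stimulus segment durations and validation hold", {
  spec <- stimulus_spec(sample_rate_hz = 8000)
  stim <- make_am_noise_stimulus(spec)
  n_const <- sum(stim$t >= stim$rhythmic_dur_s)
  expect_equal(n_const / 8000, spec$constant_dur_s, tolerance = 1 / 8000)
  expect_error(stimulus_spec(rhythmic_dur_s = 3.1), "integer number")
  expect_error(stimulus_spec(sample_rate_hz = 1500,
                             tone = probe_tone(freq_hz = 1000)), "Nyquist")
})

test_that("probe tone lands at quarter-cycle positions and spans 12 dB", {
  base <- make_am_noise_stimulus(stimulus_spec(sample_rate_hz = 8000, seed = 3))
  spec2 <- stimulus_spec(sample_rate_hz = 8000, seed = 3,
                         tone = probe_tone(position_index = 2))
  with_tone <- embed_probe_tone(base, spec2)
  expect_equal(with_tone$tone_onset_s, 3 + 1 / 12, tolerance = 1e-9)
  # level 3 vs level 1 amplitude ratio is the full 12 dB range
  amp_at <- function(level) {
    sp <- stimulus_spec(sample_rate_hz = 8000, seed = 3,
                        tone = probe_tone(position_index = 1,
                                          level_index = level))
    st <- embed_probe_tone(base, sp)
    max(abs(st$waveform - base$waveform))
  }
  expect_equal(20 * log10(amp_at(3) / amp_at(1)), 12, tolerance = 0.1)
  # zero-amplitude tone leaves the waveform unchanged
  sp0 <- stimulus_spec(sample_rate_hz = 8000, seed = 3,
                       tone = probe_tone(base_amplitude = 0))
  expect_identical(embed_probe_tone(base, sp0)$waveform, base$waveform)
  # a position outside the constant segment is rejected
  spshort <- stimulus_spec(sample_rate_hz = 8000, constant_dur_s = 1 / 3,
                           seed = 3, tone = probe_tone(position_index = 5))
  stshort <- make_am_noise_stimulus(spshort)
  expect_error(embed_probe_tone(stshort, spshort), "outside")
})

test_that("speech-like envelopes match the target edge statistics", {
  envs <- make_speech_like_envelope(n_sentences = 40, seed = 7)
  edges <- vapply(envs, function(s) length(s$edge_times), 0)
  durs <- vapply(envs, function(s) s$duration_s, 0)
  expect_equal(mean(edges), 6.9, tolerance = 0.15 * 6.9)
  expect_equal(mean(durs), 1.97, tolerance = 0.15 * 1.97)
  # syllable annotations are denser and shifted: dissociable from edges
  syl <- vapply(envs, function(s) length(s$syllable_times), 0)
  expect_gt(mean(syl), mean(edges))
  flat <- make_speech_like_envelope(n_sentences = 2, edge_rate_hz = 0, seed = 1)
  expect_length(flat[[1]]$edge_times, 0)
  expect_lt(diff(range(flat[[1]]$envelope)), 1e-12)
})

test_that("generated envelopes are recovered by the edge detector", {
  envs <- make_speech_like_envelope(n_sentences = 10, seed = 11)
  set.seed(12)
  stats <- vapply(envs, function(sn) {
    noise_sd <- sqrt(mean(sn$envelope^2)) / 10   # 20 dB SNR
    noisy <- pmax(sn$envelope + rnorm(length(sn$envelope), 0, noise_sd), 0)
    det <- detect_edges(as_envelope_trace(noisy, sn$fs))
    unlist(event_match_stats(det$edge_times, sn$edge_times, 0.05)[1:2])
  }, numeric(2))
  expect_gte(mean(stats[2, ]), 0.95)
})

test_that("regeneration with the same seed is byte-identical", {
  a <- make_am_noise_stimulus(stimulus_spec(sample_rate_hz = 4000, seed = 9))
  b <- make_am_noise_stimulus(stimulus_spec(sample_rate_hz = 4000, seed = 9))
  expect_identical(a, b)
  e1 <- make_speech_like_envelope(n_sentences = 3, seed = 4)
  e2 <- make_speech_like_envelope(n_sentences = 3, seed = 4)
  expect_identical(e1, e2)
  d1 <- simulate_detection_behavior(n_subjects = 3, seed = 2)
  d2 <- simulate_detection_behavior(n_subjects = 3, seed = 2)
  expect_identical(d1, d2)
})

test_that("ground truth forbids transient archetypes outside dominant cortex", {
  el <- make_electrode_table(2, 2, 0, dominant = FALSE, seed = 1)
  truth <- make_ground_truth(el)
  expect_true(all(truth$archetype != "transient"))
  expect_error(make_ground_truth(el, archetype = rep("transient", 4)),
               "dominant")
  expect_error(
    simulate_neural_response(
      make_am_noise_stimulus(stimulus_spec(sample_rate_hz = 4000)),
      el, truth[1:2, ]),
    "mismatched")
})

test_that("a near-noiseless sustained electrode carries the planted lag", {
  spec <- stimulus_spec(sample_rate_hz = 8000, seed = 21)
  stim <- make_am_noise_stimulus(spec)
  el <- make_electrode_table(1, 0, 0, ml_extent_mm = 0, seed = 22)
  truth <- make_ground_truth(el, hg_lag_ms = 80, snr = 50)
  sim <- simulate_neural_response(stim, el, truth, n_trials = 8, fs = 400,
                                  seed = 23)
  ep <- epoch_recording(sim$listening, "stimulus_onset", c(-0.5, 4.2))
  hg <- analytic_signal(ep, canonical_bands()$highgamma)
  hg_mean <- apply(hg$amplitude[1, , ]^2, 2, mean)
  env <- approx(stim$t, stim$envelope, pmax(ep$time, 0), rule = 2)$y
  env[ep$time < 0] <- 0
  ls <- lagged_spearman(hg_mean, env, 400, max_lag_ms = 200, step_ms = 5)
  expect_lte(abs(ls$peak_lag_ms - 80), 10)
})

test_that("articulation epochs suppress transient but not sustained responses", {
  fix <- build_am_cohort(n_hgtts = 2, n_pt = 2, n_trials = 10, seed = 31,
                         articulation = TRUE)
  epa <- epoch_recording(fix$sim$articulation, "articulation_onset",
                         c(-0.5, 2))
  hg <- analytic_signal(epa, canonical_bands()$highgamma)
  pc <- percent_change_power(hg)
  resp <- apply(pc[, , epa$time > 0 & epa$time < 1, drop = FALSE], 1, mean)
  sustained <- fix$truth$archetype == "sustained"
  expect_gt(min(resp[sustained]), 50)
  expect_lt(max(abs(resp[!sustained])), 50)
})

test_that("detection behavior follows the planted psychometric design", {
  beh <- simulate_detection_behavior(n_subjects = 10, seed = 41)
  expect_equal(mean(beh$tone_present), 0.5)
  acc <- accuracy_by_condition(beh)
  expect_true(all(diff(acc$by_level$hit_rate) > 0))
  # a steep psychometric saturates: near-perfect at the top level,
  # near-floor at the lowest
  steep <- simulate_detection_behavior(n_subjects = 6, slope = 10,
                                       position2_bonus = 0, seed = 42)
  acc2 <- accuracy_by_condition(steep)
  expect_gt(acc2$by_level$hit_rate[3], 0.99)
  expect_lt(acc2$by_level$hit_rate[1], 0.01)
})

test_that("null cohorts stay quiet: no systematic ITC or power change", {
  hits_itc <- 0; hits_pow <- 0; n_runs <- 3
  for (r in seq_len(n_runs)) {
    el <- make_electrode_table(0, 0, 4, seed = 50 + r)
    truth <- make_ground_truth(el)
    stim <- make_am_noise_stimulus(stimulus_spec(sample_rate_hz = 8000,
                                                 seed = 60 + r))
    sim <- simulate_neural_response(stim, el, truth, n_trials = 15, fs = 400,
                                    seed = 70 + r)
    ep <- epoch_recording(sim$listening, "stimulus_onset", c(-0.5, 4.2))
    lf <- analytic_signal(ep, canonical_bands()$low)
    hg <- analytic_signal(ep, canonical_bands()$highgamma)
    it <- itc(lf$phase)
    stim_sel <- ep$time >= 0 & ep$time < 3
    base_sel <- ep$time >= -0.3 & ep$time < -0.05
    d_itc <- rowMeans(it[, stim_sel]) - rowMeans(it[, base_sel])
    pc <- percent_change_power(hg)
    d_pow <- apply(pc[, , stim_sel, drop = FALSE], 1, mean)
    if (stats::wilcox.test(d_itc, exact = FALSE)$p.value < 0.01)
      hits_itc <- hits_itc + 1
    if (stats::wilcox.test(d_pow, exact = FALSE)$p.value < 0.01)
      hits_pow <- hits_pow + 1
  }
  expect_lte(hits_itc, 1)
  expect_lte(hits_pow, 1)
})
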