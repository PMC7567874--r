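# Envelope extraction, edge detection, lagged correlation, event-locked
# phase statistics, articulation detection.

test_that("envelope extraction recovers gates and modulators", {
  fs <- 8000
  t <- (0:(2 * fs - 1)) / fs
  gate <- as.numeric(t >= 0.5 & t < 1.5)
  x <- gate * sin(2 * pi * 1000 * t)
  env <- extract_envelope(x, fs, cutoff_hz = 10)
  # 90% rise within 1.5 / cutoff seconds of the gate opening
  i90 <- env$t[which(env$t > 0.4 & env$amplitude > 0.9)[1]]
  expect_lt(i90 - 0.5, 1.5 / 10)
  expect_gt(mean(env$amplitude[env$t > 0.7 & env$t < 1.3]), 0.85)
  expect_lt(mean(env$amplitude[env$t < 0.3]), 0.1)
  # silence stays silent
  expect_true(all(extract_envelope(numeric(1000), fs)$amplitude == 0))
  # AM noise stimulus: extracted envelope tracks the generating modulator
  stim <- make_am_noise_stimulus(stimulus_spec(sample_rate_hz = fs, seed = 2))
  env2 <- extract_envelope(stim$waveform, fs, cutoff_hz = 10, target_fs = 400)
  mod <- approx(stim$t, stim$envelope, env2$t)$y
  keep <- env2$t > 0.2 & env2$t < 3.6
  expect_gt(cor(env2$amplitude[keep], mod[keep]), 0.95)
})

test_that("edge detection finds one edge per pulse and rejects decays", {
  stim <- make_am_noise_stimulus(stimulus_spec(sample_rate_hz = 8000, seed = 3))
  env <- as_envelope_trace(approx(stim$t, stim$envelope,
                                  seq(0, max(stim$t), by = 1 / 500))$y, 500)
  det <- detect_edges(env)
  expect_length(det$edge_times, 9)
  expect_lt(max(abs(det$edge_times - stim$edge_times)), 0.02)
  # monotone decay has no rising edge
  decay <- as_envelope_trace(exp(-seq(0, 5, by = 0.002)), 500)
  expect_length(detect_edges(decay)$edge_times, 0)
  # global amplitude scaling moves nothing by more than one sample
  det2 <- detect_edges(as_envelope_trace(env$amplitude * 7.3, 500))
  expect_length(det2$edge_times, 9)
  expect_lt(max(abs(det2$edge_times - det$edge_times)), 1 / 500 + 1e-9)
})

test_that("lagged Spearman recovers planted lags with the right sign", {
  fs <- 200
  set.seed(4)
  env <- abs(stats::filter(rnorm(6000), rep(1, 30), sides = 2))
  env[is.na(env)] <- 0
  lag_n <- round(0.045 * fs)
  neural <- c(rep(0, lag_n), env[1:(6000 - lag_n)]) + rnorm(6000, 0, 0.3)
  ls <- lagged_spearman(neural, env, fs, max_lag_ms = 300, step_ms = 5)
  expect_lte(abs(ls$peak_lag_ms - 45), 5)
  expect_gt(ls$peak_rho, 0.5)
  # invariance to monotone transforms of either series
  ls2 <- lagged_spearman(exp(neural), env^3, fs, max_lag_ms = 300, step_ms = 5)
  expect_equal(ls2$rho, ls$rho, tolerance = 1e-9)
  # anti-correlated series: negative rho at the planted lag
  ls3 <- lagged_spearman(-neural, env, fs, max_lag_ms = 300, step_ms = 5)
  expect_lte(abs(ls3$peak_lag_ms - 45), 5)
  expect_lt(ls3$peak_rho, -0.5)
  # independent series: permutation p is not significant
  ls4 <- lagged_spearman(rnorm(6000), env, fs, max_lag_ms = 100,
                         step_ms = 25, n_perm = 39, seed = 5)
  expect_gte(ls4$p, 0.05)
  expect_error(lagged_spearman(neural[1:50], env[1:50], fs), "shorter")
})

test_that("peak-lag estimation is unbiased across planted lags", {
  fs <- 200
  set.seed(6)
  env <- abs(stats::filter(rnorm(8000), rep(1, 40), sides = 2))
  env[is.na(env)] <- 0
  for (lag_ms in c(20, 100, 200)) {
    lag_n <- round(lag_ms / 1000 * fs)
    neural <- c(rep(0, lag_n), env[1:(8000 - lag_n)])
    ls <- lagged_spearman(neural, env, fs, max_lag_ms = 300, step_ms = 5)
    expect_lte(abs(ls$peak_lag_ms - lag_ms), 5)
  }
})

test_that("post-edge ITC dissociates edges from syllable onsets", {
  fs <- 400
  envs <- make_speech_like_envelope(n_sentences = 10, seed = 7)
  el <- make_electrode_table(8, 0, 0, ml_extent_mm = 0, seed = 8)
  truth <- make_ground_truth(el)
  rec <- simulate_speech_response(envs, el, truth, fs = fs, seed = 9)
  lf <- analytic_signal(
    as_epoch_set(array(rec$data, c(nrow(rec$data), 1, ncol(rec$data))), fs),
    canonical_bands()$low)
  ph <- lf$phase[, 1, ]
  edges <- rec$events$onset_s[rec$events$type == "edge"]
  sylls <- rec$events$onset_s[rec$events$type == "syllable"]
  res <- post_edge_itc(ph, edges, sylls, fs)
  expect_gte(mean(res$table$contrast > 0), 0.75)
  expect_lt(res$p, 0.05)
  # random events fall to the 1/sqrt(N) coherence floor
  set.seed(10)
  rand_ev <- sort(runif(40, 1, max(rec$events$onset_s) - 1))
  res2 <- post_edge_itc(ph[1, ], rand_ev, NULL, fs)
  expect_lt(res2$table$itc_edge[1], 3 * sqrt(pi) / 2 / sqrt(40))
  expect_error(post_edge_itc(ph, edges, sylls, fs, window_ms = 0), "positive")
  expect_error(post_edge_itc(ph, edges[1:5], NULL, fs), "20 edge")
})

test_that("discrete-event contrasts reproduce the double dissociation", {
  fs <- 400
  envs <- make_speech_like_envelope(n_sentences = 10, seed = 11)
  el <- make_electrode_table(8, 0, 0, ml_extent_mm = 0, seed = 12)
  truth <- make_ground_truth(el)
  rec <- simulate_speech_response(envs, el, truth, fs = fs, seed = 13)
  ep <- as_epoch_set(array(rec$data, c(nrow(rec$data), 1, ncol(rec$data))), fs)
  hg <- analytic_signal(ep, canonical_bands()$highgamma)
  lf <- analytic_signal(ep, canonical_bands()$low)
  env <- as_envelope_trace(attr(rec, "envelope"), fs)
  edges <- structure(list(edge_times =
    rec$events$onset_s[rec$events$type == "edge"]), class = "edge_annotation")
  hg_res <- discrete_event_contrasts(hg$amplitude[, 1, ]^2, hg$phase[, 1, ],
                                     env, edges, fs)
  lf_res <- discrete_event_contrasts(lf$amplitude[, 1, ]^2, lf$phase[, 1, ],
                                     env, edges, fs)
  # high-gamma power encodes envelope highs vs lows
  expect_gt(mean(hg_res$table$power_peak_valley), 0)
  expect_lt(hg_res$group$p[hg_res$group$contrast == "power_peak_valley"], 0.05)
  # low-frequency phase organization encodes the edge itself
  expect_gt(mean(lf_res$table$itc_edge), 0)
  expect_lt(lf_res$group$p[lf_res$group$contrast == "itc_edge"], 0.05)
  # white-noise neural data shows no systematic contrasts
  set.seed(14)
  wn <- array(rnorm(8 * ncol(rec$data)), c(8, 1, ncol(rec$data)))
  hgw <- analytic_signal(as_epoch_set(wn, fs), canonical_bands()$highgamma)
  null_res <- discrete_event_contrasts(hgw$amplitude[, 1, ]^2,
                                       hgw$phase[, 1, ], env, edges, fs)
  expect_gt(min(null_res$group$p), 0.01)
})

test_that("articulation onsets are found from the microphone envelope", {
  fs <- 2000
  t <- (0:(4 * fs - 1)) / fs
  quiet <- rnorm(length(t), 0, 0.01)
  burst <- quiet + ifelse(t >= 1.2 & t < 2.0, 1, 0) * sin(2 * pi * 300 * t)
  res <- detect_articulation_onset(burst, fs)
  expect_equal(nrow(res), 1)
  expect_lt(abs(res$onset_s - 1.2), 0.05)
  expect_lt(abs(res$offset_s - 2.0), 0.05)
  expect_equal(nrow(detect_articulation_onset(quiet, fs)), 0)
  two <- quiet + (ifelse(t >= 0.5 & t < 1, 1, 0) +
                  ifelse(t >= 2.5 & t < 3, 1, 0)) * sin(2 * pi * 300 * t)
  res2 <- detect_articulation_onset(two, fs)
  expect_equal(nrow(res2), 2)
  expect_true(all(diff(res2$onset_s) > 0))
})
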