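# Shared fixture builders. All synthetic, generated at test time.

# Small rhythmic-noise cohort run end to end through epoching.
build_am_cohort <- function(n_hgtts = 6, n_pt = 0, n_stg = 0, n_trials = 15,
                            fs = 400, ml_extent_mm = 0, seed = 1L,
                            snr = 3, articulation = FALSE) {
  spec <- stimulus_spec(sample_rate_hz = 8000, seed = seed)
  stim <- make_am_noise_stimulus(spec)
  el <- make_electrode_table(n_hgtts, n_pt, n_stg, ml_extent_mm = ml_extent_mm,
                             seed = seed + 1L)
  truth <- make_ground_truth(el, snr = snr)
  sim <- simulate_neural_response(stim, el, truth, n_trials = n_trials,
                                  fs = fs, seed = seed + 2L,
                                  articulation = articulation)
  ep <- epoch_recording(sim$listening, "stimulus_onset", c(-0.5, 4.2))
  list(spec = spec, stim = stim, electrodes = el, truth = truth, sim = sim,
       epochs = ep)
}

# Epoch-set wrapper around an electrodes x trials x time array.
as_epoch_set <- function(arr, fs, t0 = 0, baseline = NULL) {
  structure(list(data = arr, sample_rate_hz = fs,
                 time = t0 + (seq_len(dim(arr)[3]) - 1L) / fs,
                 baseline_window_s = baseline, alignment = "stimulus_onset"),
            class = "epoch_set")
}

# Continuous series wrapped as a 1 x 1 x n epoch set.
as_series_epochs <- function(x, fs) {
  as_epoch_set(array(x, c(1L, 1L, length(x))), fs)
}

# Rank-2 exact non-negative fixture.
exact_rank2 <- function(m = 30, n = 80, seed = 1L) {
  set.seed(seed)
  W0 <- matrix(stats::runif(m * 2, 0, 1), m)
  H0 <- matrix(stats::runif(2 * n, 0, 1), 2)
  list(A = W0 %*% H0, W = W0, H = H0)
}

# Adjusted Rand index between two labelings (contingency-table form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
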