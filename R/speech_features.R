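# Acoustic envelope and edge extraction, and their neural encoding:
# lagged rank correlation, post-edge phase organization, and discrete-event
# (edge and peak/valley) contrasts.

#' Extract the acoustic envelope of an audio waveform
#'
#' Modulus of the broadband analytic signal, low-pass filtered (10 Hz by
#' default) and optionally resampled onto the neural clock.
#'
#' @param waveform mono audio samples.
#' @param fs audio sample rate (Hz).
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param target_fs optional output sample rate (Hz).
#' @return An object of class `envelope_trace`: `t`, `amplitude` (>= 0),
#'   `fs`, `cutoff_hz`.
#' @export
extract_envelope <- function(waveform, fs, cutoff_hz = 10, target_fs = NULL) {
  stopifnot(is.numeric(waveform), all(is.finite(waveform)))
  n <- length(waveform)
  X <- stats::fft(waveform)
  gain <- numeric(n)
  gain[1] <- 1
  if (n %% 2 == 0) {
    gain[2:(n / 2)] <- 2
    gain[n / 2 + 1] <- 1
  } else {
    gain[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * gain, inverse = TRUE) / n)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  env <- pmax(signal::filtfilt(bf, env), 0)
  out_fs <- target_fs %||% fs
  t_in <- (seq_len(n) - 1L) / fs
  if (out_fs != fs) {
    t_out <- seq(0, t_in[n], by = 1 / out_fs)
    env <- stats::approx(t_in, env, t_out)$y
    t_in <- t_out
  }
  structure(list(t = t_in, amplitude = env, fs = out_fs,
                 cutoff_hz = cutoff_hz),
            class = "envelope_trace")
}

#' As an envelope trace
#'
#' Wraps an already-computed envelope (e.g. a generated modulator) in the
#' `envelope_trace` container.
#'
#' @param amplitude non-negative envelope samples.
#' @param fs sample rate (Hz).
#' @return An `envelope_trace`.
#' @export
as_envelope_trace <- function(amplitude, fs) {
  structure(list(t = (seq_along(amplitude) - 1L) / fs,
                 amplitude = pmax(amplitude, 0), fs = fs, cutoff_hz = NA_real_),
            class = "envelope_trace")
}

#' Detect acoustic edges in an envelope
#'
#' Acoustic edges are moments of rapid amplitude gain: local maxima of the
#' envelope derivative above a slope quantile, with a minimum separation
#' (keeping the larger slope when two candidates collide). Invariant to
#' global amplitude scaling.
#'
#' @param env an `envelope_trace` sampled at >= 100 Hz.
#' @param slope_quantile keep candidates above this quantile of the
#'   envelope-derivative distribution.
#' @param min_separation_ms minimum edge separation (ms).
#' @param smooth_ms Savitzky-Golay frame (ms) applied before
#'   differentiation; rapid gains survive, sample-to-sample noise does not.
#' @return An object of class `edge_annotation`: `edge_times`, `slopes`.
#' @export
detect_edges <- function(env, slope_quantile = 0.9, min_separation_ms = 120,
                         smooth_ms = 51) {
  stopifnot(inherits(env, "envelope_trace"))
  if (env$fs < 100) stop("envelope must be sampled at >= 100 Hz")
  x <- env$amplitude
  if (smooth_ms > 0 && length(x) > round(smooth_ms / 1000 * env$fs) + 2)
    x <- smooth_for_display(x, env$fs, order = 2, frame_ms = smooth_ms)
  d <- c(0, diff(x)) * env$fs
  cand <- local_maxima(d)
  cand <- cand[d[cand] > 0]
  if (length(cand)) {
    thr <- stats::quantile(d, slope_quantile, names = FALSE)
    cand <- cand[d[cand] >= thr & d[cand] > 0]
  }
  if (length(cand) > 1) {
    ord <- cand[order(d[cand], decreasing = TRUE)]
    kept <- numeric(0)
    min_sep <- min_separation_ms / 1000
    for (i in ord) {
      ti <- env$t[i]
      if (!length(kept) || all(abs(env$t[kept] - ti) >= min_sep))
        kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  structure(list(edge_times = env$t[cand], slopes = d[cand]),
            class = "edge_annotation")
}

#' Lagged Spearman correlation between band power and the acoustic envelope
#'
#' Rank correlation at each neural lag (positive lag = neural after audio),
#' on concatenated series with a mask around trial boundaries. Significance
#' of the peak is assessed by circularly permuting the envelope.
#'
#' @param neural numeric series (e.g. high-gamma amplitude), same clock as
#'   `env_amp`.
#' @param env_amp envelope series.
#' @param fs common sample rate (Hz).
#' @param max_lag_ms,step_ms lag grid (ms); the curve spans -max..+max.
#' @param boundaries_s optional trial-boundary times (s); samples within
#'   `mask_ms` of a boundary are excluded.
#' @param mask_ms boundary mask half-width (ms).
#' @param n_perm permutations for the peak significance (0 to skip).
#' @param seed integer seed.
#' @return List with `lag_ms`, `rho`, `peak_lag_ms`, `peak_rho`, `p`.
#' @export
lagged_spearman <- function(neural, env_amp, fs, max_lag_ms = 500, step_ms = 5,
                            boundaries_s = NULL, mask_ms = 250, n_perm = 0,
                            seed = 1L) {
  n <- length(neural)
  stopifnot(length(env_amp) == n)
  max_lag <- round(max_lag_ms / 1000 * fs)
  if (n <= 2 * max_lag) stop("series shorter than the maximum lag")
  keep <- rep(TRUE, n)
  if (!is.null(boundaries_s)) {
    m <- round(mask_ms / 1000 * fs)
    for (b in round(boundaries_s * fs)) {
      lo <- max(1L, b - m); hi <- min(n, b + m)
      keep[lo:hi] <- FALSE
    }
  }
  lags_ms <- seq(-max_lag_ms, max_lag_ms, by = step_ms)
  rn <- rank(neural)
  curve_for <- function(ea) {
    re <- rank(ea)
    vapply(lags_ms, function(L) {
      s <- round(L / 1000 * fs)
      if (s >= 0) {
        i_n <- (1L + s):n; i_e <- 1L:(n - s)
      } else {
        i_n <- 1L:(n + s); i_e <- (1L - s):n
      }
      ok <- keep[i_n] & keep[i_e]
      stats::cor(rn[i_n][ok], re[i_e][ok])
    }, 0)
  }
  rho <- curve_for(env_amp)
  peak <- which.max(abs(rho))
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    null_max <- vapply(seq_len(n_perm), function(b) {
      s <- sample.int(n - 1L, 1L)
      max(abs(curve_for(env_amp[c((s + 1L):n, 1L:s)])))
    }, 0)
    p <- (1 + sum(null_max >= abs(rho[peak]))) / (n_perm + 1)
  }
  list(lag_ms = lags_ms, rho = rho, peak_lag_ms = lags_ms[peak],
       peak_rho = rho[peak], p = p)
}

# Event-locked ITC: mean ITC across events over [0, window) after each event.
.event_itc <- function(phase_vec, event_times, fs, window_ms) {
  w <- round(window_ms / 1000 * fs)
  n <- length(phase_vec)
  starts <- round(event_times * fs) + 1L
  starts <- starts[starts >= 1L & (starts + w - 1L) <= n]
  if (length(starts) < 2) return(NA_real_)
  ph <- t(vapply(starts, function(s) phase_vec[s:(s + w - 1L)], numeric(w)))
  mean(itc(ph))
}

#' Post-edge phase organization and the edge-vs-syllable contrast
#'
#' Re-epochs low-frequency phase at acoustic edges and at syllable onsets and
#' measures the mean ITC over the window after each event type (125 ms by
#' default). The paired edge-minus-syllable contrast is tested across
#' electrodes with the Wilcoxon signed-rank test.
#'
#' @param phase electrodes x time continuous low-frequency phase matrix (a
#'   vector is treated as one electrode).
#' @param edge_times,syllable_times event times (s); at least 20 edges.
#' @param fs sample rate (Hz).
#' @param window_ms post-event window (ms); must be positive.
#' @return List with `table` (per electrode: `itc_edge`, `itc_syllable`,
#'   `contrast`) and `p` (one-sided group Wilcoxon, edge > syllable).
#' @export
post_edge_itc <- function(phase, edge_times, syllable_times = NULL, fs,
                          window_ms = 125) {
  if (window_ms <= 0) stop("window must be positive")
  if (is.vector(phase)) phase <- matrix(phase, nrow = 1)
  if (length(edge_times) < 20)
    stop("at least 20 edge events are required")
  n_el <- nrow(phase)
  itc_edge <- vapply(seq_len(n_el), function(e)
    .event_itc(phase[e, ], edge_times, fs, window_ms), 0)
  out <- data.frame(electrode = seq_len(n_el), itc_edge = itc_edge)
  p <- NA_real_
  if (!is.null(syllable_times)) {
    out$itc_syllable <- vapply(seq_len(n_el), function(e)
      .event_itc(phase[e, ], syllable_times, fs, window_ms), 0)
    out$contrast <- out$itc_edge - out$itc_syllable
    if (n_el >= 6)
      p <- stats::wilcox.test(out$itc_edge, out$itc_syllable, paired = TRUE,
                              alternative = "greater", exact = FALSE)$p.value
  }
  list(table = out, p = p)
}

#' Discrete-event contrasts of power and phase organization
#'
#' For one band: the power difference between 50 ms windows after and before
#' each acoustic edge, the power difference between 50 ms windows centered on
#' envelope peaks versus valleys, and the matching ITC (phase-organization)
#' contrasts. Each contrast is tested across electrodes with the Wilcoxon
#' signed-rank test.
#'
#' @param power electrodes x time band power (percent change or amplitude^2).
#' @param phase electrodes x time band phase.
#' @param env an `envelope_trace` on the same clock.
#' @param edges an `edge_annotation`.
#' @param fs sample rate (Hz).
#' @param window_ms contrast window (ms).
#' @return List with `table` (per electrode contrasts) and `group`
#'   (two-sided Wilcoxon p per contrast).
#' @export
discrete_event_contrasts <- function(power, phase, env, edges, fs,
                                     window_ms = 50) {
  if (is.vector(power)) power <- matrix(power, nrow = 1)
  if (is.vector(phase)) phase <- matrix(phase, nrow = 1)
  x <- env$amplitude
  pk <- local_maxima(x)
  vl <- local_maxima(-x)
  thr <- stats::median(x)
  pk <- pk[x[pk] > thr]
  vl <- vl[x[vl] < thr]
  if (length(pk) < 5 || length(vl) < 5)
    stop("fewer than 5 envelope peaks/valleys")
  w <- round(window_ms / 1000 * fs)
  n <- ncol(power)
  win_mean <- function(m, centers, from, to) {
    idx0 <- round(centers * fs)
    vals <- vapply(idx0, function(c0) {
      lo <- c0 + from; hi <- c0 + to
      if (lo < 1L || hi > n) return(rep(NA_real_, nrow(m)))
      rowMeans(m[, lo:hi, drop = FALSE])
    }, numeric(nrow(m)))
    rowMeans(matrix(vals, nrow = nrow(m)), na.rm = TRUE)
  }
  win_itc <- function(centers, from, to) {
    vapply(seq_len(nrow(phase)), function(e) {
      idx0 <- round(centers * fs)
      segs <- lapply(idx0, function(c0) {
        lo <- c0 + from; hi <- c0 + to
        if (lo < 1L || hi > n) return(NULL)
        phase[e, lo:hi]
      })
      segs <- do.call(rbind, segs[!vapply(segs, is.null, TRUE)])
      if (is.null(segs) || nrow(segs) < 2) return(NA_real_)
      mean(itc(segs))
    }, 0)
  }
  et <- edges$edge_times
  pk_t <- env$t[pk]; vl_t <- env$t[vl]
  tab <- data.frame(
    electrode = seq_len(nrow(power)),
    power_edge = win_mean(power, et, 1L, w) - win_mean(power, et, -w, -1L),
    power_peak_valley = win_mean(power, pk_t, -w %/% 2, w %/% 2) -
      win_mean(power, vl_t, -w %/% 2, w %/% 2),
    itc_edge = win_itc(et, 1L, w) - win_itc(et, -w, -1L),
    itc_peak_valley = win_itc(pk_t, -w %/% 2, w %/% 2) -
      win_itc(vl_t, -w %/% 2, w %/% 2))
  test <- function(v) if (sum(is.finite(v)) >= 6)
    stats::wilcox.test(v, exact = FALSE)$p.value else NA_real_
  group <- data.frame(contrast = c("power_edge", "power_peak_valley",
                                   "itc_edge", "itc_peak_valley"),
                      p = c(test(tab$power_edge), test(tab$power_peak_valley),
                            test(tab$itc_edge), test(tab$itc_peak_valley)))
  list(table = tab, group = group)
}

#' Detect articulation onsets and offsets from a microphone channel
#'
#' Onset is the first time the smoothed envelope exceeds `k` times the
#' baseline RMS (the median envelope, silence-dominated recordings) for at
#' least `min_dur_s`; offsets are symmetric.
#'
#' @param audio microphone samples aligned to the neural clock.
#' @param fs sample rate (Hz).
#' @param k threshold multiplier.
#' @param min_dur_s minimum supra-threshold duration (s).
#' @return data.frame with `onset_s`, `offset_s` (zero rows when nothing
#'   exceeds threshold).
#' @export
detect_articulation_onset <- function(audio, fs, k = 3, min_dur_s = 0.05) {
  env <- extract_envelope(audio, fs, cutoff_hz = 20)$amplitude
  baseline <- stats::median(env)
  thr <- k * baseline + 1e-12
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= round(min_dur_s * fs)
  data.frame(onset_s = (starts[keep] - 1L) / fs, offset_s = ends[keep] / fs)
}
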