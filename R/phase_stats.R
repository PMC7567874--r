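# Phase-alignment statistics: inter-trial coherence and its baseline change,
# jittered-bootstrap nulls, phase-resolved amplitude (KL from uniform),
# prediction-interval engagement, and delayed-embedding trajectories.

#' Inter-trial coherence
#'
#' The modulus of the complex mean of unit phasors across trials,
#' `L = |1/N sum exp(i theta_n)|`, computed per time point: 1 for perfectly
#' aligned phases, approaching `sqrt(pi)/2 / sqrt(N)` in expectation for
#' uniform random phases.
#'
#' @param phase trials x time matrix, or electrodes x trials x time array,
#'   of phases in radians.
#' @return A numeric vector (per time point) or electrodes x time matrix.
#' @export
itc <- function(phase) {
  if (anyNA(phase) || any(!is.finite(phase)))
    stop("phases must be finite")
  if (is.matrix(phase)) {
    if (nrow(phase) < 2) stop("ITC requires at least two trials")
    return(Mod(colMeans(exp(1i * phase))))
  }
  if (length(dim(phase)) == 3) {
    if (dim(phase)[2] < 2) stop("ITC requires at least two trials")
    z <- exp(1i * phase)
    return(Mod(apply(z, c(1, 3), mean)))
  }
  stop("`phase` must be a trials x time matrix or a 3-d array")
}

#' Change in ITC from a pre-stimulus baseline
#'
#' @param itc_series numeric vector (per time) or electrodes x time matrix.
#' @param time time axis (s), aligned to the series.
#' @param baseline_window_s length-2 window (s).
#' @return Series minus its mean over the baseline window (per electrode).
#' @export
itc_change <- function(itc_series, time, baseline_window_s = c(-0.3, -0.05)) {
  sel <- time >= baseline_window_s[1] & time < baseline_window_s[2]
  if (!any(sel)) stop("baseline window lies outside the series")
  if (is.matrix(itc_series))
    return(itc_series - rowMeans(itc_series[, sel, drop = FALSE]))
  itc_series - mean(itc_series[sel])
}

# Circularly shift each row of a matrix by per-row offsets.
.row_circshift <- function(m, shifts) {
  n <- ncol(m)
  out <- m
  for (i in seq_len(nrow(m))) {
    s <- shifts[i] %% n
    if (s > 0) out[i, ] <- m[i, c((n - s + 1L):n, 1L:(n - s))]
  }
  out
}

#' Jittered-bootstrap null for phase statistics
#'
#' Builds a null distribution by circularly shifting every trial's phase
#' series by an independent uniform temporal jitter and recomputing the
#' statistic; the one-sided p-value is the fraction of null replicates at or
#' above the observed value, with the +1 correction.
#'
#' @param phase trials x time phase matrix.
#' @param statistic function of a phase matrix returning a scalar; the
#'   default is the mean ITC over time.
#' @param n_boot replicates (a warning is issued below 100).
#' @param jitter_range_s optional jitter range (s) with `fs`; defaults to the
#'   full series length.
#' @param fs sampling rate, required when `jitter_range_s` is given.
#' @param seed integer seed.
#' @return List with `observed`, `null` (length `n_boot`), and `p`.
#' @export
jitter_bootstrap_null <- function(phase, statistic = function(ph) mean(itc(ph)),
                                  n_boot = 1000, jitter_range_s = NULL,
                                  fs = NULL, seed = 1L) {
  stopifnot(is.matrix(phase))
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  set.seed(as.integer(seed))
  n <- ncol(phase)
  max_shift <- if (!is.null(jitter_range_s)) {
    if (is.null(fs)) stop("`fs` is required with `jitter_range_s`")
    max(2L, round(jitter_range_s * fs))
  } else n
  observed <- statistic(phase)
  null <- vapply(seq_len(n_boot), function(b) {
    shifts <- sample.int(max_shift, nrow(phase), replace = TRUE)
    statistic(.row_circshift(phase, shifts))
  }, 0)
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (n_boot + 1))
}

#' Phase-resolved amplitude profile
#'
#' Bins band amplitude by concurrent stimulus phase, normalizes the bin means
#' to a probability-like profile, and quantifies its non-uniformity as the
#' Kullback-Leibler divergence from uniform, with a temporally jittered
#' bootstrap p-value.
#'
#' @param amplitude trials x time amplitude matrix (or vector).
#' @param stimulus_phase matching stimulus-phase matrix/vector (radians).
#' @param n_bins phase bins (default 18 bins of 20 degrees); reduced with a
#'   warning if any bin is empty.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return List of class `phase_amplitude_profile`: `bin_centers`,
#'   `bin_means`, `profile` (normalized), `kl`, `p`.
#' @export
phase_resolved_amplitude <- function(amplitude, stimulus_phase, n_bins = 18,
                                     n_boot = 1000, seed = 1L) {
  if (is.vector(amplitude)) amplitude <- matrix(amplitude, nrow = 1)
  if (is.vector(stimulus_phase)) stimulus_phase <- matrix(stimulus_phase, nrow = 1)
  stopifnot(all(dim(amplitude) == dim(stimulus_phase)), all(amplitude >= 0))
  kl_of <- function(amp) {
    repeat {
      bins <- findInterval(as.vector(stimulus_phase),
                           seq(-pi, pi, length.out = n_bins + 1L),
                           rightmost.closed = TRUE)
      fb <- factor(bins, levels = seq_len(n_bins))
      if (all(table(fb) > 0)) break
      n_bins <<- n_bins - 1L
      warning("empty phase bin: reducing bin count to ", n_bins)
      if (n_bins < 4) stop("too few occupied phase bins")
    }
    m <- tapply(as.vector(amp), fb, mean)
    if (sum(m) <= 0) return(list(kl = 0, profile = rep(1 / n_bins, n_bins), means = m))
    p <- m / sum(m)
    nz <- p > 0
    list(kl = sum(p[nz] * log(p[nz] * n_bins)), profile = p, means = m)
  }
  obs <- kl_of(amplitude)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_boot), function(b) {
    shifts <- sample.int(ncol(amplitude), nrow(amplitude), replace = TRUE)
    kl_of(.row_circshift(amplitude, shifts))$kl
  }, 0)
  centers <- seq(-pi, pi, length.out = n_bins + 1L)
  centers <- (centers[-1] + centers[-length(centers)]) / 2
  structure(list(bin_centers = centers,
                 bin_means = as.numeric(obs$means),
                 profile = as.numeric(obs$profile), kl = obs$kl,
                 p = (1 + sum(null >= obs$kl)) / (n_boot + 1), null = null),
            class = "phase_amplitude_profile")
}

#' Analysis intervals for the rhythmic-noise paradigm
#'
#' Baseline, onset (first pulse), sustained (pulses 2 to the last), and two
#' consecutive prediction intervals of one modulation cycle each after the
#' rhythm ends.
#'
#' @param mod_freq_hz modulation frequency (Hz).
#' @param rhythmic_dur_s rhythmic-segment duration (s).
#' @param baseline_window_s baseline window (s).
#' @return data.frame with columns `interval`, `start`, `end` (s).
#' @export
interval_definitions <- function(mod_freq_hz = 3, rhythmic_dur_s = 3,
                                 baseline_window_s = c(-0.3, -0.05)) {
  period <- 1 / mod_freq_hz
  data.frame(interval = c("baseline", "onset", "sustained",
                          "early_prediction", "late_prediction"),
             start = c(baseline_window_s[1], 0, period, rhythmic_dur_s,
                       rhythmic_dur_s + period),
             end = c(baseline_window_s[2], period, rhythmic_dur_s,
                     rhythmic_dur_s + period, rhythmic_dur_s + 2 * period),
             stringsAsFactors = FALSE)
}

#' Interval engagement of low-frequency phase and high-gamma power
#'
#' Per electrode and interval, the low-frequency measure is mean ITC
#' (averaged over filter-bank bands when a bank is supplied); the high-gamma
#' measure is a signed r-squared, `sign(rho) * rho^2`, from the Spearman
#' correlation between the trial-mean high-gamma power series and a
#' modulation-frequency cosine phase-locked to the (extrapolated) stimulus
#' envelope. Group engagement per interval is tested against baseline with
#' the Wilcoxon signed-rank test across electrodes.
#'
#' @param lf_phase electrodes x trials x time phase array, or a
#'   `filter_bank` (phase averaged across bands after per-band ITC).
#' @param hg_amplitude electrodes x trials x time high-gamma amplitude array.
#' @param time epoch time axis (s).
#' @param intervals from [interval_definitions()].
#' @param mod_freq_hz modulation frequency (Hz).
#' @return A list with `table` (electrode x interval x measure), and
#'   `group` (interval x measure Wilcoxon p-values against baseline).
#' @export
interval_engagement <- function(lf_phase, hg_amplitude, time, intervals,
                                mod_freq_hz = 3) {
  if (inherits(lf_phase, "filter_bank")) {
    nb <- dim(lf_phase$phase)[1]
    itc_el <- 0
    for (b in seq_len(nb)) itc_el <- itc_el + itc(lf_phase$phase[b, , , ])
    itc_el <- itc_el / nb
  } else {
    itc_el <- itc(lf_phase)
  }
  if (min(intervals$start) < min(time) || max(intervals$end) > max(time) + 1e-9)
    stop("an interval lies outside the epoch")
  n_el <- dim(hg_amplitude)[1]
  hg_mean <- apply(hg_amplitude^2, c(1, 3), mean)
  ref <- cos(2 * pi * mod_freq_hz * time)
  rows <- list()
  for (k in seq_len(nrow(intervals))) {
    sel <- time >= intervals$start[k] & time < intervals$end[k]
    itc_meas <- rowMeans(itc_el[, sel, drop = FALSE])
    r2 <- vapply(seq_len(n_el), function(e) {
      rho <- suppressWarnings(stats::cor(hg_mean[e, sel], ref[sel],
                                         method = "spearman"))
      if (is.na(rho)) 0 else sign(rho) * rho^2
    }, 0)
    rows[[k]] <- data.frame(electrode = seq_len(n_el),
                            interval = intervals$interval[k],
                            itc = itc_meas, hg_signed_r2 = r2,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  base <- tab[tab$interval == "baseline", ]
  grp <- lapply(setdiff(intervals$interval, "baseline"), function(iv) {
    cur <- tab[tab$interval == iv, ]
    p_itc <- stats::wilcox.test(cur$itc, base$itc, paired = TRUE,
                                alternative = "greater", exact = FALSE)$p.value
    p_hg <- stats::wilcox.test(cur$hg_signed_r2, base$hg_signed_r2,
                               paired = TRUE, alternative = "greater",
                               exact = FALSE)$p.value
    data.frame(interval = iv, p_itc = p_itc, p_hg = p_hg,
               stringsAsFactors = FALSE)
  })
  list(table = tab, group = do.call(rbind, grp))
}

#' Quarter-period embedding delay
#'
#' The delay used for phase-space trajectories: one quarter of the modulation
#' period, in integer milliseconds (83 ms at 3 Hz).
#'
#' @param mod_freq_hz modulation frequency (Hz).
#' @return Delay in ms.
#' @export
quarter_period_delay <- function(mod_freq_hz) {
  assert_scalar_pos(mod_freq_hz, "mod_freq_hz")
  round(1000 / (4 * mod_freq_hz))
}

#' Delayed-embedding phase-space trajectory
#'
#' Plots a group series against itself at a fixed delay (a quarter period by
#' convention); stable oscillatory states appear as limit cycles. Samples are
#' labeled by analysis interval when interval definitions are supplied.
#'
#' @param series numeric series (e.g. group-mean high-gamma power or ITC).
#' @param delay_ms embedding delay (ms).
#' @param fs sampling rate of `series` (Hz).
#' @param time optional time axis for interval labeling.
#' @param intervals optional [interval_definitions()] output.
#' @return data.frame with `x` (current), `y` (delayed), `t`, and `state`.
#' @export
phase_space_trajectory <- function(series, delay_ms, fs, time = NULL,
                                   intervals = NULL) {
  d <- round(delay_ms / 1000 * fs)
  n <- length(series)
  if (d >= n) stop("delay must be shorter than the series")
  idx <- (d + 1L):n
  out <- data.frame(x = series[idx], y = series[idx - d],
                    t = if (!is.null(time)) time[idx] else idx / fs)
  out$state <- "unlabeled"
  if (!is.null(intervals) && !is.null(time)) {
    for (k in seq_len(nrow(intervals)))
      out$state[out$t >= intervals$start[k] & out$t < intervals$end[k]] <-
        intervals$interval[k]
  }
  out
}

#' Screen electrodes for a predictive signature
#'
#' Selects the electrodes with both a significant sustained response during
#' the rhythmic stimulus and a significant low-frequency phase reset in the
#' first prediction interval, each at the per-electrode bootstrap level
#' `alpha`.
#'
#' @param p_sustained,p_early per-electrode one-sided bootstrap p-values.
#' @param alpha significance level.
#' @return Integer indices of electrodes passing both criteria.
#' @export
predictive_electrode_screen <- function(p_sustained, p_early, alpha = 0.05) {
  stopifnot(length(p_sustained) == length(p_early))
  which(p_sustained < alpha & p_early < alpha)
}
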