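# Analytic-signal decomposition with frequency-domain bandpass Hilbert
# filters. The filter gain is the product of a rising and a falling logistic
# flank centered on the band edges: gain = 0.5 exactly at each nominal edge,
# and a half-width of 1 Hz means the flank rises from 0.12 to 0.88 over 2 Hz.

#' Define a frequency band
#'
#' @param f_lo,f_hi nominal band edges (Hz); the filter gain is 0.5 at each.
#' @param flank_hz logistic flank half-width (Hz).
#' @param name optional band label.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(f_lo, f_hi, flank_hz = 1, name = NULL) {
  stopifnot(f_lo > 0, f_hi > f_lo, flank_hz > 0)
  structure(list(f_lo = f_lo, f_hi = f_hi, flank_hz = flank_hz,
                 name = name %||% sprintf("%g-%g Hz", f_lo, f_hi)),
            class = "band_spec")
}

#' Canonical analysis bands
#'
#' Low frequency 2-15 Hz (the ITC band), theta 4-8 Hz, beta 15-30 Hz, and
#' high gamma 65-115 Hz.
#'
#' @return Named list of [band_spec()] objects.
#' @export
canonical_bands <- function() {
  list(low = band_spec(2, 15, name = "low"),
       theta = band_spec(4, 8, name = "theta"),
       beta = band_spec(15, 30, name = "beta"),
       highgamma = band_spec(65, 115, name = "highgamma"))
}

# Logistic steepness giving a 0.12 -> 0.88 transition over 2 * flank_hz.
.flank_k <- function(flank_hz) log(0.88 / 0.12) / flank_hz

#' Design a one-sided frequency-domain Hilbert bandpass filter
#'
#' Returns the complex-FFT gain vector of length `n_samples`: zero on
#' negative frequencies, twice the bandpass gain on positive frequencies
#' (unity at DC/Nyquist bins, where the gain is in any case negligible).
#' Multiplying an FFT by this vector and inverse-transforming yields the
#' band-limited analytic signal.
#'
#' @param n_samples FFT length.
#' @param sample_rate sampling rate (Hz).
#' @param band a [band_spec()].
#' @return Numeric gain vector of length `n_samples`.
#' @export
design_filter <- function(n_samples, sample_rate, band) {
  stopifnot(inherits(band, "band_spec"))
  if (band$f_hi >= sample_rate / 2)
    stop("band upper edge must lie below the Nyquist frequency")
  f <- seq(0, sample_rate, length.out = n_samples + 1L)[1:n_samples]
  pos <- f > 0 & f < sample_rate / 2
  k <- .flank_k(band$flank_hz)
  g <- stats::plogis(k * (f - band$f_lo)) * stats::plogis(k * (band$f_hi - f))
  gain <- numeric(n_samples)
  gain[pos] <- 2 * g[pos]
  gain[1] <- g[1]
  if (n_samples %% 2 == 0) gain[n_samples / 2 + 1] <- g[n_samples / 2 + 1]
  gain
}

# Core: analytic signal of the columns of a matrix (time down columns),
# with reflection padding against epoch-edge artifacts.
.analytic_cols <- function(xmat, fs, band, pad_s = 0.5) {
  n <- nrow(xmat)
  n_pad <- min(n - 1L, round(pad_s * fs))
  np <- n + 2L * n_pad
  gain <- design_filter(np, fs, band)
  xp <- apply(xmat, 2, reflect_pad, n_pad = n_pad)
  A <- stats::mvfft(stats::mvfft(xp) * gain, inverse = TRUE) / np
  A[(n_pad + 1L):(n_pad + n), , drop = FALSE]
}

#' Band-limited analytic signal of an epoch set
#'
#' Filters every electrode x trial series with the frequency-domain Hilbert
#' filter for `band` and extracts instantaneous amplitude (modulus) and phase
#' (argument). Epochs are reflection-padded before the FFT and trimmed after.
#'
#' @param epochs an `epoch_set` (or a trials x time matrix).
#' @param band a [band_spec()].
#' @param pad_s reflection padding (s).
#' @return An object of class `band_decomposition`: `amplitude` and `phase`
#'   arrays shaped like the input data, plus `band`, `time`,
#'   `sample_rate_hz`. A warning marks the result `unreliable` when the epoch
#'   holds fewer than two cycles of the band's center frequency.
#' @export
analytic_signal <- function(epochs, band, pad_s = 0.5) {
  if (is.matrix(epochs)) {
    fs_guess <- attr(epochs, "sample_rate_hz")
    if (is.null(fs_guess)) stop("matrix input needs a `sample_rate_hz` attribute")
    arr <- array(epochs, dim = c(1L, nrow(epochs), ncol(epochs)))
    epochs <- list(data = arr, sample_rate_hz = fs_guess,
                   time = (seq_len(ncol(epochs)) - 1L) / fs_guess,
                   baseline_window_s = NULL)
  }
  stopifnot(!is.null(epochs$data))
  d <- dim(epochs$data)
  fs <- epochs$sample_rate_hz
  fc <- (band$f_lo + band$f_hi) / 2
  unreliable <- FALSE
  if (d[3] / fs < 2 / fc) {
    warning("epoch shorter than two cycles of the band center; result unreliable")
    unreliable <- TRUE
  }
  xmat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  A <- .analytic_cols(xmat, fs, band, pad_s)
  amp <- aperm(array(Mod(A), dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  ph <- aperm(array(Arg(A), dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  structure(list(amplitude = amp, phase = ph, band = band,
                 time = epochs$time, sample_rate_hz = fs,
                 baseline_window_s = epochs$baseline_window_s,
                 unreliable = unreliable),
            class = "band_decomposition")
}

#' Logarithmic Hilbert filter bank
#'
#' Decomposes an epoch set with `n_bands` filters whose center frequencies
#' are log-spaced from `f_range[1]` to `f_range[2]` and whose passband widths
#' are log-spaced from `w_range[1]` to `w_range[2]`, paired index-wise (the
#' narrowest band at the lowest center). The canonical bank is 50 bands,
#' 2-16 Hz centers, 1-4 Hz widths.
#'
#' @param epochs an `epoch_set`.
#' @param n_bands number of bands.
#' @param f_range center-frequency range (Hz).
#' @param w_range passband-width range (Hz).
#' @param what which components to keep ("phase", "amplitude", or "both");
#'   phase alone halves the memory.
#' @param pad_s reflection padding (s).
#' @return A list of class `filter_bank`: `centers`, `widths`, and 4-d arrays
#'   `phase` / `amplitude` shaped band x electrode x trial x time.
#' @export
filter_bank <- function(epochs, n_bands = 50, f_range = c(2, 16),
                        w_range = c(1, 4), what = c("both", "phase", "amplitude"),
                        pad_s = 0.5) {
  what <- match.arg(what)
  centers <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_bands))
  widths <- exp(seq(log(w_range[1]), log(w_range[2]), length.out = n_bands))
  d <- dim(epochs$data)
  keep_amp <- what %in% c("both", "amplitude")
  keep_ph <- what %in% c("both", "phase")
  amp <- if (keep_amp) array(NA_real_, c(n_bands, d)) else NULL
  ph <- if (keep_ph) array(NA_real_, c(n_bands, d)) else NULL
  for (b in seq_len(n_bands)) {
    bd <- band_spec(max(centers[b] - widths[b] / 2, 0.5), centers[b] + widths[b] / 2,
                    name = sprintf("bank%02d", b))
    dec <- analytic_signal(epochs, bd, pad_s)
    if (keep_amp) amp[b, , , ] <- dec$amplitude
    if (keep_ph) ph[b, , , ] <- dec$phase
  }
  structure(list(centers = centers, widths = widths, amplitude = amp,
                 phase = ph, time = epochs$time,
                 sample_rate_hz = epochs$sample_rate_hz,
                 baseline_window_s = epochs$baseline_window_s),
            class = "filter_bank")
}

#' Percent change in band power from baseline
#'
#' Squares instantaneous amplitude and normalizes per electrode and trial to
#' the mean power in the baseline window: `100 * (power - base) / base`.
#'
#' @param decomp a `band_decomposition`.
#' @param baseline_window_s length-2 window (s); defaults to the epoch
#'   baseline.
#' @return Array of percent-change values, same shape as the amplitude.
#' @export
percent_change_power <- function(decomp, baseline_window_s = NULL) {
  stopifnot(inherits(decomp, "band_decomposition"))
  bw <- baseline_window_s %||% decomp$baseline_window_s
  if (is.null(bw)) stop("no baseline window available")
  sel <- decomp$time >= bw[1] & decomp$time < bw[2]
  if (!any(sel)) stop("baseline window lies outside the epoch")
  p <- decomp$amplitude^2
  base <- apply(p[, , sel, drop = FALSE], c(1, 2), mean)
  if (any(base == 0)) stop("zero baseline power: degenerate input")
  100 * (p - c(base)) / c(base)
}

#' Savitzky-Golay smoothing for display
#'
#' Third-order, 83 ms frame by default; polynomial-preserving, so inputs that
#' are polynomials of degree <= `order` pass through unchanged.
#'
#' @param x numeric series.
#' @param fs sampling rate of `x` (Hz).
#' @param order polynomial order.
#' @param frame_ms frame length (ms); rounded up to an odd sample count.
#' @return Smoothed series.
#' @export
smooth_for_display <- function(x, fs, order = 3, frame_ms = 83) {
  n_frame <- round(frame_ms / 1000 * fs)
  if (n_frame %% 2 == 0) n_frame <- n_frame + 1L
  if (n_frame <= order)
    stop("frame length must exceed the polynomial order")
  signal::sgolayfilt(x, p = order, n = n_frame)
}
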