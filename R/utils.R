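# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(msg) {
  stop(structure(class = c("ecogpred_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
}

# Uniform-ish integer hash of a string, for deriving stage seeds.
.string_hash <- function(s) {
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s)) * 131L) %% 1000003L
}

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed from a single master
#' seed through this deterministic map, so stages can be re-run independently
#' while the end-to-end run stays reproducible.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. "simulate", "nnmf").
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((abs(master) + .string_hash(stage)) %% 2147483587)
}

# Reflection padding of a numeric vector (no repeated end sample).
reflect_pad <- function(x, n_pad) {
  n <- length(x)
  n_pad <- min(n_pad, n - 1L)
  if (n_pad <= 0L) return(x)
  c(rev(x[2L:(n_pad + 1L)]), x, rev(x[(n - n_pad):(n - 1L)]))
}

# Indices of strict local maxima of a vector.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# 1/f^alpha Gaussian noise via spectral shaping, unit RMS.
one_over_f_noise <- function(n, fs, alpha = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1L)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- ifelse(f < fs / n, 0, f^(-alpha / 2))
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Band-limited Gaussian noise carrier with approximately unit RMS.
bandpass_noise <- function(n, fs, f_lo, f_hi, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1L)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- as.numeric(f >= f_lo & f <= f_hi)
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# Match detected event times against planted ones within a tolerance.
# Each truth event can absorb at most one detection (greedy nearest match).

#' Precision and recall of detected event times
#'
#' Greedy one-to-one matching of detected against ground-truth event times
#' within a tolerance; used to score edge detectors against planted edges.
#'
#' @param detected,truth numeric vectors of event times (s).
#' @param tol_s matching tolerance in seconds.
#' @return A list with `precision`, `recall`, `n_matched`.
#' @export
event_match_stats <- function(detected, truth, tol_s = 0.05) {
  used <- rep(FALSE, length(truth))
  n_match <- 0L
  for (d in sort(detected)) {
    j <- which(!used & abs(truth - d) <= tol_s)
    if (length(j)) {
      used[j[which.min(abs(truth[j] - d))]] <- TRUE
      n_match <- n_match + 1L
    }
  }
  list(precision = if (length(detected)) n_match / length(detected) else NA_real_,
       recall = if (length(truth)) n_match / length(truth) else NA_real_,
       n_matched = n_match)
}
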