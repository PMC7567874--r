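# Rank-2 non-negative matrix factorization of supratemporal response
# features into sustained and transient classes, archetype transfer to
# articulation epochs, anatomical-gradient statistics, and traveling-wave
# velocity estimation.

#' Rectify a baseline-referenced feature matrix
#'
#' Half-wave rectification: values below the baseline level are set to zero,
#' yielding the non-negative input the factorization requires. Percent-change
#' power and baseline-referenced ITC change use `baseline = 0`.
#'
#' @param x numeric matrix (electrodes x time).
#' @param baseline baseline level.
#' @return The rectified matrix (entries >= `baseline` kept, shifted scale
#'   preserved; sub-baseline entries set to 0).
#' @export
rectify <- function(x, baseline = 0) {
  x[x < baseline] <- 0
  x
}

#' Fit a non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius objective `||A - W H||_F^2` over non-negative
#' `W` (m x k class weights) and `H` (k x n class archetypes) with
#' Lee-Seung multiplicative updates from random non-negative starts. The
#' best of `n_replicates` restarts (smallest residual) is returned; the
#' objective is non-increasing within every replicate. Replicate seeds are
#' derived from `seed` by a counter.
#'
#' @param A non-negative feature matrix, m electrodes x n time points.
#' @param k factorization rank (2 throughout this line of analysis).
#' @param n_replicates random restarts.
#' @param max_iter,tol iteration cap and relative-improvement stop.
#' @param seed master seed.
#' @return An object of class `nnmf`: `W`, `H`, `residual` (Frobenius norm of
#'   the best fit), `objective` (trace for the best replicate), `k`,
#'   `n_replicates`, `converged`, `seed`.
#' @export
nnmf_fit <- function(A, k = 2, n_replicates = 1000, max_iter = 200,
                     tol = 1e-6, seed = 1L) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("A must be non-negative")
  if (all(A == 0)) stop("A is identically zero")
  if (nrow(A) < k) stop("need at least k rows")
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, paste0("nnmf", r)))
    W <- matrix(stats::runif(nrow(A) * k, 0.1, 1), ncol = k) * sqrt(mean(A))
    H <- matrix(stats::runif(k * ncol(A), 0.1, 1), nrow = k) * sqrt(mean(A))
    obj <- numeric(0)
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      H <- H * (t(W) %*% A) / (t(W) %*% W %*% H + eps)
      W <- W * (A %*% t(H)) / (W %*% H %*% t(H) + eps)
      o <- sum((A - W %*% H)^2)
      obj <- c(obj, o)
      if (is.finite(prev) && (prev - o) <= tol * max(prev, eps)) {
        converged <- TRUE
        break
      }
      prev <- o
    }
    if (is.null(best) || obj[length(obj)] < best$objective[length(best$objective)])
      best <- list(W = W, H = H, objective = obj, converged = converged,
                   replicate = r)
  }
  structure(list(W = best$W, H = best$H,
                 residual = sqrt(best$objective[length(best$objective)]),
                 objective = best$objective, k = k,
                 n_replicates = n_replicates, converged = best$converged,
                 seed = seed),
            class = "nnmf")
}

#' @export
print.nnmf <- function(x, ...) {
  cat(sprintf("<nnmf> rank %d, %d x %d, residual %.4g (%d replicates%s)\n",
              x$k, nrow(x$W), ncol(x$H), x$residual, x$n_replicates,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' @export
coef.nnmf <- function(object, ...) object$W

#' @export
fitted.nnmf <- function(object, ...) object$W %*% object$H

#' Normalize archetypes to unit maximum
#'
#' Removes the scale degeneracy of the factorization: each row of `H` is
#' scaled to peak 1 and the compensating scale is folded into the matching
#' column of `W`, so class weights live on the feature's own scale and the
#' class-bias threshold is meaningful.
#'
#' @param model an `nnmf` fit.
#' @return The model with normalized `H` and rescaled `W`.
#' @export
normalize_archetypes <- function(model) {
  stopifnot(inherits(model, "nnmf"))
  s <- apply(model$H, 1, max)
  s[s == 0] <- 1
  model$H <- model$H / s
  model$W <- sweep(model$W, 2, s, `*`)
  model
}

#' Order classes as (sustained, transient)
#'
#' Class identity is assigned by correlating each archetype with a canonical
#' sustained template: a comb at the modulation frequency over the rhythmic
#' segment. The better-matching archetype becomes class 1 (sustained).
#'
#' @param model an `nnmf` fit (rank 2).
#' @param time archetype time axis (s).
#' @param mod_freq_hz,rhythmic_dur_s stimulus rhythm.
#' @return The model with columns/rows reordered so class 1 is sustained,
#'   and a `class_names` field.
#' @export
assign_class_identity <- function(model, time, mod_freq_hz = 3,
                                  rhythmic_dur_s = 3) {
  stopifnot(inherits(model, "nnmf"), model$k == 2)
  templ <- numeric(length(time))
  on <- time >= 0 & time < rhythmic_dur_s
  templ[on] <- (1 + cos(2 * pi * mod_freq_hz * time[on])) / 2 + 0.5
  r <- apply(model$H, 1, function(h) suppressWarnings(stats::cor(h, templ)))
  r[is.na(r)] <- -Inf
  ord <- order(r, decreasing = TRUE)
  model$H <- model$H[ord, , drop = FALSE]
  model$W <- model$W[, ord, drop = FALSE]
  model$class_names <- c("sustained", "transient")
  model
}

#' Class bias and response magnitude
#'
#' Bias is the difference of the two class weights per electrode (positive =
#' sustained under the standard ordering); magnitude is their sum. Apply
#' after [normalize_archetypes()] and [assign_class_identity()].
#'
#' @param model a rank-2 `nnmf`.
#' @return data.frame with `bias` and `magnitude` per electrode.
#' @export
class_bias <- function(model) {
  stopifnot(inherits(model, "nnmf"), model$k == 2)
  data.frame(bias = model$W[, 1] - model$W[, 2],
             magnitude = model$W[, 1] + model$W[, 2])
}

#' Classify electrodes from one or two class biases
#'
#' Applies a binary threshold to the class bias: electrodes with
#' `|bias| > threshold` are sustained or transient by sign. When a second
#' measure's bias is supplied (power and ITC factorized separately),
#' electrodes qualifying in both with opposite signs are `mixed`; everything
#' else below threshold is `unclassified`.
#'
#' @param bias_power numeric class-bias vector (positive = sustained).
#' @param bias_itc optional second bias vector.
#' @param threshold bias threshold (10 on the normalized-archetype scale).
#' @return Character vector of classifications.
#' @export
classify_responses <- function(bias_power, bias_itc = NULL, threshold = 10) {
  cls_of <- function(b) ifelse(abs(b) > threshold,
                               ifelse(b > 0, "sustained", "transient"),
                               "unclassified")
  c1 <- cls_of(bias_power)
  if (is.null(bias_itc)) return(c1)
  c2 <- cls_of(bias_itc)
  out <- ifelse(c1 != "unclassified", c1, c2)
  both <- c1 != "unclassified" & c2 != "unclassified"
  out[both & c1 != c2] <- "mixed"
  out
}

#' Transfer conserved archetypes to a new feature matrix
#'
#' Recalculates class weights for new data while conserving the archetypes:
#' `W = A_new H^+` with the Moore-Penrose right pseudo-inverse (negative
#' weights rectified to zero), or exact non-negative least squares per
#' electrode.
#'
#' @param model a fitted `nnmf`.
#' @param A_new feature matrix on the same time axis as `H`.
#' @param method "pinv" (default) or "nnls".
#' @return The new weight matrix W (m x k).
#' @export
transfer_weights <- function(model, A_new, method = c("pinv", "nnls")) {
  method <- match.arg(method)
  A_new <- as.matrix(A_new)
  H <- model$H
  stopifnot(ncol(A_new) == ncol(H))
  if (qr(H)$rank < nrow(H)) stop("archetype matrix is rank deficient")
  G <- H %*% t(H)
  if (method == "pinv") {
    W <- A_new %*% t(H) %*% solve(G)
    W[W < 0] <- 0
    return(W)
  }
  # exact NNLS for k = 2 via active sets
  if (nrow(H) != 2) stop("nnls path implemented for rank 2")
  b <- A_new %*% t(H)
  W <- matrix(0, nrow(A_new), 2)
  for (i in seq_len(nrow(A_new))) {
    w <- solve(G, b[i, ])
    if (all(w >= 0)) { W[i, ] <- w; next }
    w1 <- max(b[i, 1] / G[1, 1], 0)
    w2 <- max(b[i, 2] / G[2, 2], 0)
    r1 <- sum((A_new[i, ] - w1 * H[1, ])^2)
    r2 <- sum((A_new[i, ] - w2 * H[2, ])^2)
    W[i, ] <- if (r1 <= r2) c(w1, 0) else c(0, w2)
  }
  W
}

#' @export
predict.nnmf <- function(object, newdata, ...) transfer_weights(object, newdata)

#' Spearman correlation of class bias with anatomical position
#'
#' Computed over electrodes with a large response magnitude, so only clearly
#' responsive sites enter the gradient estimate. Sign convention: bias is
#' negated so transient-posterior gradients give positive correlations.
#'
#' @param bias,magnitude from [class_bias()].
#' @param position anteroposterior coordinate (mm) per electrode.
#' @param magnitude_min qualifying threshold.
#' @return List with `rho`, `p`, `n`.
#' @export
gradient_correlation <- function(bias, magnitude, position,
                                 magnitude_min = 10) {
  keep <- magnitude > magnitude_min & is.finite(position)
  if (sum(keep) < 5) stop("fewer than 5 electrodes qualify for the gradient")
  ct <- suppressWarnings(stats::cor.test(-bias[keep], position[keep],
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Select the most active electrode per subject
#'
#' Argmax of a per-electrode summary (mean high-gamma percent change during
#' the stimulus, or the transient-burst magnitude), with a deterministic
#' lexicographic tie-break on electrode id.
#'
#' @param summary data.frame with columns `subject`, `id`, `value`.
#' @return One row per subject.
#' @export
select_peak_electrode <- function(summary) {
  stopifnot(all(c("subject", "id", "value") %in% names(summary)))
  do.call(rbind, lapply(split(summary, summary$subject), function(d) {
    d <- d[order(-d$value, d$id), ]
    d[1, , drop = FALSE]
  }))
}

#' Fit a mediolateral traveling wave to high-gamma peak times
#'
#' Per acoustic pulse, robust linear regression of peak time on mediolateral
#' position; velocity is the inverse slope. The mean wave averages pulses 2
#' onward. Fits with R-squared below `r2_min` are flagged undefined.
#'
#' @param peak_times matrix, electrodes x pulses, of high-gamma peak times
#'   (s) relative to each pulse.
#' @param mediolateral_pos_mm electrode positions (mm); >= 4 electrodes.
#' @param r2_min goodness-of-fit floor.
#' @return List with `velocity_m_per_s` (NA when undefined), `direction`
#'   ("medial_to_lateral" for positive slope), `per_pulse` (velocity, r2),
#'   `defined`.
#' @export
traveling_wave_fit <- function(peak_times, mediolateral_pos_mm, r2_min = 0.5) {
  peak_times <- as.matrix(peak_times)
  if (nrow(peak_times) < 4) stop("need at least 4 electrodes")
  stopifnot(length(mediolateral_pos_mm) == nrow(peak_times))
  per <- lapply(seq_len(ncol(peak_times)), function(p) {
    y <- peak_times[, p]
    ok <- is.finite(y)
    if (sum(ok) < 4) return(data.frame(pulse = p, velocity = NA, r2 = NA))
    fit <- MASS::rlm(y[ok] ~ mediolateral_pos_mm[ok], maxit = 100)
    slope <- unname(stats::coef(fit)[2])            # s per mm
    r2 <- summary(stats::lm(y[ok] ~ mediolateral_pos_mm[ok]))$r.squared
    data.frame(pulse = p, velocity = if (slope != 0) 1e-3 / slope else NA,
               r2 = r2)
  })
  per <- do.call(rbind, per)
  use <- per$r2 >= r2_min & is.finite(per$velocity)
  use[1] <- FALSE          # mean wave averages pulses 2 onward
  if (!any(use, na.rm = TRUE))
    return(list(velocity_m_per_s = NA_real_, direction = NA_character_,
                per_pulse = per, defined = FALSE))
  v <- mean(per$velocity[which(use)])
  list(velocity_m_per_s = v,
       direction = if (v > 0) "medial_to_lateral" else "lateral_to_medial",
       per_pulse = per, defined = TRUE)
}

#' Estimate per-pulse high-gamma peak times
#'
#' Time of maximum trial-averaged high-gamma power within half a modulation
#' cycle around each pulse peak.
#'
#' @param hg_mean electrodes x time trial-mean power matrix.
#' @param time epoch time axis (s).
#' @param pulse_peak_times stimulus pulse-peak times (s).
#' @param mod_freq_hz modulation frequency (Hz).
#' @return Matrix electrodes x pulses of peak times relative to each pulse
#'   peak (s).
#' @export
peak_time_by_pulse <- function(hg_mean, time, pulse_peak_times, mod_freq_hz = 3) {
  half <- 1 / (2 * mod_freq_hz)
  out <- matrix(NA_real_, nrow(hg_mean), length(pulse_peak_times))
  for (p in seq_along(pulse_peak_times)) {
    sel <- which(time >= pulse_peak_times[p] - half &
                 time < pulse_peak_times[p] + half)
    if (!length(sel)) next
    out[, p] <- time[sel[apply(hg_mean[, sel, drop = FALSE], 1, which.max)]] -
      pulse_peak_times[p]
  }
  out
}
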