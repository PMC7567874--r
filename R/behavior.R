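# Detection-task psychophysics and chronometric-stimulation outcome tests.

#' Detection accuracy by intensity level and temporal position
#'
#' Hit rate on tone-present trials per level and per level x position cell,
#' with binomial standard errors; overall per-level accuracy including
#' correct rejections is reported separately.
#'
#' @param trials a `detection_trial_table` (columns `tone_present`,
#'   `level_index`, `position_index`, `response`, `subject_id`).
#' @return List with `by_level`, `by_level_position` (hit rates), and
#'   `overall` (accuracy including correct rejections).
#' @export
accuracy_by_condition <- function(trials) {
  present <- trials[trials$tone_present %in% TRUE, ]
  cell <- function(d) {
    n <- nrow(d)
    p <- if (n) mean(d$response) else NA_real_
    data.frame(hit_rate = p, se = if (n) sqrt(p * (1 - p) / n) else NA_real_,
               n = n)
  }
  by_level <- do.call(rbind, lapply(split(present, present$level_index), cell))
  by_level$level_index <- as.integer(rownames(by_level))
  grid <- expand.grid(level_index = sort(unique(present$level_index)),
                      position_index = 1:5)
  blp <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    d <- present[present$level_index == grid$level_index[i] &
                 present$position_index == grid$position_index[i], ]
    cbind(grid[i, ], cell(d))
  }))
  cr <- trials[!trials$tone_present, ]
  overall <- do.call(rbind, lapply(split(present, present$level_index),
    function(d) {
      correct <- sum(d$response) + sum(!cr$response)
      n <- nrow(d) + nrow(cr)
      data.frame(accuracy = correct / n, n = n)
    }))
  overall$level_index <- as.integer(rownames(overall))
  rownames(by_level) <- rownames(blp) <- rownames(overall) <- NULL
  list(by_level = by_level, by_level_position = blp, overall = overall)
}

#' Test the position-2 detectability effect
#'
#' Paired Wilcoxon signed-rank tests of the position-2 hit rate against every
#' other temporal position, across subjects, at the lowest intensity level.
#' Ties are handled by the normal approximation; p-values are Holm-adjusted
#' by default.
#'
#' @param trials a `detection_trial_table`, or a subjects x positions matrix
#'   of per-subject hit rates.
#' @param level_index which level to test (1 = lowest) when `trials` is a
#'   trial table.
#' @param adjust multiple-comparison method passed to [stats::p.adjust()].
#' @return data.frame with one row per contrast (`position`, `p`,
#'   `p_adjusted`).
#' @export
position_effect_test <- function(trials, level_index = 1, adjust = "holm") {
  if (is.matrix(trials)) {
    acc <- trials
  } else {
    d <- trials[trials$tone_present %in% TRUE &
                trials$level_index == level_index, ]
    acc <- tapply(d$response, list(d$subject_id, d$position_index), mean)
  }
  if (nrow(acc) < 6) stop("at least 6 subjects are required")
  others <- setdiff(seq_len(ncol(acc)), 2)
  p <- vapply(others, function(j) {
    x <- acc[, 2]; y <- acc[, j]
    ok <- is.finite(x) & is.finite(y)
    if (all(x[ok] == y[ok])) return(1)
    stats::wilcox.test(x[ok], y[ok], paired = TRUE, alternative = "greater",
                       exact = FALSE)$p.value
  }, 0)
  data.frame(position = others, p = p,
             p_adjusted = stats::p.adjust(p, method = adjust))
}

#' Pooled two-proportion z-test
#'
#' Compares success proportions of two independent binomials with the
#' pooled-variance z statistic. One-sided by default (`alternative =
#' "less"`: tests whether group 1's proportion is below group 2's).
#' Swapping the groups flips the sign of z and maps a one-sided p to
#' `1 - p`.
#'
#' @param successes1,n1,successes2,n2 counts.
#' @param alternative "less" (default), "greater", or "two.sided".
#' @return List with `z`, `p`, `p1`, `p2`.
#' @export
two_proportion_z <- function(successes1, n1, successes2, n2,
                             alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n1 >= 5, n2 >= 5, successes1 <= n1, successes2 <= n2)
  p1 <- successes1 / n1
  p2 <- successes2 / n2
  pool <- (successes1 + successes2) / (n1 + n2)
  v <- pool * (1 - pool) * (1 / n1 + 1 / n2)
  if (v == 0)
    return(list(z = NA_real_, p = NA_real_, p1 = p1, p2 = p2,
                degenerate = TRUE))
  z <- (p1 - p2) / sqrt(v)
  p <- switch(alternative,
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(z = z, p = p, p1 = p1, p2 = p2, degenerate = FALSE)
}

#' Reconstruct integer success counts from a printed percentage
#'
#' `round(percent/100 * n)`, flagging ambiguity when more than one integer
#' count rounds to the printed percentage.
#'
#' @param percent printed accuracy (0-100).
#' @param n number of trials.
#' @return List with `successes` and `ambiguous`.
#' @export
reconstruct_counts <- function(percent, n) {
  stopifnot(percent >= 0, percent <= 100)
  s <- round(percent / 100 * n)
  matches <- which(round(100 * (0:n) / n) == round(percent)) - 1L
  list(successes = s, ambiguous = length(matches) > 1L)
}
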