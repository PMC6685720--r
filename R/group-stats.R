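#' Hemispheric laterality index of FA change
#'
#' `(dR - dL) / (|dR| + |dL|)`, where `dR` and `dL` are the post-minus-pre
#' FA changes in the right and left ROI. Bounded in \[-1, 1\]; positive
#' values mean the change is right-lateralized. Undefined (returned as
#' `NA`) when both changes are exactly zero.
#'
#' @param delta_right,delta_left FA change scores (post - pre), finite.
#' @return A numeric vector in \[-1, 1\], `NA` where both deltas are 0.
#' @examples
#' laterality_index(1, -1)        # +1, maximally right-lateralized
#' laterality_index(-0.02, -0.01) # -1/3
#' @export
laterality_index <- function(delta_right, delta_left) {
  if (any(!is.finite(delta_right)) || any(!is.finite(delta_left))) {
    abort("laterality_index requires finite inputs")
  }
  denom <- abs(delta_right) + abs(delta_left)
  ifelse(denom == 0, NA_real_, (delta_right - delta_left) / denom)
}

#' Paired pre/post location tests
#'
#' Runs both the parametric paired t test and the nonparametric Wilcoxon
#' matched-pairs signed-rank test (two-tailed) on pre/post measurements.
#' Zero differences are dropped from the Wilcoxon test (Wilcoxon's
#' original rule, as in [stats::wilcox.test()]); the exact signed-rank
#' null is used when there are no ties or zeros among fewer than 50
#' pairs. If all differences are zero, both tests report a statistic of 0
#' with p = 1 and a `"no-effect"` note.
#'
#' @param pre,post Numeric vectors of equal length (>= 3).
#' @return A tibble with one row per test: `method`, `statistic`,
#'   `p.value`, `n`, `note`.
#' @export
paired_location_test <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 3)
  d <- post - pre
  n <- length(d)
  note <- NA_character_
  if (all(d == 0)) {
    return(tibble(
      method = c("paired t", "wilcoxon signed-rank"),
      statistic = c(0, 0), p.value = c(1, 1), n = n,
      note = "no-effect: all differences zero"
    ))
  }
  s <- sd(d)
  if (s == 0) {
    t_stat <- sign(mean(d)) * Inf
    t_p <- 0
    note <- "degenerate: constant nonzero differences"
  } else {
    t_stat <- mean(d) / (s / sqrt(n))
    t_p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  w <- suppressWarnings(wilcox.test(post, pre, paired = TRUE))
  bind_rows(
    tibble(method = "paired t", statistic = t_stat, p.value = t_p, n = n,
           note = note),
    tibble(method = "wilcoxon signed-rank",
           statistic = unname(w$statistic), p.value = w$p.value, n = n,
           note = NA_character_)
  )
}

#' Two-sample location test
#'
#' Two-tailed two-sample t test, pooled variance by default (Welch by
#' flag). Degenerate input (zero variance in both groups with equal
#' means) is reported as a no-effect row rather than an error.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance t test (default `TRUE`); `FALSE` for
#'   Welch.
#' @return A one-row tibble: `method`, `statistic`, `p.value`, `n`
#'   (total), `n_a`, `n_b`, `note`.
#' @export
two_sample_test <- function(group_a, group_b, var_equal = TRUE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  method <- if (var_equal) "two-sample t (pooled)" else "two-sample t (Welch)"
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(tibble(method = method, statistic = 0, p.value = 1,
                    n = length(group_a) + length(group_b),
                    n_a = length(group_a), n_b = length(group_b),
                    note = "no-effect: both groups constant and equal"))
    }
    return(tibble(method = method,
                  statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                  p.value = 0,
                  n = length(group_a) + length(group_b),
                  n_a = length(group_a), n_b = length(group_b),
                  note = "degenerate: both groups constant, means differ"))
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  tibble(method = method, statistic = unname(tt$statistic),
         p.value = tt$p.value,
         n = length(group_a) + length(group_b),
         n_a = length(group_a), n_b = length(group_b),
         note = NA_character_)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank handling of ties: rho is the Pearson
#' correlation of the midranks. The two-tailed p-value uses the exact
#' null distribution of the rank statistic for n <= 10 without ties, and
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom otherwise. A constant input vector makes rho
#' undefined; this is flagged, not an error.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return A one-row tibble: `method`, `estimate` (rho), `p.value`, `n`,
#'   `note`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("spearman_corr requires at least 4 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    return(tibble(method = "spearman", estimate = NA_real_,
                  p.value = NA_real_, n = n,
                  note = "undefined: constant input"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !has_ties) {
    p <- cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    note <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(t_stat), df = n - 2)
    }
    note <- "t approximation"
  }
  tibble(method = "spearman", estimate = rho, p.value = min(p, 1), n = n,
         note = note)
}

#' Dose-response sweep over force thresholds
#'
#' For each threshold, counts every player's hits at or above the
#' threshold and rank-correlates the counts with that player's FA change
#' (right hemisphere by default, the hypothesis-bearing ROI). Supplying
#' the nine pooled decile boundaries (see [decile_thresholds()])
#' reproduces the threshold-robustness control; supplying a single
#' cohort-SD threshold reproduces the primary dose-response test.
#'
#' @param hit_log A hit-log data frame.
#' @param outcomes A data frame with `player_id` and the outcome column
#'   (default `delta_right`). Must cover every player in the log.
#' @param metric `"rotational"` or `"linear"`.
#' @param thresholds Numeric vector of thresholds. Default: the decile
#'   thresholds of the pooled metric distribution.
#' @param outcome Name of the outcome column in `outcomes` (default
#'   `"delta_right"`; use `"delta_left"` for the other hemisphere).
#' @param inclusive Count hits `>=` threshold (default).
#' @return A tibble with one row per threshold: `threshold`, `rho`,
#'   `p.value`, `n`, `degenerate` (TRUE where counts were constant across
#'   players and rho is undefined).
#' @export
dose_response_sweep <- function(hit_log, outcomes,
                                metric = c("rotational", "linear"),
                                thresholds = NULL,
                                outcome = "delta_right",
                                inclusive = TRUE) {
  metric <- match.arg(metric)
  assert_hit_log(hit_log)
  if (!outcome %in% names(outcomes)) {
    abort(sprintf("outcomes has no column '%s'", outcome))
  }
  log_players <- unique(as.character(hit_log$player_id))
  out_players <- as.character(outcomes$player_id)
  if (!all(log_players %in% out_players)) {
    abort("outcomes must cover every player present in the hit log")
  }
  if (is.null(thresholds)) {
    thresholds <- decile_thresholds(hit_log, metric)
  }
  if (length(thresholds) == 0) abort("thresholds must be non-empty")
  y <- outcomes[[outcome]]
  purrr::map_dfr(as.numeric(thresholds), function(th) {
    cnt <- suprathreshold_counts(hit_log, metric, th,
                                 players = out_players,
                                 inclusive = inclusive)
    res <- spearman_corr(cnt$n_supra, y)
    tibble(threshold = th, rho = res$estimate, p.value = res$p.value,
           n = res$n,
           degenerate = !is.na(res$note) & startsWith(res$note, "undefined"))
  })
}

#' Serum tau vs FA association
#'
#' Correlates peripheral tau (pg/mL) with post-injury FA. The estimator
#' is rank correlation by default; a linear (Pearson) estimator is
#' available by flag, and the choice is recorded in the output.
#'
#' @param data A data frame holding both variables (rows with missing tau
#'   are dropped).
#' @param tau,fa Column names (default `"tau"`, `"fa_post_right"`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A one-row tibble: `method`, `estimate`, `p.value`, `n`, `note`.
#' @export
tau_fa_association <- function(data, tau = "tau", fa = "fa_post_right",
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(all(c(tau, fa) %in% names(data)))
  keep <- is.finite(data[[tau]]) & is.finite(data[[fa]])
  x <- data[[tau]][keep]
  y <- data[[fa]][keep]
  if (length(x) < 4) abort("tau_fa_association requires at least 4 complete pairs")
  if (method == "spearman") {
    return(spearman_corr(x, y))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(method = "pearson", estimate = unname(ct$estimate),
         p.value = ct$p.value, n = length(x), note = NA_character_)
}
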