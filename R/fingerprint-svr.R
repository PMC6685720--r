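#' Configuration for the fingerprint-to-laterality SVR analysis
#'
#' @param nu Fraction in (0, 1\] lower-bounding the proportion of support
#'   vectors in nu-SVR. Default 20/37: roughly 20 support vectors out of
#'   37 training rows in a leave-one-out fold over 38 players.
#' @param cost Regularization strength C of the nu-SVR (default 10).
#'   Fingerprint features are proportions summing to 1, so individual
#'   entries are tiny and weaker regularization than the textbook C = 1
#'   is needed to avoid underfitting; see the methods vignette.
#' @param n_permutations Number of label shuffles for the permutation
#'   null (default 1000; 100000 reproduces a publication-scale null).
#' @param seed Integer seed controlling the permutation shuffles.
#' @param alpha_nominal Significance level for the relevance map's
#'   Bonferroni threshold (default 0.05, i.e. 0.05/648 per bin).
#' @param max_fits Refuse permutation runs needing more than this many
#'   model fits (`n_permutations x n`); guards against accidentally
#'   launching week-long jobs. Default 5e6.
#' @return A list of class `svr_config`.
#' @export
svr_config <- function(nu = 20 / 37, cost = 10, n_permutations = 1000,
                       seed = 1L, alpha_nominal = 0.05, max_fits = 5e6) {
  stopifnot(is.numeric(nu), length(nu) == 1, nu > 0, nu <= 1,
            is.numeric(cost), length(cost) == 1, cost > 0,
            n_permutations >= 1, alpha_nominal >= 0, alpha_nominal <= 1,
            max_fits >= 1)
  structure(list(nu = nu, cost = cost,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), alpha_nominal = alpha_nominal,
                 max_fits = max_fits),
            class = "svr_config")
}

#' @keywords internal
#' @noRd
validate_svr_input <- function(X, y) {
  stopifnot(is.matrix(X), is.numeric(y), nrow(X) == length(y))
  keep <- is.finite(y)
  if (!all(keep)) {
    warn(sprintf("excluding %d row(s) with undefined laterality",
                 sum(!keep)))
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (nrow(X) < 5) abort("need at least 5 players with defined laterality")
  rs <- rowSums(X)
  bad <- abs(rs - 1) > 1e-6 & rs != 0
  if (any(bad)) {
    warn(sprintf("%d fingerprint row(s) neither sum to 1 nor are all-zero",
                 sum(bad)))
  }
  list(X = X, y = unname(y), kept = unname(which(keep)))
}

#' Leave-one-out nu-SVR predictions
#'
#' For each player i, fits a linear-kernel nu-SVR mapping spatial
#' fingerprints to laterality indices on the other n - 1 players, then
#' predicts player i's laterality from their held-out fingerprint. Also
#' returns each fold's primal weight vector (length = number of bins),
#' used for the feature-relevance map.
#'
#' @param X Players x bins fingerprint matrix (rows sum to 1; all-zero
#'   rows are allowed for players without hits and are flagged).
#' @param y Observed laterality indices (`NA` rows are excluded with a
#'   warning; at least 5 defined rows are required).
#' @param config An [svr_config()].
#' @return A list: `predicted` (out-of-fold predictions), `observed`,
#'   `weights` (n x bins matrix of per-fold primal weights), `n_sv`
#'   (realized support-vector count per fold), `kept` (row indices used).
#' @export
loocv_svr_predict <- function(X, y, config = svr_config()) {
  v <- validate_svr_input(X, y)
  ctx <- loo_context(v$X)
  res <- loo_core(ctx, v$y, config$nu, config$cost, want_weights = TRUE)
  list(predicted = res$predicted, observed = v$y, weights = res$weights,
       n_sv = res$n_sv, kept = v$kept)
}

#' Squared correlation between predicted and observed values
#'
#' The cross-validated accuracy statistic: the square of the linear
#' correlation between model predictions and observations. Undefined
#' (returns `NA` with a warning) when either vector has zero variance;
#' permutation nulls count such degenerate shuffles as r^2 = 0.
#'
#' @param predicted,observed Numeric vectors of equal length >= 3.
#' @return A scalar in \[0, 1\], or `NA` if degenerate.
#' @export
prediction_r2 <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3,
            all(is.finite(predicted)), all(is.finite(observed)))
  if (var(predicted) == 0 || var(observed) == 0) {
    warn("zero variance in predicted or observed values; r^2 undefined")
    return(NA_real_)
  }
  cor(predicted, observed)^2
}

#' Permutation null for the cross-validated r^2
#'
#' Shuffles laterality indices against fingerprints and reruns the full
#' leave-one-out procedure for each shuffle, recording the cross-validated
#' r^2 each time. The permutation p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`, so p is never
#' exactly zero. Shuffles where r^2 is undefined (constant predictions)
#' count as r^2 = 0. Reproducible given `config$seed`.
#'
#' @inheritParams loocv_svr_predict
#' @return A list: `observed_r2`, `null_r2` (length `n_permutations`),
#'   `p_value`, `n_permutations`.
#' @export
permutation_null <- function(X, y, config = svr_config()) {
  v <- validate_svr_input(X, y)
  n <- nrow(v$X)
  n_fits <- as.numeric(config$n_permutations) * n
  if (n_fits > config$max_fits) {
    abort(sprintf(paste0(
      "permutation run needs %.0f model fits, above the configured budget ",
      "of %.0f; lower n_permutations, reduce the cohort, or raise ",
      "max_fits in svr_config()"), n_fits, config$max_fits))
  }
  ctx <- loo_context(v$X)
  obs <- loo_core(ctx, v$y, config$nu, config$cost, want_weights = FALSE)
  obs_r2 <- suppressWarnings(prediction_r2(obs$predicted, v$y))
  if (is.na(obs_r2)) obs_r2 <- 0
  null_r2 <- withr::with_seed(config$seed, {
    vapply(seq_len(config$n_permutations), function(b) {
      yp <- v$y[sample.int(n)]
      pr <- loo_core(ctx, yp, config$nu, config$cost,
                     want_weights = FALSE)$predicted
      if (var(pr) == 0 || var(yp) == 0) 0 else cor(pr, yp)^2
    }, numeric(1))
  })
  p <- (1 + sum(null_r2 >= obs_r2)) / (1 + config$n_permutations)
  list(observed_r2 = obs_r2, null_r2 = null_r2, p_value = p,
       n_permutations = config$n_permutations)
}

#' Per-bin feature relevance with Bonferroni threshold
#'
#' For each spatial bin, correlates the fold-specific SVR weight at that
#' bin with the observed laterality of each fold's held-out player, and
#' reports the squared correlation as the bin's relevance. Significance
#' is Bonferroni-corrected across bins: a bin is flagged when its
#' two-tailed p is below `alpha / n_bins` (0.05/648 ~ 7.7e-5 at the
#' default resolution). Zero-variance weight columns get relevance 0 and
#' are never significant.
#'
#' @param weights n x bins matrix of per-fold primal weights (from
#'   [loocv_svr_predict()]).
#' @param y Observed laterality per held-out player (length n).
#' @param alpha Nominal significance level before correction (default
#'   0.05); `alpha = 0` yields an empty significance mask.
#' @return A tibble with one row per bin: `bin` (zero-based),
#'   `relevance` (squared correlation), `p.value`, `significant`.
#'   Attribute `alpha_per_bin` records the corrected threshold.
#' @export
feature_relevance <- function(weights, y, alpha = 0.05) {
  stopifnot(is.matrix(weights), nrow(weights) == length(y),
            alpha >= 0, alpha <= 1)
  n <- length(y)
  p_bins <- ncol(weights)
  alpha_bin <- alpha / p_bins
  col_var <- apply(weights, 2, var)
  r <- rep(0, p_bins)
  ok <- col_var > 0 & var(y) > 0
  if (any(ok)) r[ok] <- as.numeric(cor(weights[, ok, drop = FALSE], y))
  r2 <- r^2
  pval <- rep(NA_real_, p_bins)
  finite_r <- ok & abs(r) < 1
  pval[finite_r] <- 2 * pt(-abs(r[finite_r]) *
                             sqrt((n - 2) / (1 - r2[finite_r])),
                           df = n - 2)
  pval[ok & abs(r) >= 1] <- 0
  sig <- !is.na(pval) & pval < alpha_bin
  out <- tibble(bin = seq_len(p_bins) - 1L, relevance = r2, p.value = pval,
                significant = sig)
  attr(out, "alpha_per_bin") <- alpha_bin
  out
}

#' Critical r^2 from the t distribution
#'
#' Inverts the t-r relation `t = r * sqrt(df / (1 - r^2))`: the squared
#' correlation at which a two-tailed test on `df` degrees of freedom is
#' exactly significant at level `alpha`. At alpha = 0.01 and df = 37 this
#' is ~0.17; at the Bonferroni-corrected 0.05/648 and df = 36, ~0.36.
#'
#' @param alpha Two-tailed significance level.
#' @param df Degrees of freedom (n - 2 for a correlation).
#' @return The critical squared correlation.
#' @export
critical_r2 <- function(alpha, df) {
  stopifnot(alpha > 0, alpha < 1, df >= 1)
  t_crit <- qt(1 - alpha / 2, df = df)
  t_crit^2 / (t_crit^2 + df)
}

#' Fingerprint-to-laterality SVR analysis
#'
#' The full multivariate stage: leave-one-out nu-SVR predictions of the
#' laterality index from spatial fingerprints, cross-validated r^2,
#' permutation null, and the Bonferroni-thresholded per-bin relevance
#' map.
#'
#' @inheritParams loocv_svr_predict
#' @param permute Run the permutation null (default `TRUE`).
#' @return An object of class `svr_laterality`: a list with `predicted`,
#'   `observed`, `r_squared`, `null_r2`, `permutation_p`, `weights`,
#'   `n_sv`, `relevance` (tibble from [feature_relevance()]), `config`,
#'   `n`, `players`. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
svr_laterality <- function(X, y, config = svr_config(), permute = TRUE) {
  loo <- loocv_svr_predict(X, y, config)
  r2 <- suppressWarnings(prediction_r2(loo$predicted, loo$observed))
  rel <- feature_relevance(loo$weights, loo$observed,
                           alpha = config$alpha_nominal)
  null_r2 <- NULL
  p <- NA_real_
  if (permute) {
    pn <- permutation_null(X, y, config)
    null_r2 <- pn$null_r2
    p <- pn$p_value
  }
  players <- rownames(X)
  if (is.null(players)) players <- as.character(seq_len(nrow(X)))
  structure(list(predicted = loo$predicted, observed = loo$observed,
                 r_squared = r2, null_r2 = null_r2, permutation_p = p,
                 weights = loo$weights, n_sv = loo$n_sv, relevance = rel,
                 config = config, n = length(loo$observed),
                 players = players[loo$kept]),
            class = "svr_laterality")
}

#' @export
print.svr_laterality <- function(x, ...) {
  cat("<svr_laterality> leave-one-out nu-SVR, n = ", x$n,
      ", bins = ", ncol(x$weights), "\n", sep = "")
  cat("  cross-validated r^2 = ", format(x$r_squared, digits = 3), sep = "")
  if (!is.na(x$permutation_p)) {
    cat(", permutation p = ", format(x$permutation_p, digits = 3),
        " (", length(x$null_r2), " shuffles)", sep = "")
  }
  cat("\n  support vectors per fold: ",
      paste(range(x$n_sv), collapse = "-"),
      " (nu = ", format(x$config$nu, digits = 3), ")\n", sep = "")
  cat("  significant bins (Bonferroni): ", sum(x$relevance$significant),
      "/", nrow(x$relevance), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-player predictions of an SVR fit
#'
#' @param x An `svr_laterality` object.
#' @param ... Unused.
#' @return A tibble with `player_id`, `observed`, `predicted`,
#'   `residual`, `n_sv`.
#' @method tidy svr_laterality
#' @export
tidy.svr_laterality <- function(x, ...) {
  tibble(player_id = x$players, observed = x$observed,
         predicted = x$predicted,
         residual = x$observed - x$predicted, n_sv = x$n_sv)
}

#' One-row model summary of an SVR fit
#'
#' @inheritParams tidy.svr_laterality
#' @return A one-row tibble: `r_squared`, `permutation_p`,
#'   `n_permutations`, `n`, `n_bins`, `nu`, `cost`, `n_significant_bins`,
#'   `critical_r2_bonferroni`.
#' @method glance svr_laterality
#' @export
glance.svr_laterality <- function(x, ...) {
  tibble(r_squared = x$r_squared, permutation_p = x$permutation_p,
         n_permutations = if (is.null(x$null_r2)) 0L else length(x$null_r2),
         n = x$n, n_bins = ncol(x$weights), nu = x$config$nu,
         cost = x$config$cost,
         n_significant_bins = sum(x$relevance$significant),
         critical_r2_bonferroni = critical_r2(
           x$config$alpha_nominal / ncol(x$weights), df = x$n - 2))
}
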