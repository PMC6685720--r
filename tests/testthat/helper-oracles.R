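# Independent brute-force oracles. Each reimplements the documented
# contract by direct enumeration or naive loops, never by calling the
# package's own code paths.

# Loop over all bin rectangles; angles must already be canonical
# (azimuth in [-180, 180), elevation in [-90, 90]).
oracle_bin_index <- function(azimuth, elevation, bin_width = 10) {
  n_az <- 360 / bin_width
  n_el <- 180 / bin_width
  az_edges <- seq(-180, 180, by = bin_width)
  el_edges <- seq(-90, 90, by = bin_width)
  vapply(seq_along(azimuth), function(h) {
    az <- azimuth[h]
    el <- elevation[h]
    for (a in seq_len(n_az)) {
      in_az <- az >= az_edges[a] & az < az_edges[a + 1]
      for (e in seq_len(n_el)) {
        in_el <- if (e == n_el) {
          el >= el_edges[e] & el <= el_edges[e + 1]
        } else {
          el >= el_edges[e] & el < el_edges[e + 1]
        }
        if (in_az && in_el) return(as.integer((a - 1) * n_el + (e - 1)))
      }
    }
    stop("no bin found")
  }, integer(1))
}

oracle_summarize <- function(hits) {
  out <- list()
  session <- tolower(hits$session_type)
  session[!session %in% c("practice", "game")] <- "other"
  for (s in c("practice", "game", "other")) {
    sel <- hits[session == s, , drop = FALSE]
    out[[s]] <- c(n = nrow(sel),
                  pct = 100 * nrow(sel) / nrow(hits),
                  lin_med = median(sel$linear_g),
                  lin_mean = mean(sel$linear_g),
                  rot_med = median(sel$rotational_rad_s2),
                  rot_mean = mean(sel$rotational_rad_s2))
  }
  out
}

# naive filter-and-count
oracle_count_supra <- function(values, threshold) {
  n <- 0L
  for (v in values) if (v >= threshold) n <- n + 1L
  n
}

oracle_exclusive <- function(rot, lin, rot_thr, lin_thr) {
  cell <- c(rot_only = 0L, lin_only = 0L, both = 0L, neither = 0L)
  for (h in seq_along(rot)) {
    r <- rot[h] >= rot_thr
    l <- lin[h] >= lin_thr
    key <- if (r && !l) "rot_only" else if (!r && l) "lin_only"
           else if (r && l) "both" else "neither"
    cell[key] <- cell[key] + 1L
  }
  cell
}

# sort-and-interpolate (quantile type 7) without calling quantile()
oracle_decile <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  vapply(seq(0.1, 0.9, by = 0.1), function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }, numeric(1))
}

oracle_mask_and <- function(a, b) {
  d <- dim(a)
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (a[i, j, k] == 1 && b[i, j, k] == 1) out[i, j, k] <- 1
  }
  out
}

oracle_mean_in_mask <- function(vol, mask) {
  d <- dim(vol)
  s <- 0
  n <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] == 1) {
      s <- s + vol[i, j, k]
      n <- n + 1
    }
  }
  s / n
}

# midranks by counting, then the Pearson formula written out
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# exhaustive 2^n sign-flip null of the signed-rank statistic
# (zeros dropped; assumes no ties among |d|)
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.numeric(signs %*% r)
  p_le <- mean(v_null <= v_obs)
  p_ge <- mean(v_null >= v_obs)
  p <- if (v_obs > n * (n + 1) / 4) 2 * p_ge else 2 * p_le
  list(statistic = v_obs, p.value = min(p, 1))
}

oracle_paired_t <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t_stat, p.value = 2 * pt(-abs(t_stat), df = n - 1))
}

# naive covariance-formula r^2
oracle_r2 <- function(a, b) {
  ca <- a - mean(a)
  cb <- b - mean(b)
  (sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2)))^2
}

random_hits <- function(n, seed, players = 4) {
  withr::with_seed(seed, {
    tibble::tibble(
      player_id = sample(sprintf("P%02d", seq_len(players)), n,
                         replace = TRUE),
      session_type = sample(c("practice", "game", "scrimmage"), n,
                            replace = TRUE),
      linear_g = rlnorm(n, log(25), 0.7),
      rotational_rad_s2 = rlnorm(n, log(1600), 0.6),
      azimuth_deg = runif(n, -180, 180 - 1e-9),
      elevation_deg = runif(n, -90, 90)
    )
  })
}
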