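test_that("laterality index evaluates the normalized right-left contrast", {
  expect_equal(laterality_index(1, -1), 1)
  expect_equal(laterality_index(-0.02, -0.01), -1 / 3)
  expect_true(is.na(laterality_index(0, 0)))
  expect_error(laterality_index(Inf, 0), "finite")
})

test_that("laterality index is bounded, antisymmetric and scale-invariant", {
  withr::with_seed(99, {
    dr <- rnorm(1000, 0, 0.05)
    dl <- rnorm(1000, 0, 0.05)
  })
  li <- laterality_index(dr, dl)
  expect_true(all(abs(li) <= 1))
  expect_equal(laterality_index(dl, dr), -li)           # hemisphere swap
  expect_equal(laterality_index(3.7 * dr, 3.7 * dl), li) # positive rescale
})

test_that("paired tests match formula and exhaustive-enumeration oracles", {
  x <- c(0.5, 0.52, 0.47, 0.55, 0.51)
  same <- paired_location_test(x, x)
  expect_equal(same$statistic[same$method == "paired t"], 0)
  expect_equal(same$p.value, c(1, 1))

  pre <- rep(0, 6)
  post <- c(-1, -2, -3, -4, -5, 0.5)
  got <- paired_location_test(pre, post)
  ora <- oracle_paired_t(pre, post)
  expect_equal(got$statistic[got$method == "paired t"], ora$statistic)
  expect_equal(got$p.value[got$method == "paired t"], ora$p.value)
  # cross-check against the reference implementation
  tt <- t.test(post, pre, paired = TRUE)
  expect_equal(got$statistic[got$method == "paired t"],
               unname(tt$statistic))

  # Wilcoxon two-tailed p equals the 2^n sign-assignment enumeration
  for (s in 1:6) {
    n <- sample(5:10, 1)
    d <- withr::with_seed(s, round(rnorm(n, 0.3, 1), 3))
    if (anyDuplicated(abs(d)) || any(d == 0)) next
    got <- paired_location_test(rep(0, n), d)
    ora <- oracle_wilcoxon_exact(d)
    expect_equal(got$statistic[got$method == "wilcoxon signed-rank"],
                 ora$statistic)
    expect_equal(got$p.value[got$method == "wilcoxon signed-rank"],
                 ora$p.value)
  }
})

test_that("two-tailed p is invariant under sign flip of all differences", {
  withr::with_seed(17, {
    pre <- runif(12, 0.4, 0.6)
    post <- pre + rnorm(12, -0.01, 0.02)
  })
  fwd <- paired_location_test(pre, post)
  rev <- paired_location_test(post, pre)
  expect_equal(fwd$p.value, rev$p.value)
  expect_equal(fwd$statistic[fwd$method == "paired t"],
               -rev$statistic[rev$method == "paired t"])
})

test_that("two-sample test matches the pooled-variance reference", {
  g <- c(0.5, 0.52, 0.48)
  expect_equal(two_sample_test(g, g)$p.value, 1)
  withr::with_seed(23, {
    a <- rnorm(20, 0.5, 0.02)
    b <- rnorm(15, 0.48, 0.02)
  })
  got <- two_sample_test(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p.value, ref$p.value)
  welch <- two_sample_test(a, b, var_equal = FALSE)
  expect_equal(welch$p.value, t.test(a, b)$p.value)
  sep <- two_sample_test(c(0, 0, 0, 1e-9), c(1, 1, 1, 1 + 1e-9))
  expect_lt(sep$p.value, 0.01)
  flat <- two_sample_test(rep(1, 3), rep(1, 4))
  expect_match(flat$note, "no-effect")
})

test_that("spearman rho equals the midrank-Pearson oracle, incl. ties", {
  up <- spearman_corr(1:10, (1:10)^3)
  expect_equal(up$estimate, 1)
  down <- spearman_corr(1:10, -(1:10)^3)
  expect_equal(down$estimate, -1)
  for (s in 1:25) {
    withr::with_seed(s + 500, {
      n <- sample(8:40, 1)
      x <- sample(1:8, n, replace = TRUE)   # heavy ties
      y <- x * -0.5 + sample(1:6, n, replace = TRUE)
    })
    got <- spearman_corr(x, y)
    expect_equal(got$estimate, oracle_spearman_rho(x, y))
  }
  const <- spearman_corr(rep(1, 6), 1:6)
  expect_true(is.na(const$estimate))
  expect_match(const$note, "undefined")
})

test_that("spearman p uses the exact null for small tie-free samples", {
  withr::with_seed(31, {
    x <- rnorm(8)
    y <- rnorm(8)
  })
  got <- spearman_corr(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(got$p.value, ref$p.value)
  expect_equal(got$note, "exact")
  # exhaustive permutation check at n = 6: P(|rho_perm| >= |rho_obs|)
  withr::with_seed(32, {
    x6 <- rnorm(6)
    y6 <- rnorm(6)
  })
  got6 <- spearman_corr(x6, y6)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ,
                 drop = FALSE]
  rho_null <- apply(perms, 1, function(p) cor(rank(x6), rank(y6[p])))
  p_enum <- mean(abs(rho_null) >= abs(got6$estimate) - 1e-12)
  expect_equal(got6$p.value, p_enum, tolerance = 1e-10)
  # large-sample branch is the documented t approximation
  withr::with_seed(33, {
    xl <- rnorm(25)
    yl <- 0.4 * xl + rnorm(25)
  })
  gl <- spearman_corr(xl, yl)
  tt <- gl$estimate * sqrt((25 - 2) / (1 - gl$estimate^2))
  expect_equal(gl$p.value, 2 * pt(-abs(tt), df = 23))
})

test_that("dose-response sweep composes counting and rank correlation", {
  co <- simulate_cohort(cohort_config(n_players = 12,
                                      hits_per_player_mean = 120, seed = 5))
  thr <- cohort_sd_threshold(co$hit_log, "rotational")$threshold
  sw <- dose_response_sweep(co$hit_log, co$outcomes, "rotational",
                            thresholds = thr)
  cnt <- suprathreshold_counts(co$hit_log, "rotational", thr,
                               players = co$outcomes$player_id)
  direct <- spearman_corr(cnt$n_supra, co$outcomes$delta_right)
  expect_equal(sw$rho, direct$estimate)
  expect_equal(sw$p.value, direct$p.value)
  expect_equal(nrow(sw), 1)
  # default sweep: one row per decile threshold
  sw9 <- dose_response_sweep(co$hit_log, co$outcomes)
  expect_equal(nrow(sw9), 9)
  expect_true(all(sw9$n == 12))
  orphan <- co$outcomes[-1, ]
  expect_error(dose_response_sweep(co$hit_log, orphan), "cover every player")
})

test_that("tau-FA association recovers exact and planted relations", {
  fa <- seq(0.4, 0.6, length.out = 10)
  exact <- tau_fa_association(data.frame(tau = 30 - 50 * fa,
                                         fa_post_right = fa))
  expect_equal(exact$estimate, -1)
  pear <- tau_fa_association(data.frame(tau = 30 - 50 * fa,
                                        fa_post_right = fa),
                             method = "pearson")
  expect_equal(pear$estimate, -1)
  expect_equal(pear$method, "pearson")
  # independence: mean rho near zero over replicate draws
  rhos <- vapply(1:200, function(s) {
    withr::with_seed(s + 2000, {
      d <- data.frame(tau = rnorm(13, 5, 2),
                      fa_post_right = runif(13, 0.4, 0.6))
    })
    tau_fa_association(d)$estimate
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
  # planted negative slope at n = 13, moderate noise: sign recovered
  hits <- vapply(1:100, function(s) {
    co <- simulate_cohort(cohort_config(n_players = 13, tau_n = 13,
                                        hits_per_player_mean = 120,
                                        seed = s))
    tau_fa_association(co$outcomes)$estimate < 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
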