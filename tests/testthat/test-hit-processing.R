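test_that("angle canonicalization wraps azimuth and folds elevation", {
  expect_equal(canonicalize_angles(190, 0)$azimuth, -170)
  expect_equal(canonicalize_angles(-180, 0)$azimuth, -180)
  expect_equal(canonicalize_angles(180, 0)$azimuth, -180)
  # crossing the pole flips to the opposite azimuth
  over <- canonicalize_angles(0, 100)
  expect_equal(over$elevation, 80)
  expect_equal(over$azimuth, -180)
  withr::with_seed(11, {
    az <- runif(500, -1000, 1000)
    el <- runif(500, -1000, 1000)
    ang <- canonicalize_angles(az, el)
    expect_true(all(ang$azimuth >= -180 & ang$azimuth < 180))
    expect_true(all(ang$elevation >= -90 & ang$elevation <= 90))
  })
  expect_error(canonicalize_angles(NaN, 0), "finite")
})

test_that("bin_index follows the stated convention at the corners", {
  expect_identical(bin_index(-180, -90), 0L)
  # +90 azimuth (right side), 0 elevation: bin [90,100) x [0,10)
  expect_identical(bin_index(90, 0), 27L * 18L + 9L)
  expect_identical(bin_index(90, 0), 495L)
  # closed top elevation edge goes to the top bin
  expect_identical(bin_index(-180, 90), 17L)
  expect_error(bin_index(Inf, 0), "finite")
})

test_that("bin_index agrees with the rectangle-enumeration oracle", {
  withr::with_seed(42, {
    az <- runif(10000, -180, 180 - 1e-9)
    el <- runif(10000, -90, 90)
  })
  expect_identical(bin_index(az, el), oracle_bin_index(az, el))
  # and at a coarser resolution
  withr::with_seed(43, {
    az <- runif(1000, -180, 180 - 1e-9)
    el <- runif(1000, -90, 90)
  })
  expect_identical(bin_index(az, el, bin_width = 30),
                   oracle_bin_index(az, el, bin_width = 30))
})

test_that("fingerprints are unit-sum 648-vectors matching per-hit accumulation", {
  one <- tibble::tibble(azimuth_deg = 37, elevation_deg = -12,
                        linear_g = 20, rotational_rad_s2 = 1500)
  fp <- compute_fingerprint(one)
  expect_length(fp, 648)
  expect_equal(sum(fp), 1)
  expect_equal(sum(fp == 1), 1)
  expect_equal(which(as.numeric(fp) == 1) - 1L, bin_index(37, -12))

  hits <- random_hits(1000, seed = 7)
  fp <- compute_fingerprint(hits)
  acc <- numeric(648)
  for (h in seq_len(nrow(hits))) {
    b <- bin_index(hits$azimuth_deg[h], hits$elevation_deg[h]) + 1L
    acc[b] <- acc[b] + 1
  }
  expect_equal(as.numeric(fp), acc / 1000)
  expect_equal(sum(fp), 1, tolerance = 1e-12)
  expect_true(all(fp >= 0))

  empty <- hits[0, ]
  fp0 <- compute_fingerprint(empty)
  expect_equal(attr(fp0, "n_hits"), 0)
  expect_true(all(fp0 == 0))
})

test_that("fingerprint_matrix rows are per-player fingerprints incl. zero-hit players", {
  hits <- random_hits(400, seed = 3)
  X <- fingerprint_matrix(hits, players = c(sort(unique(hits$player_id)),
                                            "GHOST"))
  expect_equal(ncol(X), 648)
  expect_true(all(abs(rowSums(X)[rownames(X) != "GHOST"] - 1) < 1e-12))
  expect_equal(unname(rowSums(X)["GHOST"]), 0)
  p1 <- sort(unique(hits$player_id))[1]
  expect_equal(X[p1, ],
               as.numeric(compute_fingerprint(hits[hits$player_id == p1, ])))
})

test_that("hit-log summaries match direct recomputation", {
  toy <- tibble::tibble(
    player_id = "P1",
    session_type = c("practice", "practice", "game", "meeting"),
    linear_g = c(10, 20, 30, 40),
    rotational_rad_s2 = c(1000, 2000, 3000, 4000))
  s <- summarize_hit_log(toy)
  expect_equal(s$percent[s$session_type == "practice"], 50)
  expect_equal(s$percent[s$session_type == "game"], 25)
  expect_equal(s$percent[s$session_type == "other"], 25)

  prac <- tibble::tibble(player_id = "P1", session_type = "practice",
                         linear_g = c(10, 20, 30),
                         rotational_rad_s2 = c(1, 2, 3))
  s2 <- summarize_hit_log(prac)
  expect_equal(s2$linear_median[s2$session_type == "practice"], 20)
  expect_equal(s2$linear_mean[s2$session_type == "practice"], 20)

  hits <- random_hits(500, seed = 12)
  s3 <- summarize_hit_log(hits)
  ora <- oracle_summarize(hits)
  for (grp in c("practice", "game", "other")) {
    row <- s3[s3$session_type == grp, ]
    expect_equal(row$n_hits, unname(ora[[grp]]["n"]))
    expect_equal(row$percent, unname(ora[[grp]]["pct"]))
    expect_equal(row$rotational_median, unname(ora[[grp]]["rot_med"]))
    expect_equal(row$linear_mean, unname(ora[[grp]]["lin_mean"]))
  }
})

test_that("cohort SD threshold is pooled mean + sample SD", {
  toy <- tibble::tibble(player_id = "P1", linear_g = c(1, 2, 3),
                        rotational_rad_s2 = c(1, 2, 3))
  expect_equal(cohort_sd_threshold(toy, "linear")$threshold, 2 + 1)
  flat <- tibble::tibble(player_id = "P1", linear_g = rep(5, 4),
                         rotational_rad_s2 = rep(5, 4))
  expect_equal(cohort_sd_threshold(flat, "linear")$threshold, 5)
  hits <- random_hits(300, seed = 5)
  th <- cohort_sd_threshold(hits, "rotational")
  x <- hits$rotational_rad_s2
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  expect_equal(th$threshold, m + s)
  one <- hits[1, ]
  expect_error(cohort_sd_threshold(one, "linear"), "at least 2")
})

test_that("suprathreshold counting is inclusive and monotone", {
  toy <- tibble::tibble(player_id = "P1", linear_g = c(10, 20, 30),
                        rotational_rad_s2 = c(10, 20, 30))
  expect_equal(count_suprathreshold(toy, "linear", 25), 1)
  expect_equal(count_suprathreshold(toy, "linear", 20), 2)  # boundary counts
  expect_equal(count_suprathreshold(toy, "linear", 0), 3)
  hits <- random_hits(800, seed = 9)
  withr::with_seed(10, thr <- runif(1000, 0, 200))
  got <- vapply(thr, function(t) count_suprathreshold(hits, "linear", t),
                integer(1))
  want <- vapply(thr, function(t) oracle_count_supra(hits$linear_g, t),
                 integer(1))
  expect_identical(got, want)
  ord <- order(thr)
  expect_true(all(diff(got[ord]) <= 0))
})

test_that("exclusive-threshold counts partition the log", {
  hit <- tibble::tibble(player_id = "P1", linear_g = 60,
                        rotational_rad_s2 = 3000)
  expect_equal(count_exclusive(hit, 2782, 50, "rot_only"), 0)  # exceeds both
  hit2 <- tibble::tibble(player_id = "P1", linear_g = 20,
                         rotational_rad_s2 = 3000)
  expect_equal(count_exclusive(hit2, 2782, 50, "rot_only"), 1)
  hits <- random_hits(1000, seed = 21)
  rt <- 2500
  lt <- 40
  cells <- vapply(c("rot_only", "lin_only", "both", "neither"),
                  function(m) count_exclusive(hits, rt, lt, m), integer(1))
  expect_equal(sum(cells), nrow(hits))
  expect_equal(unname(cells),
               unname(oracle_exclusive(hits$rotational_rad_s2,
                                       hits$linear_g, rt, lt)))
  pp <- exclusive_counts(hits, rt, lt)
  expect_equal(sum(pp$rot_only + pp$lin_only + pp$both + pp$neither),
               nrow(hits))
})

test_that("decile thresholds follow the linear-interpolation quantile rule", {
  hits <- tibble::tibble(player_id = "P1", linear_g = 1:100,
                         rotational_rad_s2 = 1:100)
  th <- decile_thresholds(hits, "linear")
  expect_length(th, 9)
  expect_equal(unname(th), oracle_decile(1:100))
  expect_true(all(diff(th) >= 0))
  flat <- tibble::tibble(player_id = "P1", linear_g = rep(7, 12),
                         rotational_rad_s2 = rep(7, 12))
  expect_true(all(decile_thresholds(flat, "linear") == 7))
  rnd <- random_hits(537, seed = 2)
  expect_equal(unname(decile_thresholds(rnd, "rotational")),
               oracle_decile(rnd$rotational_rad_s2))
  # suprathreshold counts across the sweep are non-increasing
  counts <- vapply(decile_thresholds(rnd, "rotational"),
                   function(t) count_suprathreshold(rnd, "rotational", t),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(decile_thresholds(rnd[1:5, ], "linear"), "at least 10")
})

test_that("hit logs round-trip through CSV", {
  hits <- random_hits(50, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hit_log(hits, path)
  back <- read_hit_log(path)
  expect_equal(as.data.frame(back), as.data.frame(hits))
})
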