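#' Planted fingerprint-to-laterality weight maps
#'
#' `default_fingerprint_weights()` is a lateral-contrast map: +0.5 on
#' bins right of the mid-sagittal plane and -0.5 left of it (rear
#' hemisphere of the head, where impacts concentrate), so the planted
#' laterality target is proportional to the right-minus-left share of a
#' player's hits. `null_fingerprint_weights()` is the all-zero map (no
#' fingerprint-laterality relation).
#'
#' @param bin_width Fingerprint bin width in degrees (default 10, i.e.
#'   648 bins).
#' @return A numeric weight vector, one entry per bin.
#' @export
default_fingerprint_weights <- function(bin_width = 10) {
  bins <- fingerprint_bins(bin_width)
  az <- bins$azimuth_center
  ifelse(abs(az) < 90, 0.5 * sign(az), 0)
}

#' @rdname default_fingerprint_weights
#' @export
null_fingerprint_weights <- function(bin_width = 10) {
  rep(0, (360 / bin_width) * (180 / bin_width))
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a
#' season-long collegiate-football cohort wearing helmet accelerometers,
#' with right-skewed impact magnitudes, impacts concentrated near the
#' mid-sagittal plane, a planted negative dose-response between
#' suprathreshold rotational hit counts and right-hemisphere FA change, a
#' planted linear fingerprint-to-laterality map, and a planted negative
#' tau-FA relation in a concussed subgroup.
#'
#' @param n_players Cohort size (default 38).
#' @param hits_per_player_mean Mean hits per player over the season
#'   (default 503, i.e. ~19,000 hits across 38 players).
#' @param hits_per_player_dispersion Negative-binomial size parameter for
#'   per-player hit counts (default 2.5; players differ widely in
#'   exposure). `Inf` gives Poisson counts.
#' @param session_mix Named probabilities for practice/game/other
#'   (default .59/.37/.04).
#' @param linear_logmean,linear_logsd Lognormal parameters of linear
#'   acceleration in g (defaults reproduce a median of ~25 g and mean of
#'   ~31.5 g).
#' @param rotational_logmean,rotational_logsd Lognormal parameters of
#'   rotational acceleration in rad/s^2 (median ~1600, mean ~1950).
#' @param azimuth_concentration Angular clustering strength near the 0
#'   and 180 degree azimuth clusters; the within-cluster spread is
#'   `60 / azimuth_concentration` degrees (default 3, i.e. 20 degrees).
#' @param elevation_sd Within-player elevation spread in degrees
#'   (default 20).
#' @param dose_response_beta FA units of right-hemisphere change per
#'   suprathreshold rotational hit; values <= 0 plant integrity loss
#'   proportional to exposure (default -1e-3).
#' @param fingerprint_weights Planted fingerprint-to-laterality weight
#'   vector w*, one entry per bin ([default_fingerprint_weights()];
#'   [null_fingerprint_weights()] for a null cohort).
#' @param lat_noise_sd Noise SD on the planted laterality target
#'   (default 0.14, putting the planted map's explainable variance near
#'   r^2 ~ 0.6).
#' @param noise_sd_fa Gaussian noise SD on FA change scores (default
#'   0.01).
#' @param fa_pre_mean,fa_pre_sd Preseason ROI FA distribution (defaults
#'   0.55, 0.02 — typical midbrain corticospinal-tract values).
#' @param tau_n Size of the concussed subgroup with serum tau (default
#'   13).
#' @param tau_baseline,tau_slope,tau_noise_sd Tau model: `tau = baseline
#'   + slope x postseason right FA + noise`, in pg/mL (defaults 30, -50,
#'   2.9, putting the planted association near r ~ -0.6).
#' @param bin_width Fingerprint bin width in degrees (default 10).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_players = 38,
                          hits_per_player_mean = 503,
                          hits_per_player_dispersion = 2.5,
                          session_mix = c(practice = 0.59, game = 0.37,
                                          other = 0.04),
                          linear_logmean = log(25), linear_logsd = 0.68,
                          rotational_logmean = log(1600),
                          rotational_logsd = 0.63,
                          azimuth_concentration = 3, elevation_sd = 20,
                          dose_response_beta = -1e-3,
                          fingerprint_weights =
                            default_fingerprint_weights(bin_width),
                          lat_noise_sd = 0.14,
                          noise_sd_fa = 0.01,
                          fa_pre_mean = 0.55, fa_pre_sd = 0.02,
                          tau_n = 13, tau_baseline = 30, tau_slope = -50,
                          tau_noise_sd = 2.9,
                          bin_width = 10, seed = 1L) {
  cfg <- list(n_players = n_players,
              hits_per_player_mean = hits_per_player_mean,
              hits_per_player_dispersion = hits_per_player_dispersion,
              session_mix = session_mix,
              linear_logmean = linear_logmean, linear_logsd = linear_logsd,
              rotational_logmean = rotational_logmean,
              rotational_logsd = rotational_logsd,
              azimuth_concentration = azimuth_concentration,
              elevation_sd = elevation_sd,
              dose_response_beta = dose_response_beta,
              fingerprint_weights = fingerprint_weights,
              lat_noise_sd = lat_noise_sd, noise_sd_fa = noise_sd_fa,
              fa_pre_mean = fa_pre_mean, fa_pre_sd = fa_pre_sd,
              tau_n = tau_n, tau_baseline = tau_baseline,
              tau_slope = tau_slope, tau_noise_sd = tau_noise_sd,
              bin_width = bin_width, seed = as.integer(seed))
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (is.numeric(v) && any(is.na(v) | is.nan(v))) {
      abort(sprintf("cohort_config field '%s' contains non-finite values",
                    nm))
    }
  }
  n_bins <- (360 / bin_width) * (180 / bin_width)
  stopifnot(cfg$n_players >= 3,
            cfg$linear_logsd > 0, cfg$rotational_logsd > 0,
            cfg$noise_sd_fa >= 0, cfg$lat_noise_sd >= 0,
            cfg$azimuth_concentration > 0,
            cfg$hits_per_player_mean >= 0,
            cfg$hits_per_player_dispersion > 0,
            abs(sum(cfg$session_mix) - 1) < 1e-8)
  if (length(cfg$fingerprint_weights) != n_bins) {
    abort(sprintf(
      "fingerprint_weights must have length %d for bin_width = %g (got %d)",
      n_bins, bin_width, length(cfg$fingerprint_weights)))
  }
  structure(cfg, class = "cohort_config")
}

#' Simulate a synthetic head-impact cohort with planted effects
#'
#' Draws a full season of per-hit telemetry and pre/post FA outcomes
#' under the generative model described in [cohort_config()] and the
#' methods vignette:
#' * per-player hit counts are negative-binomial; impact magnitudes are
#'   lognormal; azimuth follows a two-cluster mixture at 0/180 degrees
#'   with player-level front/back preference and lateral offset;
#' * right-hemisphere FA change is `dose_response_beta` times the number
#'   of hits with rotational acceleration at or above the cohort
#'   mean + 1 SD, plus Gaussian noise;
#' * a laterality target is drawn as `<fingerprint, fingerprint_weights>`
#'   plus noise (clamped to \[-0.8, 0.8\]), and the left-hemisphere change
#'   is back-solved so [laterality_index()] reproduces the target
#'   exactly;
#' * serum tau is generated for a concussed subgroup as a negative linear
#'   function of postseason right FA.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort`: `hit_log` (tibble, one
#'   row per impact), `outcomes` (tibble, one row per player),
#'   `fingerprints` (players x bins matrix), `ground_truth` (the exact
#'   config used).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n_players
    ids <- sprintf("P%03d", seq_len(n))
    disp <- config$hits_per_player_dispersion
    n_hits <- if (is.infinite(disp)) {
      rpois(n, config$hits_per_player_mean)
    } else {
      rnbinom(n, size = disp, mu = config$hits_per_player_mean)
    }
    # player-level heterogeneity: front/back mix, lateral bias, stance
    p_back <- rbeta(n, 3, 3)
    az_offset <- rnorm(n, 0, 25)
    el_offset <- rnorm(n, 0, 12)
    az_sd <- 60 / config$azimuth_concentration
    hit_log <- purrr::map_dfr(seq_len(n), function(i) {
      m <- n_hits[i]
      if (m == 0) return(NULL)
      centers <- ifelse(runif(m) < p_back[i], 0, 180)
      ang <- canonicalize_angles(
        centers + az_offset[i] + rnorm(m, 0, az_sd),
        el_offset[i] + rnorm(m, 0, config$elevation_sd))
      tibble(
        player_id = ids[i],
        session_type = sample(names(config$session_mix), m, replace = TRUE,
                              prob = config$session_mix),
        linear_g = rlnorm(m, config$linear_logmean, config$linear_logsd),
        rotational_rad_s2 = rlnorm(m, config$rotational_logmean,
                                   config$rotational_logsd),
        azimuth_deg = ang$azimuth,
        elevation_deg = ang$elevation
      )
    })
    if (nrow(hit_log) == 0) {
      abort("simulated cohort has no hits; increase hits_per_player_mean")
    }
    X <- fingerprint_matrix(hit_log, players = ids,
                            bin_width = config$bin_width)
    # planted dose-response on suprathreshold rotational exposure
    rot_thr <- cohort_sd_threshold(hit_log, "rotational")$threshold
    supra <- suprathreshold_counts(hit_log, "rotational", rot_thr,
                                   players = ids)$n_supra
    delta_right <- config$dose_response_beta * supra +
      rnorm(n, 0, config$noise_sd_fa)
    # planted fingerprint -> laterality map; left delta back-solved
    lat_target <- drop(X %*% config$fingerprint_weights) +
      rnorm(n, 0, config$lat_noise_sd)
    lat_target <- pmin(pmax(lat_target, -0.8), 0.8)
    delta_left <- ifelse(
      delta_right == 0, 0,
      ifelse(delta_right < 0,
             delta_right * (1 + lat_target) / (1 - lat_target),
             delta_right * (1 - lat_target) / (1 + lat_target)))
    fa_pre_right <- rnorm(n, config$fa_pre_mean, config$fa_pre_sd)
    fa_pre_left <- rnorm(n, config$fa_pre_mean, config$fa_pre_sd)
    fa_post_right <- pmin(pmax(fa_pre_right + delta_right, 0), 1)
    fa_post_left <- pmin(pmax(fa_pre_left + delta_left, 0), 1)
    # keep change scores consistent with the (rarely) clipped FA values
    delta_right <- fa_post_right - fa_pre_right
    delta_left <- fa_post_left - fa_pre_left
    concussed <- seq_len(n) %in%
      sample.int(n, size = min(config$tau_n, n))
    tau <- ifelse(
      concussed,
      config$tau_baseline + config$tau_slope * fa_post_right +
        rnorm(n, 0, config$tau_noise_sd),
      NA_real_)
    outcomes <- tibble(
      player_id = ids, group = "RSHI", concussed = concussed,
      n_hits = as.integer(n_hits), n_supra_rotational = supra,
      fa_pre_left = fa_pre_left, fa_post_left = fa_post_left,
      fa_pre_right = fa_pre_right, fa_post_right = fa_post_right,
      delta_left = delta_left, delta_right = delta_right,
      laterality = laterality_index(delta_right, delta_left),
      tau = tau)
    structure(list(hit_log = hit_log, outcomes = outcomes,
                   fingerprints = X, ground_truth = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$outcomes), " players, ",
      nrow(x$hit_log), " hits, seed ", x$ground_truth$seed, "\n", sep = "")
  cat("  planted: beta = ", x$ground_truth$dose_response_beta,
      " FA/hit, |w*| > 0 in ",
      sum(x$ground_truth$fingerprint_weights != 0), " bins, tau slope = ",
      x$ground_truth$tau_slope, " pg/mL per FA\n", sep = "")
  invisible(x)
}

#' Simulate a toy FA volume and ROI mask pair
#'
#' Builds a scalar FA field that equals `fa_inside` on the voxels of a
#' simple geometric ROI and `fa_outside` elsewhere, plus optional
#' Gaussian noise (clamped to \[0, 1\]) — a minimal fixture for testing
#' mask intersection, hemisphere splitting and mean-FA extraction.
#'
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param roi_spec `NULL` for an empty mask, or a list with `shape`
#'   (`"box"` or `"ellipsoid"`), `center` (1-based voxel coordinates) and
#'   `radii` (half-extents in voxels).
#' @param fa_inside,fa_outside FA values in \[0, 1\].
#' @param noise_sd Gaussian noise SD added to the field (default 0).
#' @param seed Integer seed.
#' @return A list with `volume` (an [fa_volume()]) and `mask` (a
#'   [roi_mask()]).
#' @export
simulate_fa_volumes <- function(grid_shape, roi_spec,
                                fa_inside = 0.5, fa_outside = 0.2,
                                noise_sd = 0, seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            fa_inside >= 0, fa_inside <= 1,
            fa_outside >= 0, fa_outside <= 1, noise_sd >= 0)
  mask_arr <- array(0, dim = grid_shape)
  if (!is.null(roi_spec)) {
    stopifnot(is.list(roi_spec),
              all(c("shape", "center", "radii") %in% names(roi_spec)))
    ctr <- roi_spec$center
    rad <- roi_spec$radii
    stopifnot(length(ctr) == 3, length(rad) == 3, all(rad >= 0))
    if (any(ctr - rad < 1) || any(ctr + rad > grid_shape)) {
      abort("grid too small to contain the requested ROI")
    }
    i <- slice.index(mask_arr, 1)
    j <- slice.index(mask_arr, 2)
    k <- slice.index(mask_arr, 3)
    inside <- switch(
      match.arg(roi_spec$shape, c("box", "ellipsoid")),
      box = abs(i - ctr[1]) <= rad[1] & abs(j - ctr[2]) <= rad[2] &
        abs(k - ctr[3]) <= rad[3],
      ellipsoid = ((i - ctr[1]) / max(rad[1], .5))^2 +
        ((j - ctr[2]) / max(rad[2], .5))^2 +
        ((k - ctr[3]) / max(rad[3], .5))^2 <= 1)
    mask_arr[inside] <- 1
  }
  vol_arr <- array(fa_outside, dim = grid_shape)
  vol_arr[mask_arr == 1] <- fa_inside
  if (noise_sd > 0) {
    vol_arr <- withr::with_seed(seed, {
      pmin(pmax(vol_arr + array(rnorm(length(vol_arr), 0, noise_sd),
                                dim = grid_shape), 0), 1)
    })
  }
  aff <- default_affine(grid_shape)
  list(volume = fa_volume(vol_arr, affine = aff, label = "synthetic FA"),
       mask = roi_mask(mask_arr, affine = aff, label = "synthetic ROI"))
}

#' Write a synthetic cohort to disk
#'
#' Writes the hit log and outcome table as CSV and the planted ground
#' truth as a JSON sidecar.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_hit_log(cohort$hit_log, file.path(dir, "hit_log.csv"))
  write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
            row.names = FALSE)
  jsonlite::write_json(unclass(cohort$ground_truth),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
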