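#' @keywords internal
#' @noRd
metric_column <- function(metric = c("rotational", "linear")) {
  metric <- match.arg(metric)
  c(rotational = "rotational_rad_s2", linear = "linear_g")[[metric]]
}

#' @keywords internal
#' @noRd
assert_hit_log <- function(hits, require_angles = FALSE) {
  needed <- c("player_id", "linear_g", "rotational_rad_s2")
  if (require_angles) needed <- c(needed, "azimuth_deg", "elevation_deg")
  missing_cols <- setdiff(needed, names(hits))
  if (length(missing_cols) > 0) {
    abort(paste0("hit log is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  invisible(hits)
}

#' Canonicalize impact angles
#'
#' Wraps azimuth into \[-180, 180) degrees and folds elevation into
#' \[-90, 90\] by spherical reflection (an elevation beyond the pole flips
#' to the opposite azimuth). The angular convention follows helmet
#' telemetry: 0 deg azimuth at the back of the head, +90 deg the right
#' side, -90 deg the left side; elevation -90 deg points down, +90 deg up.
#'
#' @param azimuth,elevation Numeric vectors of angles in degrees.
#' @return A list with components `azimuth` and `elevation`.
#' @examples
#' canonicalize_angles(190, 0)   # wraps to -170
#' canonicalize_angles(0, 100)   # folds over the pole to azimuth 180
#' @export
canonicalize_angles <- function(azimuth, elevation) {
  if (any(!is.finite(azimuth)) || any(!is.finite(elevation))) {
    abort("angles must be finite")
  }
  el <- ((elevation + 180) %% 360) - 180
  over <- el > 90
  under <- el < -90
  azimuth <- ifelse(over | under, azimuth + 180, azimuth)
  el[over] <- 180 - el[over]
  el[under] <- -180 - el[under]
  az <- ((azimuth + 180) %% 360) - 180
  list(azimuth = az, elevation = el)
}

#' Spherical bin index for an impact location
#'
#' Assigns each (azimuth, elevation) pair to one rectangular bin on the
#' sphere. With the default 10-degree bins this yields 36 azimuth x 18
#' elevation = 648 bins. Bins are half-open `[edge, edge + width)`; the top
#' elevation edge (+90) is closed so every canonical angle has a bin. The
#' flattening is azimuth-major: `index = azimuth_bin * n_elevation_bins +
#' elevation_bin`, zero-based, so `(-180, -90)` maps to bin 0.
#'
#' @inheritParams canonicalize_angles
#' @param bin_width Bin width in degrees; must divide both 360 and 180
#'   (default 10).
#' @return Integer vector of zero-based bin indices in
#'   `[0, (360/bin_width) * (180/bin_width) - 1]`.
#' @examples
#' bin_index(-180, -90)  # 0
#' bin_index(90, 0)      # 495: right side of the head, horizontal
#' @export
bin_index <- function(azimuth, elevation, bin_width = 10) {
  stopifnot(length(bin_width) == 1, bin_width > 0,
            360 %% bin_width == 0, 180 %% bin_width == 0)
  ang <- canonicalize_angles(azimuth, elevation)
  n_el <- 180 / bin_width
  az_bin <- floor((ang$azimuth + 180) / bin_width)
  el_bin <- pmin(floor((ang$elevation + 90) / bin_width), n_el - 1)
  as.integer(az_bin * n_el + el_bin)
}

#' Bin scheme metadata for the spatial fingerprint
#'
#' @param bin_width Bin width in degrees (default 10, giving 648 bins).
#' @return A tibble with one row per bin: zero-based `bin`, azimuth and
#'   elevation edges, and bin centers. Ordered by `bin`.
#' @export
fingerprint_bins <- function(bin_width = 10) {
  n_az <- 360 / bin_width
  n_el <- 180 / bin_width
  az_lo <- rep(seq(-180, 180 - bin_width, by = bin_width), each = n_el)
  el_lo <- rep(seq(-90, 90 - bin_width, by = bin_width), times = n_az)
  tibble(
    bin = seq_len(n_az * n_el) - 1L,
    azimuth_lo = az_lo,
    azimuth_hi = az_lo + bin_width,
    elevation_lo = el_lo,
    elevation_hi = el_lo + bin_width,
    azimuth_center = az_lo + bin_width / 2,
    elevation_center = el_lo + bin_width / 2
  )
}

#' Spatial fingerprint of a player's head impacts
#'
#' Histograms impact locations over the spherical bin scheme of
#' [bin_index()] and normalizes by the number of hits, giving the
#' proportion of a player's impacts in each bin (entries sum to 1). A
#' player with no hits gets an all-zero vector with `n_hits = 0`.
#'
#' @param hits A data frame of hits with `azimuth_deg` and `elevation_deg`
#'   columns (one player's hits).
#' @param bin_width Bin width in degrees (default 10, i.e. 648 bins).
#' @param rotational_min,linear_min Optional acceleration filters applied
#'   before binning (keep hits with metric `>=` the bound). Default: all
#'   hits are used.
#' @return A numeric vector of length `(360/bin_width) * (180/bin_width)`
#'   of class `impact_fingerprint`, with attributes `n_hits` and
#'   `bin_width`. Position `i` corresponds to zero-based bin `i - 1`.
#' @export
compute_fingerprint <- function(hits, bin_width = 10,
                                rotational_min = NULL, linear_min = NULL) {
  n_bins <- as.integer((360 / bin_width) * (180 / bin_width))
  if (!is.null(rotational_min)) {
    hits <- hits[hits$rotational_rad_s2 >= rotational_min, , drop = FALSE]
  }
  if (!is.null(linear_min)) {
    hits <- hits[hits$linear_g >= linear_min, , drop = FALSE]
  }
  n_hits <- nrow(hits)
  if (n_hits == 0) {
    w <- numeric(n_bins)
  } else {
    idx <- bin_index(hits$azimuth_deg, hits$elevation_deg, bin_width)
    w <- tabulate(idx + 1L, nbins = n_bins) / n_hits
  }
  structure(w, n_hits = n_hits, bin_width = bin_width,
            class = "impact_fingerprint")
}

#' @export
print.impact_fingerprint <- function(x, ...) {
  cat("<impact_fingerprint> ", length(x), " bins (",
      attr(x, "bin_width"), " deg), ", attr(x, "n_hits"), " hits, ",
      sum(x > 0), " occupied\n", sep = "")
  invisible(x)
}

#' Players-by-bins fingerprint matrix
#'
#' @param hit_log A hit-log data frame (see [read_hit_log()] for the
#'   schema) covering one or more players.
#' @param players Optional character vector fixing row order and including
#'   players with zero logged hits (all-zero rows). Defaults to the sorted
#'   set of players present in the log.
#' @inheritParams compute_fingerprint
#' @return A numeric matrix (players x bins) with `rownames` the player
#'   ids and attribute `n_hits` (named per-player hit counts). Rows of
#'   players with at least one hit sum to 1.
#' @export
fingerprint_matrix <- function(hit_log, players = NULL, bin_width = 10,
                               rotational_min = NULL, linear_min = NULL) {
  assert_hit_log(hit_log, require_angles = TRUE)
  if (is.null(players)) players <- sort(unique(hit_log$player_id))
  players <- as.character(players)
  n_bins <- as.integer((360 / bin_width) * (180 / bin_width))
  X <- matrix(0, nrow = length(players), ncol = n_bins,
              dimnames = list(players, NULL))
  n_hits <- stats::setNames(integer(length(players)), players)
  split_hits <- split(hit_log, as.character(hit_log$player_id))
  for (p in intersect(players, names(split_hits))) {
    fp <- compute_fingerprint(split_hits[[p]], bin_width = bin_width,
                              rotational_min = rotational_min,
                              linear_min = linear_min)
    X[p, ] <- as.numeric(fp)
    n_hits[p] <- attr(fp, "n_hits")
  }
  attr(X, "n_hits") <- n_hits
  attr(X, "bin_width") <- bin_width
  X
}

#' Per-session-type summary of a hit log
#'
#' Tabulates hit counts, percentages of the total, and the median and mean
#' of linear and rotational acceleration by session type. Session labels
#' other than "practice" or "game" are grouped as "other" (scrimmages,
#' meetings, ...).
#'
#' @param hit_log A hit-log data frame with at least `session_type`,
#'   `linear_g` and `rotational_rad_s2` columns.
#' @return A tibble with one row per session type (practice, game, other,
#'   always all three) plus a `total` row: `n_hits`, `percent`, and
#'   median/mean of each acceleration. Medians/means of empty groups are
#'   `NA`.
#' @export
summarize_hit_log <- function(hit_log) {
  stopifnot(all(c("session_type", "linear_g", "rotational_rad_s2") %in%
                  names(hit_log)))
  lev <- c("practice", "game", "other")
  session <- tolower(as.character(hit_log$session_type))
  session[!session %in% c("practice", "game")] <- "other"
  session <- factor(session, levels = lev)
  total <- nrow(hit_log)
  safe <- function(f, x) if (length(x) == 0) NA_real_ else f(x)
  per <- tibble(session_type = session,
                linear_g = hit_log$linear_g,
                rotational_rad_s2 = hit_log$rotational_rad_s2) %>%
    group_by(.data$session_type, .drop = FALSE) %>%
    summarise(
      n_hits = dplyr::n(),
      linear_median = safe(median, .data$linear_g),
      linear_mean = safe(mean, .data$linear_g),
      rotational_median = safe(median, .data$rotational_rad_s2),
      rotational_mean = safe(mean, .data$rotational_rad_s2),
      .groups = "drop"
    ) %>%
    mutate(percent = if (total > 0) 100 * .data$n_hits / total else NA_real_,
           session_type = as.character(.data$session_type))
  tot_row <- tibble(
    session_type = "total",
    n_hits = total,
    linear_median = safe(median, hit_log$linear_g),
    linear_mean = safe(mean, hit_log$linear_g),
    rotational_median = safe(median, hit_log$rotational_rad_s2),
    rotational_mean = safe(mean, hit_log$rotational_rad_s2),
    percent = if (total > 0) 100 else NA_real_
  )
  bind_rows(per, tot_row) %>%
    select("session_type", "n_hits", "percent", "linear_median",
           "linear_mean", "rotational_median", "rotational_mean")
}

#' Cohort-derived force threshold (mean + 1 SD)
#'
#' Pools all hits across the cohort and returns the mean plus one sample
#' standard deviation (n - 1 denominator) of the chosen acceleration
#' metric — the objective exposure threshold used to define
#' "suprathreshold" hits.
#'
#' @param hit_log A hit-log data frame.
#' @param metric `"rotational"` (rad/s^2) or `"linear"` (g).
#' @param n_sd Number of standard deviations above the mean (default 1).
#' @return A one-row tibble: `metric`, `n_hits`, `mean`, `sd`, `threshold`,
#'   `provenance`.
#' @export
cohort_sd_threshold <- function(hit_log, metric = c("rotational", "linear"),
                                n_sd = 1) {
  metric <- match.arg(metric)
  assert_hit_log(hit_log)
  x <- hit_log[[metric_column(metric)]]
  if (length(x) < 2) abort("need at least 2 hits to compute a cohort SD threshold")
  m <- mean(x)
  s <- sd(x)
  tibble(metric = metric, n_hits = length(x), mean = m, sd = s,
         threshold = m + n_sd * s,
         provenance = sprintf("cohort mean + %g SD", n_sd))
}

#' Count suprathreshold hits
#'
#' Counts hits whose acceleration is at or above a threshold. The boundary
#' is inclusive (`>=`) by default: a hit exactly at the threshold counts
#' as exposure.
#'
#' @param hits A data frame of hits (typically one player's).
#' @param metric `"rotational"` or `"linear"`.
#' @param threshold Positive threshold in the metric's units.
#' @param inclusive Count hits `>=` the threshold (default) or strictly
#'   `>`.
#' @return An integer count.
#' @export
count_suprathreshold <- function(hits, metric = c("rotational", "linear"),
                                 threshold, inclusive = TRUE) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  x <- hits[[metric_column(metric)]]
  if (inclusive) sum(x >= threshold) else sum(x > threshold)
}

#' Per-player suprathreshold hit counts
#'
#' @inheritParams count_suprathreshold
#' @param hit_log A hit-log data frame covering one or more players.
#' @param players Optional player ids fixing the output rows (players
#'   absent from the log get a zero count).
#' @return A tibble with `player_id`, `n_hits` (all logged hits) and
#'   `n_supra`.
#' @export
suprathreshold_counts <- function(hit_log, metric = c("rotational", "linear"),
                                  threshold, players = NULL,
                                  inclusive = TRUE) {
  metric <- match.arg(metric)
  assert_hit_log(hit_log)
  if (is.null(players)) players <- sort(unique(hit_log$player_id))
  col <- metric_column(metric)
  cmp <- if (inclusive) `>=` else `>`
  counts <- hit_log %>%
    mutate(player_id = as.character(.data$player_id)) %>%
    group_by(.data$player_id) %>%
    summarise(n_hits = dplyr::n(),
              n_supra = sum(cmp(.data[[col]], threshold)),
              .groups = "drop")
  tibble(player_id = as.character(players)) %>%
    left_join(counts, by = "player_id") %>%
    mutate(n_hits = ifelse(is.na(.data$n_hits), 0L, .data$n_hits),
           n_supra = as.integer(ifelse(is.na(.data$n_supra), 0L,
                                       .data$n_supra)))
}

#' Exclusive-threshold hit counts
#'
#' Counts hits exceeding one force threshold but not the other, isolating
#' the independent contribution of rotational vs linear loading.
#' "Exceeds" is inclusive (`>=`), "does not exceed" is strict (`<`).
#'
#' @param hits A data frame of hits.
#' @param rot_threshold,lin_threshold Positive thresholds (rad/s^2, g).
#' @param mode Which cell of the 2x2 partition to count: `"rot_only"`
#'   (rotational >= threshold and linear < threshold), `"lin_only"`,
#'   `"both"`, or `"neither"`.
#' @return An integer count. The four modes partition the hits:
#'   rot_only + lin_only + both + neither equals the total.
#' @export
count_exclusive <- function(hits, rot_threshold, lin_threshold,
                            mode = c("rot_only", "lin_only", "both",
                                     "neither")) {
  mode <- match.arg(mode)
  stopifnot(rot_threshold > 0, lin_threshold > 0)
  rot <- hits$rotational_rad_s2 >= rot_threshold
  lin <- hits$linear_g >= lin_threshold
  switch(mode,
         rot_only = sum(rot & !lin),
         lin_only = sum(!rot & lin),
         both = sum(rot & lin),
         neither = sum(!rot & !lin))
}

#' Per-player exclusive-threshold counts
#'
#' @inheritParams count_exclusive
#' @inheritParams suprathreshold_counts
#' @return A tibble with `player_id`, `n_hits`, `rot_only`, `lin_only`,
#'   `both`, `neither`.
#' @export
exclusive_counts <- function(hit_log, rot_threshold, lin_threshold,
                             players = NULL) {
  assert_hit_log(hit_log)
  if (is.null(players)) players <- sort(unique(hit_log$player_id))
  counts <- hit_log %>%
    mutate(player_id = as.character(.data$player_id),
           rot = .data$rotational_rad_s2 >= rot_threshold,
           lin = .data$linear_g >= lin_threshold) %>%
    group_by(.data$player_id) %>%
    summarise(n_hits = dplyr::n(),
              rot_only = sum(.data$rot & !.data$lin),
              lin_only = sum(!.data$rot & .data$lin),
              both = sum(.data$rot & .data$lin),
              neither = sum(!.data$rot & !.data$lin),
              .groups = "drop")
  tibble(player_id = as.character(players)) %>%
    left_join(counts, by = "player_id") %>%
    mutate(dplyr::across(c("n_hits", "rot_only", "lin_only", "both",
                           "neither"),
                         ~ as.integer(ifelse(is.na(.x), 0L, .x))))
}

#' Decile thresholds of the pooled acceleration distribution
#'
#' Returns the nine interior decile boundaries (10th, 20th, ..., 90th
#' percentiles) of the pooled metric distribution, for use as a threshold
#' sweep in dose-response analyses. Quantiles use linear interpolation
#' (type 7).
#'
#' @inheritParams cohort_sd_threshold
#' @return A named, non-decreasing numeric vector of 9 thresholds.
#' @export
decile_thresholds <- function(hit_log, metric = c("rotational", "linear")) {
  metric <- match.arg(metric)
  assert_hit_log(hit_log)
  x <- hit_log[[metric_column(metric)]]
  if (length(x) < 10) abort("need at least 10 hits for decile thresholds")
  quantile(x, probs = seq(0.1, 0.9, by = 0.1), type = 7, names = TRUE)
}

#' Read / write hit logs
#'
#' Hit logs are delimited text with columns `player_id`, `session_type`,
#' `linear_g`, `rotational_rad_s2`, `azimuth_deg`, `elevation_deg` — one
#' row per impact.
#'
#' @param path Path to a CSV file.
#' @return `read_hit_log()` returns a tibble; `write_hit_log()` returns
#'   `path` invisibly.
#' @export
read_hit_log <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  assert_hit_log(df, require_angles = TRUE)
  df$player_id <- as.character(df$player_id)
  df
}

#' @rdname read_hit_log
#' @param hit_log A hit-log data frame.
#' @export
write_hit_log <- function(hit_log, path) {
  assert_hit_log(hit_log, require_angles = TRUE)
  write.csv(hit_log, path, row.names = FALSE)
  invisible(path)
}
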