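#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spatial fingerprint as an azimuth-elevation map
#'
#' Tile map of the proportion of hits per spherical bin, in the head
#' coordinate frame (azimuth 0 = back of the head, +90 = right side;
#' elevation +90 = up).
#'
#' @param fingerprint An `impact_fingerprint` (from
#'   [compute_fingerprint()]) or a plain numeric vector of bin
#'   proportions.
#' @param bin_width Bin width in degrees; taken from the fingerprint's
#'   attribute when present.
#' @param log10_scale Color by `log10(proportion)` of occupied bins
#'   (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_fingerprint <- function(fingerprint, bin_width = NULL,
                             log10_scale = FALSE) {
  if (is.null(bin_width)) {
    bin_width <- attr(fingerprint, "bin_width")
    if (is.null(bin_width)) bin_width <- 10
  }
  bins <- fingerprint_bins(bin_width)
  stopifnot(length(fingerprint) == nrow(bins))
  df <- bins %>%
    mutate(value = as.numeric(fingerprint))
  if (log10_scale) {
    df$value <- ifelse(df$value > 0, log10(df$value), NA_real_)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$azimuth_center,
                                   y = .data$elevation_center,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey92") +
    ggplot2::labs(x = "azimuth (deg; 0 = back of head, +90 = right)",
                  y = "elevation (deg)",
                  fill = if (log10_scale) "log10 prop." else "proportion") +
    ggplot2::theme_minimal()
}

#' Plot a dose-response threshold sweep
#'
#' Spearman rho between per-player suprathreshold hit counts and FA
#' change, as a function of the force threshold; points are filled where
#' p < 0.05.
#'
#' @param sweep A tibble from [dose_response_sweep()].
#' @return A ggplot object.
#' @export
plot_dose_response <- function(sweep) {
  stopifnot(all(c("threshold", "rho", "p.value") %in% names(sweep)))
  df <- sweep %>% mutate(significant = .data$p.value < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$rho)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "white")) +
    ggplot2::labs(x = "force threshold", y = "Spearman rho",
                  fill = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' Plot an SVR laterality analysis
#'
#' @param object An `svr_laterality` fit.
#' @param type `"prediction"` (observed vs leave-one-out predicted
#'   laterality), `"null"` (permutation null of r^2 with the observed
#'   value marked), or `"relevance"` (per-bin relevance map with
#'   Bonferroni-significant bins outlined).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot svr_laterality
#' @export
autoplot.svr_laterality <- function(object,
                                    type = c("prediction", "null",
                                             "relevance"), ...) {
  type <- match.arg(type)
  if (type == "prediction") {
    df <- tidy(object)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$observed,
                                       y = .data$predicted)) +
        ggplot2::geom_abline(linetype = 2, color = "grey60") +
        ggplot2::geom_point(size = 2) +
        ggplot2::labs(
          x = "observed laterality index",
          y = "predicted laterality index (leave-one-out)",
          title = sprintf("cross-validated r^2 = %.3f%s", object$r_squared,
                          if (is.na(object$permutation_p)) "" else
                            sprintf(", permutation p = %.4g",
                                    object$permutation_p))) +
        ggplot2::theme_minimal())
  }
  if (type == "null") {
    if (is.null(object$null_r2)) {
      abort("fit has no permutation null; rerun with permute = TRUE")
    }
    df <- tibble(r2 = object$null_r2)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$r2)) +
        ggplot2::geom_histogram(bins = 40, fill = "grey70",
                                color = "white") +
        ggplot2::geom_vline(xintercept = object$r_squared,
                            color = "firebrick", linewidth = 1) +
        ggplot2::labs(x = "null cross-validated r^2", y = "count",
                      title = sprintf("observed r^2 = %.3f vs %d shuffles",
                                      object$r_squared,
                                      length(object$null_r2))) +
        ggplot2::theme_minimal())
  }
  n_bins <- nrow(object$relevance)
  bin_width <- sqrt(360 * 180 / n_bins)
  bins <- fingerprint_bins(bin_width)
  df <- dplyr::bind_cols(bins, object$relevance["relevance"],
                         object$relevance["significant"])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$azimuth_center,
                                   y = .data$elevation_center)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$relevance)) +
    ggplot2::geom_tile(data = df[df$significant, , drop = FALSE],
                       fill = NA, color = "firebrick", linewidth = 0.6) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                  fill = "r^2",
                  title = "per-bin relevance (Bonferroni-significant outlined)") +
    ggplot2::theme_minimal()
}
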