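#' Phase-group histogram of circadian calls
#'
#' Hourly phase-group counts per condition, shaded by light/dark peak.
#'
#' @param object A [call_circadian()] result.
#' @param light_window Hours `c(on, off)` of the light phase.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.rhythm_calls <- function(object, light_window = c(0, 16), ...) {
  g <- phase_groups(object, light_window = light_window)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, fill = .data$peak_light)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "goldenrod2", `FALSE` = "grey25"),
      labels = c(`TRUE` = "light", `FALSE` = "dark"), name = "peak"
    ) +
    ggplot2::labs(x = "phase group (ZT h)", y = "circadian features") +
    ggplot2::theme_minimal()
}

#' Sample ordination plot
#'
#' @param object A [pca_scores()] result.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2, coloured by condition, shaped by
#'   light/dark.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.pca_result <- function(object, ...) {
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * object$explained[i])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$condition,
                               shape = .data$light)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = lab(1), y = lab(2), shape = "light phase") +
    ggplot2::theme_minimal()
}

#' Plot the time course of selected features
#'
#' Replicate means with per-replicate points, one panel per feature,
#' coloured by condition; dark phases shaded.
#'
#' @param exp A [tc_experiment()].
#' @param features Feature ids to show.
#' @param log2p1 Plot on the log2(value + 1) scale (default TRUE).
#' @return A ggplot object.
#' @export
plot_profile <- function(exp, features, log2p1 = TRUE) {
  stopifnot(inherits(exp, "tc_experiment"))
  df <- as_tibble(exp) %>% filter(.data$feature %in% features)
  if (!nrow(df)) abort("no matching features.")
  if (log2p1) df$value <- log2(df$value + 1)
  dark_start <- seq(exp$photoperiod[2], max(df$time_h), by = 24)
  dark <- tibble(
    xmin = dark_start,
    xmax = pmin(dark_start + (24 - diff(exp$photoperiod)), max(df$time_h))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$value,
                                   colour = .data$condition)) +
    ggplot2::geom_rect(
      data = dark, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      fill = "grey90"
    ) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "time after treatment (h)",
                  y = if (log2p1) "log2(abundance + 1)" else "abundance") +
    ggplot2::theme_minimal()
}
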