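#' @method tidy filn_ranking
#' @export
tidy.filn_ranking <- function(x, ...) {
  as_tibble(x)
}

#' @method glance filn_ranking
#' @export
glance.filn_ranking <- function(x, ...) {
  tibble(hemisphere = attr(x, "hemisphere") %||% NA_character_,
         n_areas = nrow(x),
         min_filn = min(x$mean_filn), max_filn = max(x$mean_filn),
         n_min = min(x$n), n_max = max(x$n))
}

#' Plot an fILN hierarchy ranking
#'
#' Areas ordered from lowest (most feedforward) to highest (most feedback)
#' mean fILN, with SEM error bars.
#'
#' @param object A `filn_ranking` from [rank_areas()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot filn_ranking
#' @export
autoplot.filn_ranking <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$area, .data$rank),
                                   y = .data$mean_filn)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_filn - .data$sem,
      ymax = .data$mean_filn + .data$sem), linewidth = 0.3, size = 0.3) +
    ggplot2::labs(x = NULL, y = "fILN",
                  title = paste0("Hierarchy ranking (",
                                 attr(object, "hemisphere") %||% "", ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}

#' Plot hemisphere shares
#'
#' Per-animal ipsi/contra shares with the cohort mean.
#'
#' @param shares Output of [hemisphere_share()].
#' @return A ggplot.
#' @export
plot_hemisphere_share <- function(shares) {
  ggplot2::ggplot(shares, ggplot2::aes(x = .data$hemisphere, y = .data$share)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction of cortical cells") +
    ggplot2::theme_minimal()
}

#' Plot module fractional counts
#'
#' Mean module weights per hemisphere, ranked by decreasing ipsilateral
#' weight.
#'
#' @param mf Output of [module_fraction()].
#' @return A ggplot.
#' @export
plot_module_fraction <- function(mf) {
  means <- mf |>
    group_by(.data$hemisphere, .data$module) |>
    summarise(fraction = mean_na(.data$fraction), sem = sem_na(.data$fraction),
              .groups = "drop")
  ord <- means |>
    filter(.data$hemisphere == "ipsi") |>
    arrange(desc(.data$fraction)) |>
    pull("module")
  means$module <- factor(means$module, levels = ord)
  ggplot2::ggplot(means, ggplot2::aes(x = .data$module, y = .data$fraction,
                                      fill = .data$hemisphere)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$fraction - .data$sem, ymax = .data$fraction + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2,
      linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "fractional count") +
    ggplot2::theme_minimal()
}

#' Plot interhemispheric laminar change
#'
#' Heat-style tile map of the mean contra − ipsi change in laminar fractions
#' per sensory-motor area and layer, marking significant areas.
#'
#' @param lc The `changes` tibble from [laminar_change()].
#' @return A ggplot.
#' @export
plot_laminar_change <- function(lc) {
  ggplot2::ggplot(lc, ggplot2::aes(x = .data$layer, y = .data$area,
                                   fill = .data$mean_change)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(data = filter(lc, .data$direction != "ns"),
                       ggplot2::aes(label = "*"), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "contra - ipsi") +
    ggplot2::theme_minimal()
}
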