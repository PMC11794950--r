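#' @importFrom ggplot2 autoplot
NULL

#' Plot aggregate Tn5 footprint profiles
#'
#' Flank-normalized insertion frequency around the motif center, one line
#' per cell group, faceted by peak subset.
#'
#' @param x A `phr_footprint`.
#' @param smooth Rolling-mean half-width (bp) applied for display only.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_footprint <- function(x, smooth = 5, ...) {
  df <- x$profile |>
    dplyr::group_by(.data$peak_set, .data$group) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::mutate(norm_smooth = stats::filter(
      .data$norm, rep(1 / (2 * smooth + 1), 2 * smooth + 1))) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$norm_smooth,
                                   colour = factor(.data$group))) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~peak_set) +
    ggplot2::labs(x = "Position relative to motif center (bp)",
                  y = "Normalized insertions", colour = "Group",
                  title = sprintf("Tn5 footprint: %s", x$motif)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_footprint
#' @export
autoplot.phr_footprint <- function(x, ...) plot_footprint(x, ...)

#' Rank plot of ADT-motif correlations
#'
#' Motifs ordered by their correlation with one ADT, the canonical motif
#' highlighted.
#'
#' @param x A `phr_rankcorr`.
#' @param adt ADT name to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_rank_correlation <- function(x, adt, ...) {
  df <- dplyr::filter(x$table, .data$adt == !!adt)
  if (!nrow(df)) abort(sprintf("No correlations for ADT %s.", adt))
  canon <- if (!is.null(x$canonical)) {
    x$canonical$motif[x$canonical$adt == adt]
  } else {
    character()
  }
  df$canonical <- df$motif %in% canon
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$r,
                                   colour = .data$canonical)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "Motif rank", y = "Pearson r",
                  title = sprintf("%s vs motif deviations", adt)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rank_correlation
#' @export
autoplot.phr_rankcorr <- function(x, adt, ...) plot_rank_correlation(x, adt)

#' Plot per-quantile coverage tracks
#'
#' @param coverage Tibble from [quantile_coverage()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, ...) {
  ggplot2::ggplot(coverage, ggplot2::aes(.data$pos, .data$coverage)) +
    ggplot2::geom_area(fill = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Position (bp)", y = "Coverage per 10k fragments") +
    ggplot2::theme_minimal()
}
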