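# Figure helpers: overlaid PSCs, family pies, stacked superimposed panels.

#' Overlaid PSC traces for one run
#'
#' @param traces A list of `psc_trace` objects (or the long tibble from
#'   [traces_long()]).
#' @return A ggplot object: one line per accession over retention time.
#' @export
plot_traces <- function(traces) {
  long <- if (is.data.frame(traces)) traces else traces_long(traces)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = rt_min, y = value, colour = accession)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "retention time (min)", y = "protein score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Venom composition pie chart
#'
#' @param fam A tibble from [family_abundance()].
#' @return A ggplot pie of family fractions.
#' @export
plot_family_pie <- function(fam) {
  fam$label <- sprintf("%s (%.1f%%)", fam$family, 100 * fam$fraction)
  ggplot2::ggplot(fam, ggplot2::aes(x = "", y = fraction, fill = label)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "toxin family") +
    ggplot2::theme_void()
}

#' Superimposed UV / TPC / XIC / PSC panels
#'
#' Stacks the available chromatographic views on one shared retention-time
#' axis, the standard way of reading a nanofractionation run. PSC values
#' stay on their fraction midpoints; nothing is resampled for display.
#'
#' @param psc_traces List of `psc_trace` objects.
#' @param tpc Optional TPC trace from [build_tpc()].
#' @param xic Optional long XIC tibble (`label`, `rt_min`, `intensity`).
#' @param uv Optional UV tibble (`rt_min`, absorbance).
#' @return A ggplot with one facet row per data kind.
#' @export
plot_superimposed <- function(psc_traces, tpc = NULL, xic = NULL, uv = NULL) {
  panels <- list()
  if (!is.null(uv))
    panels$UV <- tibble::tibble(panel = "UV", series = "UV",
                                rt_min = uv$rt_min, value = uv[[2]])
  if (!is.null(tpc))
    panels$TPC <- tibble::tibble(panel = "TPC", series = "TPC",
                                 rt_min = tpc$rt_min, value = tpc$value)
  if (!is.null(xic))
    panels$XIC <- tibble::tibble(panel = "XIC", series = xic$label,
                                 rt_min = xic$rt_min, value = xic$intensity)
  if (length(psc_traces) > 0) {
    long <- traces_long(psc_traces)
    panels$PSC <- tibble::tibble(panel = "PSC", series = long$accession,
                                 rt_min = long$rt_min, value = long$value)
  }
  df <- dplyr::bind_rows(panels)
  df$panel <- factor(df$panel, levels = c("UV", "TPC", "XIC", "PSC"))
  ggplot2::ggplot(df, ggplot2::aes(x = rt_min, y = value, colour = series)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(panel), scales = "free_y") +
    ggplot2::labs(x = "retention time (min)", y = NULL) +
    ggplot2::theme_minimal()
}
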