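# Bar-plot summaries of potential impact fractions, mirroring the standard
# presentation: one bar per group per scenario, CI whiskers when bootstrap
# bounds are present.

#' Bar plot of potential impact fractions
#'
#' Plots PIF (percent of projected tobacco-related cancers preventable) per
#' group and scenario from an aggregated attribution table. If the table
#' carries bootstrap bounds (`pif_low`, `pif_high`) they are drawn as error
#' bars; otherwise the plot is emitted without whiskers and a warning is
#' raised. Bar heights equal `100 * pif` from the table exactly.
#'
#' @param attribution An aggregated attribution tibble (e.g., `by_country`,
#'   `by_site` or `by_hdi` from [run_tobacco_pipeline()], or a
#'   [bootstrap_attribution()] result).
#' @param x Grouping column mapped to the x axis: `"country"`, `"site"`,
#'   `"hdi_group"` or `"gender"`.
#' @param scenarios Scenarios to show (default all but baseline, whose PIF
#'   is identically zero).
#' @return A ggplot object.
#' @export
plot_pif <- function(attribution,
                     x = intersect(c("country", "site", "hdi_group",
                                     "gender"), names(attribution))[1],
                     scenarios = setdiff(.scenario_names, "baseline")) {
  if (is.na(x) || is.null(x) || !x %in% names(attribution)) {
    abort("no grouping column to plot; supply `x`")
  }
  df <- attribution %>%
    filter(.data$scenario %in% scenarios) %>%
    mutate(pif_pct = 100 * .data$pif)
  has_ci <- all(c("pif_low", "pif_high") %in% names(df)) &&
    !all(is.na(df$pif_low))
  if (!has_ci) {
    warn("no confidence bounds in the attribution table; plotting bars without whiskers")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data$pif_pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = NULL,
                  y = "Preventable share of projected cases (PIF, %)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (has_ci) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * .data$pif_low, ymax = 100 * .data$pif_high),
      width = 0.3)
  }
  p
}
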