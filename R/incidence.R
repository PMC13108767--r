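# Annualisation of five-year cancer projection anchors. Within each interval
# [t, t+5] the annual increment is (cases_{t+5} - cases_t) / 5, so anchor
# years are reproduced exactly and anchors lying on a straight line are
# interpolated with zero error. Fractional cases are carried unrounded; any
# rounding happens only at report time.

#' Annualize five-year incidence anchors
#'
#' Expands anchors at 2025, 2030, ..., 2050 into annual projected case
#' counts 2025-2050 per `(country, gender, site)` stratum by constant linear
#' interpolation within each five-year interval.
#'
#' @param anchors A validated anchors tibble (see
#'   [validate_incidence_anchors()]), complete per stratum.
#' @return Tibble with columns `country`, `gender`, `site`, `year`
#'   (2025-2050 inclusive), `cases`.
#' @export
#' @examples
#' a <- generate_anchors("Oman", sites = "lung", base_cases = 100,
#'                       growth = 0.1)
#' s <- annualize_incidence(a)
#' s$cases[s$year %in% 2026:2029]  # 110 120 130 140
annualize_incidence <- function(anchors) {
  anchors <- validate_incidence_anchors(anchors)
  years <- seq(min(.anchor_years), max(.anchor_years))
  anchors %>%
    group_by(.data$country, .data$gender, .data$site) %>%
    dplyr::group_modify(~ tibble(
      year = years,
      cases = stats::approx(x = .x$year, y = .x$cases,
                            xout = years, method = "linear")$y
    )) %>%
    ungroup()
}

#' Cumulative cases over a year range
#'
#' Inclusive sum of annual projected cases over calendar years
#' `year_from ... year_to` (default the full 2025-2050 window, i.e., 26
#' annual values) per stratum.
#'
#' @param series An annualized incidence tibble (see
#'   [annualize_incidence()]).
#' @param year_from,year_to Inclusive year range; must lie within the
#'   series. `year_from = 2026` reproduces a 25-value convention.
#' @return Tibble with columns `country`, `gender`, `site`, `total_cases`.
#' @export
cumulative_cases <- function(series, year_from = 2025, year_to = 2050) {
  if (year_from > year_to) abort("year_from must be <= year_to")
  rng <- range(series$year)
  if (year_from < rng[1] || year_to > rng[2]) {
    abort(sprintf("requested range %d-%d outside the series range %d-%d",
                  year_from, year_to, rng[1], rng[2]))
  }
  series %>%
    filter(.data$year >= year_from, .data$year <= year_to) %>%
    group_by(.data$country, .data$gender, .data$site) %>%
    summarise(total_cases = sum(.data$cases), .groups = "drop")
}
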