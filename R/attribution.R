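# Levin attributable fractions and potential impact fractions. PAFs are
# always computed at the finest stratum (country, gender, site, scenario) and
# only then combined by case-weighting: Levin's formula is nonlinear, so the
# aggregation order matters, and count-weighting is the only order consistent
# with multiplying each stratum's PAF by its own case count.

#' Levin population attributable fraction
#'
#' `PAF = p (RR - 1) / (1 + p (RR - 1))` for exposure prevalence `p` as a
#' proportion and relative risk `RR`. The function deliberately rejects
#' `p > 1`: prevalences are stored as percent (0-100) throughout the package
#' and must be divided by 100 before reaching Levin's formula, and this
#' domain guard makes percent/proportion confusion impossible.
#'
#' @param p Smoking prevalence as a proportion in \[0, 1\].
#' @param rr Relative risk, > 0.
#' @return PAF as a fraction; in \[0, 1) whenever `rr >= 1`.
#' @export
#' @examples
#' levin_paf(0.5, 3)  # 0.5
levin_paf <- function(p, rr) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p must be a proportion in [0, 1]; divide percent values by 100",
          class = "pifcast_domain_error")
  }
  if (any(is.na(rr)) || any(rr <= 0)) {
    abort("rr must be > 0", class = "pifcast_domain_error")
  }
  p * (rr - 1) / (1 + p * (rr - 1))
}

#' Stratum-level attribution of cancer cases to smoking
#'
#' Joins scenario prevalences, gender- and site-specific relative risks, and
#' cumulative projected cases, and computes at every
#' `(country, gender, site, scenario)` stratum: the PAF under the baseline
#' prevalence, the PAF under the scenario prevalence (same RR), the PIF
#' (their difference), cases attributable to current smoking, and preventable
#' cases `PIF * total`. Cervix in men does not exist by construction and is
#' skipped; any other stratum lacking an RR is an error.
#'
#' @param scenarios Scenario table from [build_scenario_table()] (or
#'   [interaction_scenarios()]).
#' @param rr Validated relative-risk table.
#' @param totals Cumulative cases per stratum from [cumulative_cases()].
#' @return Tibble with columns `country`, `gender`, `site`, `scenario`,
#'   `total_cases`, `paf_current`, `paf_scenario`, `pif`,
#'   `attributable_cases`, `preventable_cases`.
#' @export
attribute_cases <- function(scenarios, rr, totals) {
  need <- totals %>%
    distinct(.data$site, .data$gender) %>%
    filter(!(.data$site == "cervix" & .data$gender == "men")) %>%
    anti_join(rr, by = c("site", "gender"))
  if (nrow(need) > 0) {
    abort(c("missing relative risks for applicable strata:",
            paste(need$site, need$gender, sep = "/")),
          class = "pifcast_lookup_error")
  }

  scenarios %>%
    select("country", "gender", "scenario", "baseline_prevalence",
           "prevalence") %>%
    inner_join(totals, by = c("country", "gender"),
               relationship = "many-to-many") %>%
    filter(!(.data$site == "cervix" & .data$gender == "men")) %>%
    inner_join(rr %>% select("site", "gender", "rr"),
               by = c("site", "gender")) %>%
    mutate(
      paf_current = levin_paf(.data$baseline_prevalence / 100, .data$rr),
      paf_scenario = levin_paf(.data$prevalence / 100, .data$rr),
      pif = .data$paf_current - .data$paf_scenario,
      attributable_cases = .data$paf_current * .data$total_cases,
      preventable_cases = .data$pif * .data$total_cases
    ) %>%
    select("country", "gender", "site", "scenario", "total_cases",
           "paf_current", "paf_scenario", "pif", "attributable_cases",
           "preventable_cases")
}

#' Aggregate attribution results
#'
#' Sums case counts over strata and recomputes the fractions as
#' case-weighted ratios: aggregate `PAF = sum(attributable) / sum(total)` and
#' aggregate `PIF = sum(preventable) / sum(total)` — never an unweighted mean
#' of stratum fractions. The scenario is always kept as a grouping key.
#' Requesting `"hdi_group"` attaches the country-to-tier map first.
#'
#' @param strata Stratum results from [attribute_cases()].
#' @param by Character vector of grouping keys, any subset of
#'   `c("country", "gender", "site", "hdi_group")`; empty for the regional
#'   aggregate.
#' @param hdi Country-to-HDI-tier tibble (default [emr_hdi_groups()]); used
#'   only when `"hdi_group"` is requested.
#' @return Tibble with the grouping keys plus `scenario`, `total_cases`,
#'   `attributable_cases`, `preventable_cases`, `paf`, `pif`.
#' @export
#' @examples
#' # weighted vs naive: strata with attributable 10/100 and 30/300 aggregate
#' # to PAF (10+30)/400 = 0.10, not mean(0.10, 0.10) by accident of equal
#' # stratum fractions -- see tests for the contrasting case
aggregate_attribution <- function(strata, by = character(0),
                                  hdi = emr_hdi_groups()) {
  allowed <- c("country", "gender", "site", "hdi_group")
  bad <- setdiff(by, allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown grouping key(s): %s", paste(bad, collapse = ", ")))
  }
  key <- paste(strata$country, strata$gender, strata$site, strata$scenario,
               sep = "\r")
  if (anyDuplicated(key) > 0) {
    dup <- unique(key[duplicated(key)])
    abort(c("overlapping strata would be double-counted:",
            gsub("\r", "/", head(dup, 10))),
          class = "pifcast_aggregation_error")
  }
  if ("hdi_group" %in% by) {
    missing <- setdiff(unique(strata$country), hdi$country)
    if (length(missing) > 0) {
      abort(c("countries without an HDI group:", missing),
            class = "pifcast_aggregation_error")
    }
    strata <- strata %>% left_join(hdi, by = "country")
  }
  strata %>%
    group_by(across(all_of(c(by, "scenario")))) %>%
    summarise(
      total_cases = sum(.data$total_cases),
      attributable_cases = sum(.data$attributable_cases),
      preventable_cases = sum(.data$preventable_cases),
      .groups = "drop"
    ) %>%
    mutate(
      paf = .data$attributable_cases / .data$total_cases,
      pif = .data$preventable_cases / .data$total_cases
    )
}

#' Scale projected incidence (sensitivity analysis)
#'
#' Applies a multiplicative factor to all case counts of an attribution
#' table — total, attributable and preventable — leaving PAF and PIF exactly
#' unchanged. Factors 0.9 and 1.1 reproduce the +-10% incidence-projection
#' sensitivity analyses.
#'
#' @param attribution A stratum or aggregated attribution tibble.
#' @param factor Positive scaling factor.
#' @return The attribution tibble with scaled counts.
#' @export
scale_incidence <- function(attribution, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) ||
      factor <= 0) {
    abort("factor must be a single positive number",
          class = "pifcast_domain_error")
  }
  cols <- intersect(c("total_cases", "attributable_cases",
                      "preventable_cases"), names(attribution))
  attribution %>% mutate(across(all_of(cols), ~ .x * factor))
}
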