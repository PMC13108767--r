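# Counterfactual 2025 smoking prevalence under the policy scenarios. A
# scenario's reduction is the policy gap (current value to target) times the
# fitted coefficient, summed over the scenario's policies; single-policy
# scenarios use the univariable-model coefficient, the combined scenario the
# multivariable-model coefficients. Counterfactual prevalence is floored at
# zero (and capped at 100 for pathological positive-coefficient inputs); the
# level shift is held constant over the whole 2025-2050 window.

.scenario_names <- c("baseline", "max_mpower", "affordability_plus10",
                     "max_literacy", "combined")

.scenario_policies <- list(
  baseline = character(0),
  max_mpower = "mpower",
  affordability_plus10 = "affordability",
  max_literacy = "literacy",
  combined = c("mpower", "affordability", "literacy")
)

#' Scenario definitions
#'
#' The five modelled scenarios and the policies each one moves to target:
#' full MPOWER implementation (score 34), a 10-unit increase in the
#' affordability index, maximum adult literacy (100%), all three combined,
#' and the no-change baseline.
#'
#' @return A tibble with columns `scenario` and `policies` (list column).
#' @export
scenario_definitions <- function() {
  tibble(scenario = .scenario_names,
         policies = unname(.scenario_policies[.scenario_names]))
}

#' Policy gap to target
#'
#' The distance from a current policy value to its scenario target: MPOWER
#' to the maximum score of 34, literacy to 100%, and affordability a flat
#' 10-unit increase regardless of the current value.
#'
#' @param current Numeric vector of current policy values.
#' @param policy One of `"mpower"`, `"affordability"`, `"literacy"`.
#' @return Numeric vector of non-negative gaps in predictor units.
#' @export
#' @examples
#' policy_gap(31, "mpower")      # 3
#' policy_gap(4.2, "affordability")  # 10
policy_gap <- function(current, policy) {
  policy <- match.arg(policy, .policy_predictors)
  switch(policy,
    mpower = {
      if (any(current > 34, na.rm = TRUE)) {
        abort("MPOWER score above the maximum of 34; gap would be negative",
              class = "pifcast_validation_error")
      }
      34 - current
    },
    literacy = {
      if (any(current > 100, na.rm = TRUE)) {
        abort("literacy rate above 100%; gap would be negative",
              class = "pifcast_validation_error")
      }
      100 - current
    },
    affordability = rep_len(10, length(current))
  )
}

#' Counterfactual prevalence for one scenario
#'
#' `reduction = sum over the scenario's policies of (-beta * gap)`;
#' `prevalence = min(100, max(0, baseline - reduction))`. Arithmetic is
#' signed throughout: a positive coefficient produces a negative reduction,
#' i.e., a higher counterfactual prevalence.
#'
#' @param baseline_percent Baseline (2025) prevalence in percent.
#' @param gaps Named numeric vector of policy gaps (predictor units).
#' @param coefficients Named numeric vector of fitted coefficients
#'   (percentage points per predictor unit) covering the scenario's policies.
#' @param scenario Scenario name (see [scenario_definitions()]).
#' @return One-row tibble: `scenario`, `baseline_prevalence`, `reduction`,
#'   `prevalence`.
#' @export
#' @examples
#' project_prevalence(30, c(mpower = 10), c(mpower = -0.26), "max_mpower")
project_prevalence <- function(baseline_percent, gaps, coefficients,
                               scenario) {
  scenario <- match.arg(scenario, .scenario_names)
  pols <- .scenario_policies[[scenario]]
  missing <- setdiff(pols, names(coefficients))
  if (length(missing) > 0) {
    abort(sprintf("missing coefficient(s) for scenario '%s': %s",
                  scenario, paste(missing, collapse = ", ")),
          class = "pifcast_config_error")
  }
  missing_gap <- setdiff(pols, names(gaps))
  if (length(missing_gap) > 0) {
    abort(sprintf("missing gap(s) for scenario '%s': %s",
                  scenario, paste(missing_gap, collapse = ", ")),
          class = "pifcast_config_error")
  }
  reduction <- if (length(pols) == 0) 0 else
    sum(-coefficients[pols] * gaps[pols])
  tibble(
    scenario = scenario,
    baseline_prevalence = baseline_percent,
    reduction = reduction,
    prevalence = clip(baseline_percent - reduction, 0, 100)
  )
}

# current policy values per (country, gender): the baseline-year value when
# observed, else the latest observed year; the year used is recorded
current_policy_values <- function(panel, baseline_year = .baseline_year) {
  panel %>%
    tidyr::pivot_longer(all_of(.policy_predictors),
                        names_to = "policy", values_to = "value") %>%
    filter(!is.na(.data$value)) %>%
    arrange(.data$country, .data$gender, .data$policy,
            dplyr::desc(.data$year == baseline_year), dplyr::desc(.data$year)) %>%
    distinct(.data$country, .data$gender, .data$policy, .keep_all = TRUE) %>%
    select("country", "gender", "policy", "value", source_year = "year")
}

# coefficient per (gender, policy) for single-policy scenarios (univariable
# fits) and the combined scenario (multivariable fit)
scenario_coefficients <- function(fits) {
  purrr::map_dfr(c("men", "women"), function(g) {
    f <- fits[[g]]
    bind_rows(
      purrr::map_dfr(.policy_predictors, function(p) {
        tibble(gender = g, source = "univariable", policy = p,
               beta = unname(f[[p]]$betas[[p]]))
      }),
      tibble(gender = g, source = "multivariable",
             policy = names(f$multivariable$betas),
             beta = unname(f$multivariable$betas))
    )
  })
}

#' Build the full scenario-prevalence table
#'
#' Computes, per country and gender, the counterfactual 2025 prevalence under
#' all five scenarios. Single-policy scenarios use the univariable-model
#' coefficients; the combined scenario uses the multivariable-model
#' coefficients. Gaps are taken from the baseline-year policy values when
#' observed, otherwise from the latest observed year (recorded in
#' `gap_source_year`). Countries without a baseline prevalence row are
#' skipped and listed in the `skipped` attribute.
#'
#' @param panel A validated policy panel including baseline-year rows.
#' @param fits A [fit_policy_models()] result (or an equivalently shaped
#'   nested list of `fe_fit` objects).
#' @param baseline_year Year of the baseline prevalence (default 2025).
#' @return Tibble with columns `country`, `gender`, `scenario`,
#'   `baseline_prevalence`, `reduction`, `prevalence`, `gap_source_year`,
#'   `coefficient_source`.
#' @export
build_scenario_table <- function(panel, fits,
                                 baseline_year = .baseline_year) {
  base <- panel %>%
    filter(.data$year == baseline_year) %>%
    select("country", "gender", baseline_prevalence = "prevalence")
  all_cg <- panel %>% distinct(.data$country, .data$gender)
  skipped <- anti_join(all_cg, base, by = c("country", "gender"))
  if (nrow(skipped) > 0) {
    inform(c(sprintf("skipping %d country-gender strata without a %d baseline row:",
                     nrow(skipped), baseline_year),
             paste(skipped$country, skipped$gender, sep = "/")))
  }

  cur <- current_policy_values(panel, baseline_year)
  cur$gap <- NA_real_
  for (p in .policy_predictors) {
    i <- cur$policy == p
    if (any(i)) cur$gap[i] <- policy_gap(cur$value[i], p)
  }
  # earliest year any policy value was taken from (flags fallback use)
  src <- cur %>%
    group_by(.data$country, .data$gender) %>%
    summarise(gap_source_year = min(.data$source_year), .groups = "drop")

  coefs <- scenario_coefficients(fits)
  # scenario -> policies, long; baseline contributes no rows (reduction 0)
  scen_pol <- purrr::map_dfr(.scenario_names, function(sc) {
    pols <- .scenario_policies[[sc]]
    if (length(pols) == 0) return(NULL)
    tibble(scenario = sc, policy = pols,
           source = if (sc == "combined") "multivariable" else "univariable")
  })

  rows <- base %>% dplyr::cross_join(tibble(scenario = .scenario_names))
  red <- rows %>%
    left_join(scen_pol, by = "scenario", relationship = "many-to-many") %>%
    left_join(cur %>% select("country", "gender", "policy", "gap"),
              by = c("country", "gender", "policy")) %>%
    left_join(coefs, by = c("gender", "policy", "source"))
  incomplete <- red %>%
    filter(!is.na(.data$policy), is.na(.data$beta) | is.na(.data$gap))
  if (nrow(incomplete) > 0) {
    abort(c("missing coefficient or policy value for scenario rows:",
            paste(incomplete$country, incomplete$gender, incomplete$scenario,
                  incomplete$policy, sep = "/")),
          class = "pifcast_config_error")
  }
  red <- red %>%
    group_by(.data$country, .data$gender, .data$scenario) %>%
    summarise(
      reduction = sum(ifelse(is.na(.data$policy), 0,
                             -.data$beta * .data$gap)),
      .groups = "drop"
    )

  out <- rows %>%
    left_join(red, by = c("country", "gender", "scenario")) %>%
    left_join(src, by = c("country", "gender")) %>%
    mutate(
      prevalence = clip(.data$baseline_prevalence - .data$reduction, 0, 100),
      coefficient_source = ifelse(.data$scenario == "combined",
                                  "multivariable",
                                  ifelse(.data$scenario == "baseline", "none",
                                         "univariable"))
    ) %>%
    select("country", "gender", "scenario", "baseline_prevalence",
           "reduction", "prevalence", "gap_source_year",
           "coefficient_source") %>%
    arrange(.data$country, .data$gender,
            match(.data$scenario, .scenario_names))
  attr(out, "skipped") <- skipped
  out
}

#' Combined scenario under the mpower-by-literacy interaction model
#'
#' Recomputes the combined-policy scenario using the interaction model's
#' marginal effects evaluated at each country's own covariate values:
#' `d(prevalence)/d(mpower) = beta_mpower + beta_inter * literacy` and
#' `d(prevalence)/d(literacy) = beta_literacy + beta_inter * mpower`; the
#' affordability effect is its main coefficient. Gaps and the zero floor are
#' as in [build_scenario_table()]. With a zero interaction coefficient this
#' reproduces the main-effects combined scenario exactly.
#'
#' @param panel A validated policy panel including baseline-year rows.
#' @param fits A [fit_policy_models()] result containing `interaction` fits.
#' @param baseline_year Year of the baseline prevalence (default 2025).
#' @return Tibble with the same columns as [build_scenario_table()],
#'   `scenario = "combined"`, `coefficient_source = "interaction"`.
#' @export
interaction_scenarios <- function(panel, fits,
                                  baseline_year = .baseline_year) {
  for (g in c("men", "women")) {
    if (is.null(fits[[g]]$interaction)) {
      abort(sprintf("no interaction fit for %s", g),
            class = "pifcast_config_error")
    }
  }
  base <- panel %>%
    filter(.data$year == baseline_year) %>%
    select("country", "gender", baseline_prevalence = "prevalence")
  cur <- current_policy_values(panel, baseline_year)

  purrr::map_dfr(seq_len(nrow(base)), function(r) {
    ctry <- base$country[r]; g <- base$gender[r]
    fit <- fits[[g]]$interaction
    b <- fit$betas
    gv <- cur %>% filter(.data$country == ctry, .data$gender == g)
    val <- setNames(gv$value, gv$policy)
    gap <- setNames(vapply(seq_len(nrow(gv)), function(i)
      policy_gap(gv$value[i], gv$policy[i]), numeric(1)), gv$policy)
    eff <- c(
      mpower = unname(b[["mpower"]] + b[[.interaction_term]] * val[["literacy"]]),
      affordability = unname(b[["affordability"]]),
      literacy = unname(b[["literacy"]] + b[[.interaction_term]] * val[["mpower"]])
    )
    reduction <- sum(-eff * gap[names(eff)])
    tibble(
      country = ctry, gender = g, scenario = "combined",
      baseline_prevalence = base$baseline_prevalence[r],
      reduction = reduction,
      prevalence = clip(base$baseline_prevalence[r] - reduction, 0, 100),
      gap_source_year = if (nrow(gv) > 0) min(gv$source_year) else NA_integer_,
      coefficient_source = "interaction"
    )
  }) %>%
    arrange(.data$country, .data$gender)
}
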