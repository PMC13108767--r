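# End-to-end orchestration: fit all models, build scenarios, annualize
# incidence, attribute, aggregate at the reporting levels, and (optionally)
# bootstrap. Deterministic given (inputs, seed); every resolved analysis
# choice is echoed into the bundle's log.

#' Run the full policy-to-preventable-cancers pipeline
#'
#' Orchestrates the whole analysis: per-gender fixed-effects fits
#' (univariable, multivariable, interaction), the five-scenario
#' counterfactual prevalence table, annualization and accumulation of the
#' incidence anchors, Levin attribution at the finest stratum, aggregation by
#' country, cancer site, HDI tier and region, the optional incidence-scaling
#' sensitivity, and the optional country-level bootstrap for regional CIs.
#'
#' @param panel,anchors,rr Validated input tables (see the `read_*` and
#'   `generate_*` families).
#' @param hdi Country-to-HDI-tier map (default [emr_hdi_groups()]).
#' @param year_from,year_to Inclusive summation window (default 2025-2050,
#'   26 annual values).
#' @param incidence_scale Multiplicative sensitivity factor on projected
#'   cases (default 1; the reported sensitivity analyses use 0.9 and 1.1).
#' @param n_boot Bootstrap replications for regional and HDI-level CIs; 0
#'   (default) skips the bootstrap.
#' @param seed Seed for the bootstrap.
#' @param ci_level Confidence level for bootstrap intervals.
#' @return An object of class `pif_run`: a list with elements `fits`
#'   (a [fit_policy_models()] nested list), `fit_table` (tidy coefficients of
#'   all models), `scenarios`, `totals`, `strata`, `by_country`, `by_site`,
#'   `by_hdi`, `region`, optional `region_ci` and `hdi_ci`, and `log`
#'   (character vector of resolved analysis decisions).
#' @export
#' @examples
#' b <- generate_study_bundle(seed = 42, n_countries = 4)
#' run <- run_tobacco_pipeline(b$panel, b$anchors, b$rr, b$hdi)
#' run$region
run_tobacco_pipeline <- function(panel, anchors, rr,
                                 hdi = emr_hdi_groups(),
                                 year_from = 2025, year_to = 2050,
                                 incidence_scale = 1,
                                 n_boot = 0, seed = 1, ci_level = 0.95) {
  log <- c(
    sprintf("summation window: %d-%d inclusive (%d annual values)",
            year_from, year_to, year_to - year_from + 1),
    "coefficient source: univariable fits for single-policy scenarios, multivariable fit for combined",
    sprintf("incidence scale factor: %g", incidence_scale),
    "scenario reduction held constant over the projection window; floor at 0, cap at 100"
  )

  fits <- fit_policy_models(panel)
  fit_table <- purrr::map_dfr(c("men", "women"), function(g) {
    purrr::map_dfr(names(fits[[g]]), function(m) {
      f <- fits[[g]][[m]]
      tidy(f) %>%
        mutate(gender = g, model = m, .before = 1) %>%
        left_join(
          tibble(term = names(f$vif %||% setNames(numeric(0), character(0))),
                 vif = unname(f$vif %||% numeric(0))),
          by = "term") %>%
        dplyr::bind_cols(glance(f)[rep(1, nrow(tidy(f))),
                                   c("r2_within", "r2_between", "r2_overall")])
    })
  })

  scenarios <- build_scenario_table(panel, fits)
  series <- annualize_incidence(anchors)
  totals <- cumulative_cases(series, year_from, year_to)
  strata <- attribute_cases(scenarios, rr, totals)
  if (incidence_scale != 1) {
    strata <- scale_incidence(strata, incidence_scale)
    log <- c(log, sprintf("all case counts scaled by %g (sensitivity run)",
                          incidence_scale))
  }

  out <- list(
    fits = fits,
    fit_table = fit_table,
    scenarios = scenarios,
    series = series,
    totals = totals,
    strata = strata,
    by_country = aggregate_attribution(strata, "country", hdi),
    by_site = aggregate_attribution(strata, "site", hdi),
    by_gender = aggregate_attribution(strata, "gender", hdi),
    by_hdi = aggregate_attribution(strata, "hdi_group", hdi),
    region = aggregate_attribution(strata, character(0), hdi),
    log = log
  )

  if (n_boot > 0) {
    log <- c(log, sprintf("bootstrap: %d reps, country resampling, %g%% percentile CIs, seed %d",
                          n_boot, 100 * ci_level, seed))
    out$region_ci <- bootstrap_attribution(panel, anchors, rr, hdi,
                                           by = character(0),
                                           n_reps = n_boot, seed = seed,
                                           ci_level = ci_level,
                                           year_from = year_from,
                                           year_to = year_to)
    out$hdi_ci <- bootstrap_attribution(panel, anchors, rr, hdi,
                                        by = "hdi_group",
                                        n_reps = n_boot, seed = seed,
                                        ci_level = ci_level,
                                        year_from = year_from,
                                        year_to = year_to)
    if (incidence_scale != 1) {
      count_cols <- c("total_cases", "attributable_cases",
                      "preventable_cases", "attributable_low",
                      "attributable_high", "preventable_low",
                      "preventable_high")
      scale_counts <- function(tb) tb %>%
        mutate(across(all_of(intersect(count_cols, names(tb))),
                      ~ .x * incidence_scale))
      out$region_ci <- scale_counts(out$region_ci)
      out$hdi_ci <- scale_counts(out$hdi_ci)
    }
    out$log <- log
  }
  structure(out, class = "pif_run")
}

#' @export
print.pif_run <- function(x, ...) {
  cat("pifcast pipeline run\n")
  cat(sprintf("  %d countries, %d strata\n",
              n_distinct(x$strata$country), nrow(x$strata)))
  cat("Regional results by scenario:\n")
  print(x$region %>%
          mutate(paf_pct = 100 * .data$paf, pif_pct = 100 * .data$pif) %>%
          select("scenario", "total_cases", "attributable_cases",
                 "preventable_cases", "paf_pct", "pif_pct"))
  invisible(x)
}

#' Write a pipeline result bundle to CSV files
#'
#' Exports the machine-readable tables of a [run_tobacco_pipeline()] result
#' (full precision) plus a `run_log.txt` of the resolved analysis decisions.
#' Report-style rounding belongs to the caller; see [round_half_up()].
#'
#' @param run A `pif_run` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_result_bundle <- function(run, dir) {
  stopifnot(inherits(run, "pif_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(run$fit_table, file.path(dir, "fits.csv"))
  write_table(run$scenarios, file.path(dir, "scenarios.csv"))
  write_table(run$totals, file.path(dir, "cumulative_cases.csv"))
  write_table(run$strata, file.path(dir, "attribution_strata.csv"))
  write_table(run$by_country, file.path(dir, "table1_by_country.csv"))
  write_table(run$by_site, file.path(dir, "table2_by_site.csv"))
  write_table(run$by_hdi, file.path(dir, "s7_by_hdi.csv"))
  write_table(run$region, file.path(dir, "region.csv"))
  if (!is.null(run$region_ci)) {
    write_table(run$region_ci, file.path(dir, "region_ci.csv"))
  }
  if (!is.null(run$hdi_ci)) {
    write_table(run$hdi_ci, file.path(dir, "hdi_ci.csv"))
  }
  writeLines(run$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Round half away from zero
#'
#' Report-style rounding for case counts (R's `round()` rounds half to
#' even). Used only at presentation time; all internal arithmetic carries
#' fractional cases.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
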