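# Nonparametric bootstrap uncertainty. The default resampling unit is the
# country: countries are drawn with replacement, each draw becomes a
# pseudo-unit (duplicates renamed), the regressions are refit and the
# downstream stages rerun on the replicate, and percentile bounds are taken
# from the empirical distribution over replicates. The point estimate always
# comes from the unresampled data. One master seed spawns independent
# per-replicate substreams, so replicates are order-independent.

.resample_units <- c("country", "country_panel_rows", "rr_lognormal")

# draw replicate inputs for one bootstrap iteration
resample_inputs <- function(inputs, resample_unit, countries) {
  out <- inputs
  if ("country" %in% resample_unit) {
    draws <- sample(countries, length(countries), replace = TRUE)
    pseudo <- paste0(draws, "#", seq_along(draws))
    out <- lapply(out, function(tb) {
      if (!is.data.frame(tb) || !"country" %in% names(tb)) return(tb)
      sp <- split(seq_len(nrow(tb)), tb$country)
      take <- sp[draws]
      new <- tb[unlist(take, use.names = FALSE), , drop = FALSE]
      new$country <- rep(pseudo, lengths(take))
      new
    })
  }
  if ("country_panel_rows" %in% resample_unit) {
    out$panel <- out$panel %>%
      group_by(.data$country, .data$gender) %>%
      dplyr::slice_sample(prop = 1, replace = TRUE) %>%
      ungroup()
  }
  if ("rr_lognormal" %in% resample_unit) {
    rr <- out$rr
    if (is.null(rr) || !all(c("ci_low", "ci_high") %in% names(rr))) {
      abort("rr_lognormal resampling needs an rr table with ci_low/ci_high",
            class = "pifcast_config_error")
    }
    sdlog <- (log(rr$ci_high) - log(rr$ci_low)) / (2 * qnorm(0.975))
    out$rr <- rr %>% mutate(rr = rlnorm(n(), meanlog = log(.data$rr),
                                        sdlog = sdlog))
  }
  out
}

#' Percentile bootstrap confidence intervals for a pipeline statistic
#'
#' Reruns `statistic` on resampled versions of `inputs` and returns
#' percentile confidence bounds from the empirical distribution of the
#' replicates. `statistic` must be a pure function of its inputs returning a
#' named numeric vector; the reported point estimate is always
#' `statistic(inputs)` on the unresampled data and never depends on `n_reps`
#' or `seed`. Failed replicates (e.g., a singular refit) are dropped and
#' counted; more than 10% failures is an error.
#'
#' @param inputs A named list of data frames (e.g., `panel`, `totals`, `rr`,
#'   `hdi`). Every element with a `country` column participates in country
#'   resampling.
#' @param statistic Function `inputs -> named numeric vector`.
#' @param n_reps Number of bootstrap replications (default 1000).
#' @param seed Master seed; spawns one independent substream per replicate.
#' @param ci_level Confidence level (default 0.95); bounds are the
#'   `(1 - ci_level)/2` and `1 - (1 - ci_level)/2` empirical quantiles.
#' @param resample_unit One or more of `"country"` (default; refit on
#'   countries drawn with replacement), `"country_panel_rows"` (resample each
#'   country's panel rows), `"rr_lognormal"` (draw each relative risk from a
#'   lognormal matched to its CI). Units combine.
#' @return Tibble with columns `statistic`, `estimate`, `conf.low`,
#'   `conf.high`; attributes `n_reps`, `n_failed`, and the replicate matrix
#'   `replicates`.
#' @export
bootstrap_ci <- function(inputs, statistic, n_reps = 1000, seed = 1,
                         ci_level = 0.95, resample_unit = "country") {
  stopifnot(n_reps >= 1, ci_level > 0, ci_level < 1)
  resample_unit <- match.arg(resample_unit, .resample_units,
                             several.ok = TRUE)
  point <- statistic(inputs)
  if (is.null(names(point)) || any(names(point) == "")) {
    abort("statistic must return a fully named numeric vector")
  }
  countries <- unique(unlist(lapply(inputs, function(tb) {
    if (is.data.frame(tb) && "country" %in% names(tb)) tb$country
  })))

  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_reps))
  reps <- matrix(NA_real_, nrow = n_reps, ncol = length(point),
                 dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (i in seq_len(n_reps)) {
    val <- with_seed(sub_seeds[i], {
      tryCatch({
        ri <- resample_inputs(inputs, resample_unit, countries)
        statistic(ri)
      }, error = function(e) NULL)
    })
    if (is.null(val)) {
      n_failed <- n_failed + 1L
    } else {
      common <- intersect(names(point), names(val))
      reps[i, common] <- val[common]
    }
  }
  if (n_failed > 0.10 * n_reps) {
    abort(sprintf("%d of %d bootstrap replicates failed (> 10%%)",
                  n_failed, n_reps),
          class = "pifcast_bootstrap_error")
  }
  alpha <- (1 - ci_level) / 2
  lo <- apply(reps, 2, quantile, probs = alpha, na.rm = TRUE, names = FALSE)
  hi <- apply(reps, 2, quantile, probs = 1 - alpha, na.rm = TRUE,
              names = FALSE)
  out <- tibble(statistic = names(point), estimate = unname(point),
                conf.low = unname(lo), conf.high = unname(hi))
  attr(out, "n_reps") <- n_reps
  attr(out, "n_failed") <- n_failed
  attr(out, "replicates") <- reps
  out
}

# statistic factory: refit models, rebuild scenarios, attribute, aggregate
attribution_statistic <- function(by, year_from, year_to) {
  function(inputs) {
    fits <- fit_policy_models(inputs$panel, interaction = FALSE)
    scen <- suppressMessages(build_scenario_table(inputs$panel, fits))
    strata <- attribute_cases(scen, inputs$rr, inputs$totals)
    agg <- aggregate_attribution(strata, by = by, hdi = inputs$hdi)
    keys <- agg %>%
      select(all_of(c(by, "scenario"))) %>%
      purrr::pmap_chr(function(...) paste(..., sep = "|"))
    vals <- c(
      setNames(agg$pif, paste0(keys, "|pif")),
      setNames(agg$preventable_cases, paste0(keys, "|preventable_cases")),
      setNames(agg$paf, paste0(keys, "|paf")),
      setNames(agg$attributable_cases, paste0(keys, "|attributable_cases"))
    )
    vals
  }
}

#' Bootstrap confidence intervals for attribution results
#'
#' Runs the country-level bootstrap over the full estimation pipeline
#' (regression refit, scenario construction, Levin attribution, aggregation)
#' and attaches percentile CIs for PAF, PIF, attributable and preventable
#' cases at the requested aggregation level. Incidence anchors are
#' annualized and accumulated once up front; a country's cumulative totals
#' follow it into each replicate.
#'
#' @param panel,anchors,rr Validated input tables.
#' @param hdi Country-to-HDI-tier map (default [emr_hdi_groups()]).
#' @param by Aggregation keys as in [aggregate_attribution()]; default
#'   regional (empty).
#' @param year_from,year_to Summation window (default 2025-2050 inclusive).
#' @inheritParams bootstrap_ci
#' @return The aggregated attribution tibble with columns `paf_low/high`,
#'   `pif_low/high`, `attributable_low/high`, `preventable_low/high`
#'   appended; attribute `n_failed` as in [bootstrap_ci()].
#' @export
bootstrap_attribution <- function(panel, anchors, rr,
                                  hdi = emr_hdi_groups(),
                                  by = character(0),
                                  n_reps = 1000, seed = 1, ci_level = 0.95,
                                  resample_unit = "country",
                                  year_from = 2025, year_to = 2050) {
  if ("country" %in% by && "country" %in% resample_unit) {
    abort(c("country resampling is incoherent for per-country CIs",
            "use resample_unit = c(\"country_panel_rows\", \"rr_lognormal\") for country-level intervals"),
          class = "pifcast_config_error")
  }
  totals <- cumulative_cases(annualize_incidence(anchors), year_from, year_to)
  inputs <- list(panel = panel, totals = totals, rr = rr, hdi = hdi)
  stat <- attribution_statistic(by, year_from, year_to)
  ci <- bootstrap_ci(inputs, stat, n_reps = n_reps, seed = seed,
                     ci_level = ci_level, resample_unit = resample_unit)

  fits <- fit_policy_models(panel, interaction = FALSE)
  scen <- suppressMessages(build_scenario_table(panel, fits))
  agg <- aggregate_attribution(attribute_cases(scen, rr, totals),
                               by = by, hdi = hdi)
  keys <- agg %>%
    select(all_of(c(by, "scenario"))) %>%
    purrr::pmap_chr(function(...) paste(..., sep = "|"))
  bound <- function(metric, col) {
    ci[[col]][match(paste0(keys, "|", metric), ci$statistic)]
  }
  out <- agg
  out$paf_low <- bound("paf", "conf.low")
  out$paf_high <- bound("paf", "conf.high")
  out$pif_low <- bound("pif", "conf.low")
  out$pif_high <- bound("pif", "conf.high")
  out$attributable_low <- bound("attributable_cases", "conf.low")
  out$attributable_high <- bound("attributable_cases", "conf.high")
  out$preventable_low <- bound("preventable_cases", "conf.low")
  out$preventable_high <- bound("preventable_cases", "conf.high")
  attr(out, "n_failed") <- attr(ci, "n_failed")
  attr(out, "n_reps") <- n_reps
  out
}
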