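# Synthetic data with known ground truth. The generator emulates the study
# conditions of the regional analysis: 16 countries observed biennially
# 2010-2020 plus a 2025 baseline year, two genders, policy exposures in
# realistic EMR ranges, incidence anchors that grow exactly linearly within
# five-year intervals (so interpolation error is zero by construction), and
# site/gender relative risks in [1.1, 10].

# evaluate code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

default_betas <- function() {
  list(
    men = c(mpower = -0.26, affordability = -0.35, literacy = -0.20),
    women = c(mpower = -0.10, affordability = -0.08, literacy = -0.05)
  )
}

#' Generate a synthetic policy panel with known coefficients
#'
#' Draws policy exposures in realistic Eastern-Mediterranean ranges (integer
#' MPOWER 20-31, affordability 0-15% of GDP per capita, literacy 30-100%)
#' with mild positive MPOWER-literacy correlation, then builds prevalence as
#' `intercept + sum(beta * x) + beta_interaction * mpower * literacy +
#' country effect + year effect + Gaussian noise`, clipped to \[0, 100\].
#' Per-gender defaults keep men's prevalence roughly in 0-60% and women's in
#' 0-26%. The true parameters are returned alongside the panel so downstream
#' estimators can be validated exactly.
#'
#' @param n_countries Number of countries (>= 2). Up to 16 are drawn from
#'   [emr_countries()]; beyond that, synthetic names are appended.
#' @param years Fit years (>= 2 values); default biennial 2010-2020.
#' @param baseline_year Baseline year appended to the panel (default 2025);
#'   set to `NULL` to omit.
#' @param beta Named list with elements `men` and `women`, each a named
#'   vector of true coefficients (percentage points of prevalence per unit of
#'   `mpower`, `affordability`, `literacy`). Default [default_betas()].
#' @param beta_interaction Named vector (`men`, `women`) of true
#'   mpower-by-literacy interaction coefficients; default 0.
#' @param intercept,country_effect_sd,noise_sd Named vectors (`men`, `women`)
#'   of the overall intercept, the SD of country intercept shifts, and the
#'   residual SD, all in percentage points.
#' @param year_effect_sd SD of common year shocks (percentage points).
#' @param mpower_literacy_rho Target correlation between the latent drivers
#'   of MPOWER and literacy (default 0.3).
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @return A list with `panel` (a validated policy panel tibble carrying
#'   attributes `fit_years` and `clip_fraction`) and `truth` (a list of the
#'   generating parameters, including realised country and year effects).
#' @export
#' @examples
#' sim <- generate_panel(n_countries = 4, seed = 1)
#' dplyr::count(sim$panel, gender)
generate_panel <- function(n_countries = 16,
                           years = seq(2010, 2020, by = 2),
                           baseline_year = 2025,
                           beta = default_betas(),
                           beta_interaction = c(men = 0, women = 0),
                           intercept = c(men = 52, women = 14),
                           country_effect_sd = c(men = 8, women = 3),
                           year_effect_sd = 1,
                           noise_sd = c(men = 1.5, women = 0.5),
                           mpower_literacy_rho = 0.3,
                           seed = 1) {
  stopifnot(n_countries >= 2, length(years) >= 2)
  if (any(noise_sd < 0)) abort("noise_sd must be >= 0")
  pool <- emr_countries()
  countries <- if (n_countries <= length(pool)) pool[seq_len(n_countries)]
  else c(pool, sprintf("Synthetica-%02d", seq_len(n_countries - length(pool))))
  all_years <- sort(unique(c(years, baseline_year)))

  with_seed(seed, {
    u <- rnorm(n_countries)                       # development latent
    z <- rnorm(n_countries)
    rho <- mpower_literacy_rho
    v <- rho * u + sqrt(1 - rho^2) * z            # MPOWER latent
    lit_base <- clip(65 + 18 * u, 32, 98)
    mp_base <- 23 + 2.5 * v
    aff_base <- runif(n_countries, 1, 8)

    grid <- tidyr::expand_grid(
      country = countries,
      year = all_years,
      gender = c("men", "women")
    ) %>%
      mutate(ci = match(.data$country, countries))

    t0 <- grid$year - min(all_years)
    # exposures are national (identical across genders within country-year)
    key <- paste(grid$country, grid$year)
    uidx <- match(key, key[!duplicated(key)])
    n_cells <- max(uidx)
    lit_nat <- clip(lit_base[grid$ci] + 0.4 * t0 +
                      rnorm(n_cells, 0, 1.5)[uidx], 30, 100)
    mp_nat <- as.integer(round(clip(
      mp_base[grid$ci] + 0.35 * t0 + rnorm(n_cells, 0, 1)[uidx], 20, 31)))
    aff_nat <- clip(aff_base[grid$ci] + 0.15 * t0 +
                      rnorm(n_cells, 0, 0.5)[uidx], 0, 15)

    ce <- list(
      men = rnorm(n_countries, 0, country_effect_sd[["men"]]),
      women = rnorm(n_countries, 0, country_effect_sd[["women"]])
    )
    ye <- rnorm(length(all_years), 0, year_effect_sd)
    names(ye) <- all_years

    lin <- function(g) {
      b <- beta[[g]]
      idx <- grid$gender == g
      intercept[[g]] +
        b[["mpower"]] * mp_nat[idx] +
        b[["affordability"]] * aff_nat[idx] +
        b[["literacy"]] * lit_nat[idx] +
        beta_interaction[[g]] * mp_nat[idx] * lit_nat[idx] +
        ce[[g]][grid$ci[idx]] +
        ye[as.character(grid$year[idx])] +
        rnorm(sum(idx), 0, noise_sd[[g]])
    }
    prev <- numeric(nrow(grid))
    for (g in c("men", "women")) prev[grid$gender == g] <- lin(g)

    clipped <- prev < 0 | prev > 100
    clip_fraction <- mean(clipped)
    if (clip_fraction > 0.05) {
      warn(sprintf(
        "%.1f%% of generated prevalence values were clipped to [0, 100]; estimates fitted to this panel may be biased",
        100 * clip_fraction))
    }

    panel <- grid %>%
      mutate(
        prevalence = clip(prev, 0, 100),
        mpower = mp_nat,
        affordability = aff_nat,
        literacy = lit_nat
      ) %>%
      select(all_of(.panel_cols)) %>%
      arrange(.data$country, .data$year, .data$gender)
    panel <- validate_policy_panel(panel)
    attr(panel, "fit_years") <- sort(years)
    attr(panel, "clip_fraction") <- clip_fraction

    truth <- list(
      beta = beta,
      beta_interaction = beta_interaction,
      intercept = intercept,
      country_effects = lapply(ce, function(x) setNames(x, countries)),
      year_effects = ye,
      noise_sd = noise_sd,
      clip_fraction = clip_fraction,
      seed = seed
    )
    list(panel = panel, truth = truth)
  })
}

#' Generate linear incidence anchors
#'
#' Anchors follow `cases(year) = base * (1 + growth * (year - 2025))` at the
#' six anchor years, exactly linear so that annual interpolation reproduces
#' the generating line with zero error. Cervix anchors are emitted for women
#' only.
#'
#' @param countries Character vector of countries.
#' @param sites Cancer sites; default the 13 tobacco-related sites.
#' @param base_cases Base (2025) case count per stratum: a positive scalar,
#'   or `NULL` (default) to sample log-uniformly in \[200, 20000\] per
#'   stratum.
#' @param growth Annual linear growth rate as a fraction of the base
#'   (default 0.03/year). May be negative provided no anchor goes below zero.
#' @param seed Integer seed (used only when `base_cases` is sampled).
#' @return Validated anchors tibble, with the per-stratum truth (`base`,
#'   `growth`) attached as attribute `truth`.
#' @export
#' @examples
#' a <- generate_anchors("Oman", sites = "lung", base_cases = 100, growth = 0.1)
#' a[a$year == 2030, "cases"]  # 150
generate_anchors <- function(countries,
                             sites = tobacco_cancer_sites(),
                             base_cases = NULL,
                             growth = 0.03,
                             seed = 1) {
  if (!is.null(base_cases) && any(base_cases <= 0)) {
    abort("base_cases must be > 0")
  }
  strata <- bind_rows(
    tidyr::expand_grid(country = countries, gender = "men",
                       site = intersect(sites, applicable_sites("men"))),
    tidyr::expand_grid(country = countries, gender = "women",
                       site = intersect(sites, applicable_sites("women")))
  )
  with_seed(seed, {
    strata$base <- if (is.null(base_cases)) {
      exp(runif(nrow(strata), log(200), log(20000)))
    } else {
      rep_len(base_cases, nrow(strata))
    }
    strata$growth <- rep_len(growth, nrow(strata))
    anchors <- strata %>%
      tidyr::expand_grid(year = .anchor_years) %>%
      mutate(cases = .data$base * (1 + .data$growth * (.data$year - 2025)))
    if (any(anchors$cases < 0)) {
      abort("growth is so negative that projected cases fall below zero")
    }
    out <- validate_incidence_anchors(
      anchors %>% select(all_of(.anchor_cols)))
    attr(out, "truth") <- strata
    out
  })
}

#' Generate a synthetic relative-risk table
#'
#' One relative risk per `(site, gender)`, sampled log-uniformly in
#' \[1.1, 10\] (cervix women-only), with 95% CI bounds placed at
#' `rr * exp(+-1.96 * sdlog)` for use by the lognormal RR bootstrap.
#'
#' @param sites Cancer sites; default the 13 tobacco-related sites.
#' @param sdlog Log-scale SD implied by the CI bounds (default 0.1).
#' @param seed Integer seed.
#' @return Validated RR tibble with columns `site`, `gender`, `rr`,
#'   `ci_low`, `ci_high`.
#' @export
generate_rr_table <- function(sites = tobacco_cancer_sites(),
                              sdlog = 0.1,
                              seed = 1) {
  tbl <- bind_rows(
    tibble(site = intersect(sites, applicable_sites("men")), gender = "men"),
    tibble(site = intersect(sites, applicable_sites("women")), gender = "women")
  )
  with_seed(seed, {
    tbl$rr <- exp(runif(nrow(tbl), log(1.1), log(10)))
    tbl$ci_low <- tbl$rr * exp(-1.96 * sdlog)
    tbl$ci_high <- tbl$rr * exp(1.96 * sdlog)
    validate_rr_table(tbl)
  })
}

#' Generate a full synthetic study bundle
#'
#' Convenience wrapper producing, from one seed, all four inputs of the
#' pipeline under the default study conditions: a 16-country biennial
#' 2010-2020 panel with a 2025 baseline, linear incidence anchors, a
#' relative-risk table, and the fixed HDI grouping.
#'
#' @param seed Integer master seed.
#' @param n_countries Number of countries (default 16).
#' @param ... Passed on to [generate_panel()].
#' @return List with elements `panel`, `anchors`, `rr`, `hdi`, `truth`.
#' @export
generate_study_bundle <- function(seed = 1, n_countries = 16, ...) {
  sim <- generate_panel(n_countries = n_countries, seed = seed, ...)
  countries <- unique(sim$panel$country)
  anchors <- generate_anchors(countries, seed = seed + 1L)
  rr <- generate_rr_table(seed = seed + 2L)
  hdi <- emr_hdi_groups() %>% filter(.data$country %in% countries)
  if (nrow(hdi) < length(countries)) {
    extra <- tibble(country = setdiff(countries, hdi$country),
                    hdi_group = factor("medium",
                                       levels = c("low", "medium", "high")))
    hdi <- bind_rows(hdi, extra)
  }
  list(panel = sim$panel, anchors = anchors, rr = rr, hdi = hdi,
       truth = sim$truth)
}
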