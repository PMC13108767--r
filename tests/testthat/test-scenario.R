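test_that("policy gaps follow the target rules", {
  expect_equal(policy_gap(31, "mpower"), 3)        # Iran-style maximum score
  expect_equal(policy_gap(20, "mpower"), 14)
  expect_equal(policy_gap(4.2, "affordability"), 10)
  expect_equal(policy_gap(13.7, "affordability"), 10)
  expect_equal(policy_gap(100, "literacy"), 0)
  expect_equal(policy_gap(c(40, 85), "literacy"), c(60, 15))
  expect_error(policy_gap(35, "mpower"), class = "pifcast_validation_error")
  expect_error(policy_gap(101, "literacy"), class = "pifcast_validation_error")
})

test_that("projected prevalence is baseline minus coefficient times gap, floored and capped", {
  out <- project_prevalence(30, c(mpower = 10), c(mpower = -0.26),
                            "max_mpower")
  expect_equal(out$reduction, 2.6)
  expect_equal(out$prevalence, 27.4)

  floored <- project_prevalence(1, c(literacy = 15), c(literacy = -0.2),
                                "max_literacy")
  expect_equal(floored$reduction, 3)
  expect_equal(floored$prevalence, 0)

  # signed arithmetic: a positive coefficient raises counterfactual prevalence
  up <- project_prevalence(99.5, c(mpower = 10), c(mpower = 0.2),
                           "max_mpower")
  expect_equal(up$reduction, -2)
  expect_equal(up$prevalence, 100)

  zero <- project_prevalence(12, c(mpower = 0, affordability = 0,
                                   literacy = 0),
                             c(mpower = -1, affordability = -1,
                               literacy = -1), "combined")
  expect_equal(zero$prevalence, 12)
  expect_equal(project_prevalence(12, c(), c(), "baseline")$prevalence, 12)

  expect_error(project_prevalence(30, c(mpower = 10), c(literacy = -0.2),
                                  "max_mpower"),
               class = "pifcast_config_error")
})

test_that("the scenario table has 5 x countries x genders rows and a faithful baseline", {
  sim <- generate_panel(n_countries = 16, seed = 201)
  fits <- fit_policy_models(sim$panel, interaction = FALSE)
  scen <- build_scenario_table(sim$panel, fits)
  expect_equal(nrow(scen), 5 * 16 * 2)
  base <- dplyr::filter(scen, scenario == "baseline")
  input <- dplyr::filter(sim$panel, year == 2025)
  joined <- dplyr::left_join(base, input, by = c("country", "gender"))
  expect_equal(joined$prevalence.x, joined$prevalence.y)
  expect_equal(base$reduction, rep(0, nrow(base)))
  # determinism: identical inputs give identical tables
  expect_equal(build_scenario_table(sim$panel, fits), scen,
               ignore_attr = TRUE)
  expect_true(all(scen$prevalence >= 0 & scen$prevalence <= 100))
})

test_that("combined reduction is the sum of per-policy reductions under multivariable betas", {
  sim <- generate_panel(n_countries = 6, seed = 202)
  fits <- fit_policy_models(sim$panel, interaction = FALSE)
  scen <- build_scenario_table(sim$panel, fits)
  base25 <- dplyr::filter(sim$panel, year == 2025)
  for (i in seq_len(nrow(base25))) {
    row <- base25[i, ]
    b <- fits[[row$gender]]$multivariable$betas
    gaps <- c(mpower = policy_gap(row$mpower, "mpower"),
              affordability = 10,
              literacy = policy_gap(row$literacy, "literacy"))
    expected <- sum(-b[names(gaps)] * gaps)
    got <- scen$reduction[scen$country == row$country &
                            scen$gender == row$gender &
                            scen$scenario == "combined"]
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # single-policy scenarios use the univariable betas
  row <- base25[1, ]
  b1 <- fits[[row$gender]]$mpower$betas[["mpower"]]
  got <- scen$reduction[scen$country == row$country &
                          scen$gender == row$gender &
                          scen$scenario == "max_mpower"]
  expect_equal(got, -b1 * policy_gap(row$mpower, "mpower"), tolerance = 1e-12)
})

test_that("with negative betas, larger gaps never increase counterfactual prevalence", {
  betas_uni <- c(mpower = -0.2, affordability = -0.3, literacy = -0.15)
  fits <- stub_fits(betas_uni, betas_uni)
  p <- hand_panel()
  p25 <- dplyr::filter(p, year == 2020) %>% dplyr::mutate(year = 2025L)
  panel <- dplyr::bind_rows(p, p25)
  scen1 <- build_scenario_table(panel, fits)
  lower <- panel
  lower$mpower <- pmax(20L, lower$mpower - 5L)  # larger MPOWER gap
  scen2 <- build_scenario_table(lower, fits)
  m1 <- dplyr::filter(scen1, scenario == "max_mpower")
  m2 <- dplyr::filter(scen2, scenario == "max_mpower")
  expect_true(all(m2$prevalence <= m1$prevalence + 1e-12))
})

test_that("countries without a baseline row are skipped and reported", {
  sim <- generate_panel(n_countries = 4, seed = 203)
  fits <- fit_policy_models(sim$panel, interaction = FALSE)
  panel <- dplyr::filter(sim$panel,
                         !(country == "Bahrain" & year == 2025))
  expect_message(scen <- build_scenario_table(panel, fits), "Bahrain")
  expect_equal(nrow(scen), 5 * 3 * 2)
  expect_equal(nrow(attr(scen, "skipped")), 2)
})

test_that("gap source year falls back to the latest observed year", {
  sim <- generate_panel(n_countries = 3, seed = 204)
  fits <- fit_policy_models(sim$panel, interaction = FALSE)
  panel <- sim$panel
  panel$mpower[panel$year == 2025] <- NA_integer_
  scen <- build_scenario_table(panel, fits)
  expect_true(all(scen$gap_source_year == 2025 | scen$gap_source_year == 2020))
  expect_true(any(scen$gap_source_year == 2020))
})

test_that("a zero interaction coefficient reproduces the main-effects combined scenario", {
  betas <- c(mpower = -0.2, affordability = -0.3, literacy = -0.15)
  fits <- stub_fits(betas, betas,
                    beta_inter = c(betas, "mpower:literacy" = 0))
  p <- hand_panel()
  p25 <- dplyr::filter(p, year == 2020) %>% dplyr::mutate(year = 2025L)
  panel <- dplyr::bind_rows(p, p25)
  main <- dplyr::filter(build_scenario_table(panel, fits),
                        scenario == "combined")
  inter <- interaction_scenarios(panel, fits)
  expect_equal(inter$reduction, main$reduction, tolerance = 1e-14)
  expect_equal(inter$prevalence, main$prevalence, tolerance = 1e-14)
})

test_that("interaction marginal effects attenuate MPOWER at higher literacy and are recovered from noiseless data", {
  # positive interaction with negative main effect: the MPOWER effect
  # shrinks in magnitude as literacy rises
  b_int <- c(mpower = -0.4, affordability = -0.3, literacy = -0.15,
             "mpower:literacy" = 0.003)
  eff_low <- b_int[["mpower"]] + b_int[["mpower:literacy"]] * 40
  eff_high <- b_int[["mpower"]] + b_int[["mpower:literacy"]] * 95
  expect_lt(abs(eff_high), abs(eff_low))

  simx <- noiseless_panel(n_countries = 8, seed = 205,
                          beta_interaction = c(men = 0.004, women = 0.001))
  fits <- fit_policy_models(simx$panel)
  inter <- interaction_scenarios(simx$panel, fits)
  # manual recomputation from the truth for one stratum
  row <- dplyr::filter(simx$panel, year == 2025, gender == "men")[1, ]
  truth_b <- simx$truth$beta$men
  bi <- simx$truth$beta_interaction[["men"]]
  eff <- c(truth_b[["mpower"]] + bi * row$literacy,
           truth_b[["affordability"]],
           truth_b[["literacy"]] + bi * row$mpower)
  gaps <- c(policy_gap(row$mpower, "mpower"), 10,
            policy_gap(row$literacy, "literacy"))
  expected <- sum(-eff * gaps)
  got <- inter$reduction[inter$country == row$country &
                           inter$gender == "men"]
  expect_equal(got, expected, tolerance = 1e-6)
})
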