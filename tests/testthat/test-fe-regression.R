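# The estimator builds its own design matrix and solves by QR; the oracle in
# these tests is R's lm() formula interface on explicit factor dummies -- an
# independent code path that must agree to 1e-8.

lm_oracle <- function(panel, gender, predictors, interaction = FALSE) {
  df <- dplyr::filter(panel, gender == !!gender, year != 2025)
  rhs <- paste(predictors, collapse = " + ")
  if (interaction) rhs <- paste(rhs, "+ I(mpower * literacy)")
  f <- stats::as.formula(paste("prevalence ~", rhs,
                               "+ factor(country) + factor(year)"))
  stats::lm(f, data = df)
}

test_that("fixed-effects coefficients and SEs equal dummy-variable OLS on random small panels", {
  for (seed in 1:8) {
    nc <- 3 + (seed %% 4)
    ny <- 3 + ((seed * 3) %% 4)
    sim <- generate_panel(n_countries = nc,
                          years = seq(2010, by = 2, length.out = ny),
                          baseline_year = NULL, seed = 100 + seed)
    fit <- fit_fixed_effects(sim$panel, "men")
    ora <- lm_oracle(sim$panel, "men", c("mpower", "affordability", "literacy"))
    co <- coef(ora)
    expect_equal(unname(fit$beta0), unname(co[["(Intercept)"]]),
                 tolerance = 1e-8)
    expect_equal(unname(fit$betas),
                 unname(co[c("mpower", "affordability", "literacy")]),
                 tolerance = 1e-8)
    se_ora <- sqrt(diag(vcov(ora)))
    expect_equal(unname(fit$se),
                 unname(se_ora[c("(Intercept)", "mpower", "affordability",
                                 "literacy")]),
                 tolerance = 1e-8)
  }
})

test_that("the interaction model matches the lm oracle and nests the main-effects model", {
  sim <- generate_panel(n_countries = 6, seed = 71,
                        beta_interaction = c(men = 0.004, women = 0.001))
  fit <- fit_fixed_effects(sim$panel, "men", interaction = TRUE)
  ora <- lm_oracle(sim$panel, "men", c("mpower", "affordability", "literacy"),
                   interaction = TRUE)
  expect_equal(unname(fit$betas[["mpower:literacy"]]),
               unname(coef(ora)[["I(mpower * literacy)"]]), tolerance = 1e-8)
  # noiseless data with a known interaction: marginal effects recovered exactly
  simx <- noiseless_panel(n_countries = 6, seed = 72,
                          beta_interaction = c(men = 0.004, women = 0.001))
  fitx <- fit_fixed_effects(simx$panel, "men", interaction = TRUE)
  expect_equal(unname(fitx$betas[["mpower:literacy"]]), 0.004,
               tolerance = 1e-7)
})

test_that("adding a constant to all prevalence values shifts only the intercept", {
  sim <- generate_panel(n_countries = 5, seed = 81)
  shifted <- sim$panel
  shifted$prevalence <- shifted$prevalence + 10
  f0 <- fit_fixed_effects(sim$panel, "men")
  f1 <- fit_fixed_effects(shifted, "men")
  expect_equal(f1$betas, f0$betas, tolerance = 1e-10)
  expect_equal(f1$beta0, f0$beta0 + 10, tolerance = 1e-8)
  expect_equal(f1$country_effects$effect, f0$country_effects$effect,
               tolerance = 1e-8)
})

test_that("men and women fits are independent", {
  sim <- generate_panel(n_countries = 5, seed = 82)
  f0 <- fit_fixed_effects(sim$panel, "men")
  perturbed <- sim$panel
  w <- perturbed$gender == "women"
  perturbed$prevalence[w] <- pmin(100, perturbed$prevalence[w] + 3)
  f1 <- fit_fixed_effects(perturbed, "men")
  expect_identical(f0$betas, f1$betas)
})

test_that("degenerate designs fail loudly and by name", {
  p <- hand_panel()
  flat <- p
  flat$affordability <- rep(rep(c(2, 1, 3), each = 3), 2) # constant within country
  err <- expect_error(fit_fixed_effects(flat, "men", "affordability"),
                      class = "pifcast_singularity_error")
  expect_match(conditionMessage(err), "affordability")

  two <- dplyr::filter(p, country %in% c("Bahrain", "Oman"),
                       year %in% c(2016, 2018))
  expect_error(fit_fixed_effects(two, "men"), class = "pifcast_rank_error")

  one_country <- dplyr::filter(p, country == "Bahrain")
  expect_error(fit_fixed_effects(one_country, "men"),
               class = "pifcast_fit_error")

  # residuals of a healthy fit are centred on zero
  fit <- fit_fixed_effects(generate_panel(6, seed = 83)$panel, "women")
  expect_lt(abs(mean(fit$residuals)), 1e-8)
})

test_that("VIF is 1 for orthogonal predictors and Inf under perfect collinearity", {
  p <- hand_panel()
  # two exactly orthogonal (zero-correlation) predictors by construction
  p$mpower <- rep(c(22L, 22L, 26L, 26L, 22L, 26L, 26L, 22L, 24L), 2)
  p$literacy <- rep(c(70, 90, 70, 90, 90, 70, 90, 70, 80), 2)
  stopifnot(abs(cor(p$mpower, p$literacy)) < 1e-12)
  v <- compute_vif(p, "men", c("mpower", "literacy"))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-10)

  dup <- hand_panel()
  dup$affordability <- dup$literacy
  v2 <- compute_vif(dup, "men", c("affordability", "literacy"))
  expect_true(all(is.infinite(v2)))
})

test_that("VIF matches the bivariate closed form 1/(1 - rho^2) and car::vif", {
  # construct two columns whose sample correlation is exactly 0.6
  n <- 400
  set.seed(1)
  x <- scale(rnorm(n))[, 1]
  e <- stats::residuals(stats::lm(rnorm(n) ~ x))
  e <- scale(e)[, 1]
  y <- 0.6 * x + sqrt(1 - 0.36) * e
  p <- tibble::tibble(
    country = rep(sprintf("C%02d", 1:20), each = n / 20),
    year = rep(rep(c(2010L, 2012L, 2014L, 2016L, 2018L), 4), 20),
    gender = "men", prevalence = 10,
    mpower = 25 + 3 * x, affordability = 5, literacy = 65 + 10 * y
  )
  v <- compute_vif(p, "men", c("mpower", "literacy"))
  expect_equal(unname(v), rep(1 / (1 - 0.36), 2), tolerance = 1e-8)

  skip_if_not_installed("car")
  cv <- car::vif(stats::lm(prevalence + rnorm(n) ~ mpower + literacy,
                           data = p))
  expect_equal(unname(v), unname(cv), tolerance = 1e-8)
})

test_that("R2 components are 1 on noiseless effect-free data and near 0 under a null", {
  sim <- generate_panel(
    n_countries = 6, seed = 91,
    noise_sd = c(men = 0, women = 0),
    country_effect_sd = c(men = 0, women = 0), year_effect_sd = 0)
  fit <- fit_fixed_effects(sim$panel, "men")
  r2 <- r_squared_components(fit)
  expect_equal(unlist(r2), c(r2_within = 1, r2_between = 1, r2_overall = 1),
               tolerance = 1e-9)

  null <- generate_panel(
    n_countries = 40, years = seq(2010, 2028, by = 2), seed = 92,
    beta = list(men = c(mpower = 0, affordability = 0, literacy = 0),
                women = c(mpower = 0, affordability = 0, literacy = 0)),
    noise_sd = c(men = 4, women = 2))
  fit0 <- fit_fixed_effects(null$panel, "men")
  expect_lt(fit0$r2_within, 0.08)

  noisy <- fit_fixed_effects(generate_panel(8, seed = 93)$panel, "women")
  r2n <- unlist(r_squared_components(noisy))
  expect_true(all(r2n >= 0 & r2n <= 1))
})

test_that("tidy and glance return the documented broom-style tables", {
  fit <- fit_fixed_effects(generate_panel(6, seed = 95)$panel, "men")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$term,
               c("(Intercept)", "mpower", "affordability", "literacy"))
  ce <- tidy(fit, effects = "country")
  expect_equal(ce$estimate[1], 0) # reference country
  gl <- glance(fit)
  expect_equal(gl$nobs, fit$nobs)
  expect_gte(gl$max_vif, 1)
})
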