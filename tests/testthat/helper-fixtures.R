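# Shared fixtures, built in code. Panels used for exact-recovery checks are
# noiseless; `hand_panel()` is a fully deterministic 3-country panel written
# out literally so expected values can be derived by hand.

noiseless_args <- function() {
  list(noise_sd = c(men = 0, women = 0),
       country_effect_sd = c(men = 6, women = 2),
       year_effect_sd = 0.8)
}

noiseless_panel <- function(n_countries = 5, seed = 11, ...) {
  do.call(generate_panel,
          c(list(n_countries = n_countries, seed = seed, ...),
            noiseless_args()))
}

# 3 countries x 3 years x 2 genders, values typed in literally
hand_panel <- function() {
  tibble::tibble(
    country = rep(rep(c("Bahrain", "Oman", "Qatar"), each = 3), 2),
    year = rep(rep(c(2016L, 2018L, 2020L), 3), 2),
    gender = rep(c("men", "women"), each = 9),
    prevalence = c(30, 28, 27, 25, 24, 22, 35, 33, 30,
                   6, 5.5, 5, 4, 3.8, 3.5, 8, 7.5, 7),
    mpower = rep(c(22L, 24L, 26L, 20L, 23L, 25L, 21L, 22L, 27L), 2),
    affordability = rep(c(2, 2.5, 3, 1, 1.5, 2, 3, 3.5, 4.5), 2),
    literacy = rep(c(80, 82, 85, 70, 72, 75, 90, 91, 93), 2)
  )
}

# small complete anchor grid: 2 countries x 2 genders x all sites
toy_anchors <- function(countries = c("Oman", "Qatar"), base = 100,
                        growth = 0.1) {
  generate_anchors(countries, base_cases = base, growth = growth, seed = 3)
}

# fe_fit-shaped stubs carrying prescribed coefficients, for scenario-engine
# tests that need exact control over the betas
stub_fits <- function(beta_uni, beta_multi, beta_inter = NULL) {
  per_gender <- function() {
    f <- lapply(names(beta_uni), function(p) {
      structure(list(betas = beta_uni[p], predictors = p), class = "fe_fit")
    })
    names(f) <- names(beta_uni)
    f$multivariable <- structure(list(betas = beta_multi,
                                      predictors = names(beta_multi)),
                                 class = "fe_fit")
    if (!is.null(beta_inter)) {
      f$interaction <- structure(
        list(betas = beta_inter, predictors = names(beta_inter)),
        class = "fe_fit")
    }
    f
  }
  list(men = per_gender(), women = per_gender())
}
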