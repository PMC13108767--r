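# Two-way fixed-effects estimation of policy-prevalence associations.
# Coefficients come from least squares on a hand-built design with country
# and year indicator columns (reference-cell coding, first country/year as
# reference). At panel sizes of ~100 rows per gender this is exact and
# transparent, and numerically identical to the within estimator.

.policy_predictors <- c("mpower", "affordability", "literacy")
.interaction_term <- "mpower:literacy"

# resolve fit years: explicit > panel attribute > all non-baseline years
resolve_fit_years <- function(panel, years) {
  if (!is.null(years)) return(sort(unique(years)))
  fy <- attr(panel, "fit_years")
  if (!is.null(fy)) return(sort(unique(fy)))
  sort(setdiff(unique(panel$year), .baseline_year))
}

# predictor matrix (policy columns plus optional interaction product,
# uncentered raw values) for the rows of `df`
predictor_matrix <- function(df, predictors, interaction) {
  P <- as.matrix(df[, predictors, drop = FALSE])
  storage.mode(P) <- "double"
  if (interaction) {
    if (!all(c("mpower", "literacy") %in% predictors)) {
      abort("interaction = TRUE requires both 'mpower' and 'literacy' among the predictors")
    }
    P <- cbind(P, df$mpower * df$literacy)
    colnames(P) <- c(predictors, .interaction_term)
  }
  P
}

#' Fit a two-way fixed-effects prevalence regression
#'
#' Regresses smoking prevalence (percent, 0-100) on one or more policy
#' exposures with country and year fixed effects, for one gender subset.
#' Coefficients are absolute percentage-point changes in prevalence per unit
#' of the predictor. Rows with a missing predictor are dropped listwise for
#' the model at hand (no imputation); observations are unweighted, each
#' country contributing equally per observed year. Men and women are always
#' fitted separately.
#'
#' @param panel A validated policy panel (see [read_policy_panel()] or
#'   [generate_panel()]).
#' @param gender `"men"` or `"women"`.
#' @param predictors Subset of `c("mpower", "affordability", "literacy")`.
#' @param interaction If `TRUE`, appends the raw (uncentered)
#'   mpower-by-literacy product term; requires both predictors.
#' @param years Years used for estimation; defaults to the panel's
#'   `fit_years` attribute, else all years except the 2025 baseline.
#' @return An object of class `fe_fit`: a list with elements `gender`,
#'   `predictors`, `beta0`, `betas`, `se`, `country_effects`, `year_effects`
#'   (tibbles; reference level has effect 0), `residuals`, `r2_within`,
#'   `r2_between`, `r2_overall`, `vif` (multi-predictor fits only), `nobs`,
#'   and the estimation sample `data`. Use [tidy()] / [glance()] to extract
#'   results as tibbles.
#' @export
#' @examples
#' sim <- generate_panel(n_countries = 5, noise_sd = c(men = 0, women = 0),
#'                       seed = 7)
#' fit <- fit_fixed_effects(sim$panel, "men")
#' tidy(fit)
fit_fixed_effects <- function(panel, gender,
                              predictors = .policy_predictors,
                              interaction = FALSE,
                              years = NULL) {
  gender <- match.arg(gender, c("men", "women"))
  bad <- setdiff(predictors, .policy_predictors)
  if (length(bad) > 0) {
    abort(sprintf("unknown predictor(s): %s", paste(bad, collapse = ", ")))
  }
  years <- resolve_fit_years(panel, years)

  rows <- panel$gender == gender & panel$year %in% years
  df <- panel[rows, , drop = FALSE]
  df <- df[complete.cases(df[, c("prevalence", predictors)]), , drop = FALSE]

  if (n_distinct(df$country) < 2 || n_distinct(df$year) < 2) {
    abort("fixed-effects fit needs at least 2 countries and 2 years of complete data",
          class = "pifcast_fit_error")
  }

  P <- predictor_matrix(df, predictors, interaction)
  terms <- colnames(P)

  # a predictor constant within every country cannot be separated from the
  # country effects
  for (k in terms) {
    within_var <- tapply(P[, k], df$country, var)
    if (all(within_var < 1e-12, na.rm = TRUE)) {
      abort(sprintf("predictor '%s' has zero within-country variance; it is collinear with the country fixed effects", k),
            class = "pifcast_singularity_error")
    }
  }

  countries <- sort(unique(df$country))
  yrs <- sort(unique(df$year))
  C <- outer(df$country, countries[-1], `==`) * 1
  colnames(C) <- paste0("country:", countries[-1])
  Y <- outer(df$year, yrs[-1], `==`) * 1
  colnames(Y) <- paste0("year:", yrs[-1])
  X <- cbind(`(Intercept)` = 1, P, C, Y)

  n <- nrow(X); p <- ncol(X)
  if (n < p) {
    abort(sprintf("fewer observations (%d) than parameters (%d)", n, p),
          class = "pifcast_rank_error")
  }
  y <- df$prevalence
  ls <- lm.fit(X, y)
  if (ls$rank < p) {
    aliased <- colnames(X)[is.na(ls$coefficients)]
    abort(c("design matrix is rank deficient",
            sprintf("aliased column(s): %s", paste(aliased, collapse = ", "))),
          class = "pifcast_singularity_error")
  }

  coefs <- ls$coefficients
  resid <- ls$residuals
  sigma2 <- sum(resid^2) / (n - p)
  piv <- ls$qr$pivot
  R <- qr.R(ls$qr)
  cov_unscaled <- chol2inv(R)
  se <- numeric(p)
  se[piv] <- sqrt(diag(cov_unscaled) * sigma2)
  names(se) <- colnames(X)

  betas <- coefs[terms]
  xb <- as.numeric(coefs[["(Intercept)"]] + P %*% betas)
  r2 <- r2_components_xb(y, xb, df$country)

  vif <- if (ncol(P) >= 2) vif_from_matrix(P) else NULL

  structure(list(
    gender = gender,
    predictors = terms,
    interaction = interaction,
    beta0 = unname(coefs[["(Intercept)"]]),
    betas = betas,
    se = se[c("(Intercept)", terms)],
    country_effects = tibble(
      country = countries,
      effect = c(0, unname(coefs[paste0("country:", countries[-1])]))
    ),
    year_effects = tibble(
      year = yrs,
      effect = c(0, unname(coefs[paste0("year:", yrs[-1])]))
    ),
    residuals = unname(resid),
    fitted = unname(y - resid),
    xb = xb,
    r2_within = r2[["within"]],
    r2_between = r2[["between"]],
    r2_overall = r2[["overall"]],
    vif = vif,
    sigma = sqrt(sigma2),
    nobs = n,
    df.residual = n - p,
    years = yrs,
    data = df
  ), class = "fe_fit")
}

# squared-correlation R2 decomposition, Stata xtreg convention: xb excludes
# the fixed effects (with them the between component is identically 1)
r2_components_xb <- function(y, xb, country) {
  safe_cor2 <- function(a, b) {
    if (sd(a) < 1e-12 || sd(b) < 1e-12) return(NA_real_)
    stats::cor(a, b)^2
  }
  cm_y <- tapply(y, country, mean)
  cm_xb <- tapply(xb, country, mean)
  within <- safe_cor2(y - cm_y[country], xb - cm_xb[country])
  between <- safe_cor2(as.numeric(cm_y), as.numeric(cm_xb))
  overall <- safe_cor2(y, xb)
  c(within = within, between = between, overall = overall)
}

#' R-squared components of a fixed-effects fit
#'
#' Returns the within, between and overall R-squared of a fitted model as
#' squared correlations between the linear predictor `xb = beta0 + X * beta`
#' (fixed effects excluded) and the response: within uses country-demeaned
#' values, between uses country means, overall raw values. A component whose
#' variance is degenerate (zero) is returned as `NA`.
#'
#' @param fit An `fe_fit` object.
#' @return A tibble with columns `r2_within`, `r2_between`, `r2_overall`,
#'   each in \[0, 1\] where defined.
#' @export
r_squared_components <- function(fit) {
  stopifnot(inherits(fit, "fe_fit"))
  tibble(r2_within = fit$r2_within,
         r2_between = fit$r2_between,
         r2_overall = fit$r2_overall)
}

vif_from_matrix <- function(P) {
  k <- ncol(P)
  out <- setNames(numeric(k), colnames(P))
  for (j in seq_len(k)) {
    yj <- P[, j]
    Xj <- cbind(1, P[, -j, drop = FALSE])
    fj <- lm.fit(Xj, yj)
    tss <- sum((yj - mean(yj))^2)
    r2 <- if (tss < 1e-12) 1 else 1 - sum(fj$residuals^2) / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Variance inflation factors of the policy predictors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` regresses predictor *k* on the
#' other policy predictors (with intercept) over the same rows a
#' fixed-effects fit would use. Perfect collinearity yields `Inf`, not an
#' error.
#'
#' @inheritParams fit_fixed_effects
#' @return Named numeric vector of VIFs (all >= 1), one per predictor.
#' @export
compute_vif <- function(panel, gender, predictors = .policy_predictors,
                        interaction = FALSE, years = NULL) {
  gender <- match.arg(gender, c("men", "women"))
  if (length(predictors) + interaction < 2) {
    abort("VIF needs at least 2 predictors")
  }
  years <- resolve_fit_years(panel, years)
  df <- panel %>%
    filter(.data$gender == !!gender, .data$year %in% years) %>%
    filter(if_all(all_of(predictors), ~ !is.na(.x)))
  vif_from_matrix(predictor_matrix(df, predictors, interaction))
}

#' Fit the full model set for one panel
#'
#' Fits, per gender, the three univariable policy models (used by the
#' single-policy scenarios), the multivariable model (used by the combined
#' scenario), and optionally the mpower-by-literacy interaction variant.
#'
#' @inheritParams fit_fixed_effects
#' @param interaction Also fit the interaction model (default `TRUE`).
#' @return Nested list `fits[[gender]][[model]]` with models `mpower`,
#'   `affordability`, `literacy`, `multivariable`, and `interaction`.
#' @export
fit_policy_models <- function(panel, years = NULL, interaction = TRUE) {
  fits <- lapply(c(men = "men", women = "women"), function(g) {
    m <- lapply(setNames(.policy_predictors, .policy_predictors),
                function(pr) fit_fixed_effects(panel, g, pr, years = years))
    m$multivariable <- fit_fixed_effects(panel, g, .policy_predictors,
                                         years = years)
    if (interaction) {
      m$interaction <- fit_fixed_effects(panel, g, .policy_predictors,
                                         interaction = TRUE, years = years)
    }
    m
  })
  structure(fits, class = "policy_fits")
}

#' @export
print.fe_fit <- function(x, ...) {
  cat(sprintf("Two-way fixed-effects fit (%s), %d obs, %d countries x %d years\n",
              x$gender, x$nobs, nrow(x$country_effects), length(x$years)))
  print(tidy(x), n = Inf)
  cat(sprintf("R2 within %.3f | between %.3f | overall %.3f\n",
              x$r2_within, x$r2_between, x$r2_overall))
  invisible(x)
}

#' Tidy a fixed-effects fit
#'
#' @param x An `fe_fit` object.
#' @param effects Which terms to return: `"coefficients"` (intercept and
#'   policy slopes, the default), `"country"` or `"year"` fixed effects.
#' @param ... Unused.
#' @return A tibble. For coefficients: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy fe_fit
#' @export
tidy.fe_fit <- function(x, effects = c("coefficients", "country", "year"),
                        ...) {
  effects <- match.arg(effects)
  if (effects == "country") {
    return(x$country_effects %>% rename(term = "country", estimate = "effect"))
  }
  if (effects == "year") {
    return(x$year_effects %>%
             mutate(year = as.character(.data$year)) %>%
             rename(term = "year", estimate = "effect"))
  }
  est <- c(x$beta0, unname(x$betas))
  se <- unname(x$se)
  stat <- est / se
  tibble(
    term = c("(Intercept)", x$predictors),
    estimate = est,
    std.error = se,
    statistic = stat,
    p.value = 2 * stats::pt(abs(stat), df = x$df.residual, lower.tail = FALSE)
  )
}

#' Glance at a fixed-effects fit
#'
#' @param x An `fe_fit` object.
#' @param ... Unused.
#' @return One-row tibble with the fit diagnostics (R-squared components,
#'   residual SD, sample sizes, and the maximum VIF where defined).
#' @method glance fe_fit
#' @export
glance.fe_fit <- function(x, ...) {
  tibble(
    r2_within = x$r2_within,
    r2_between = x$r2_between,
    r2_overall = x$r2_overall,
    sigma = x$sigma,
    nobs = x$nobs,
    n_countries = nrow(x$country_effects),
    n_years = length(x$years),
    df.residual = x$df.residual,
    max_vif = if (is.null(x$vif)) NA_real_ else max(x$vif)
  )
}

#' Coefficient plot for a fixed-effects fit
#'
#' @param object An `fe_fit` object.
#' @param conf_level Confidence level for the error bars (default 0.95).
#' @param ... Unused.
#' @return A ggplot object: point estimates with normal-approximation
#'   intervals for the policy coefficients.
#' @method autoplot fe_fit
#' @export
autoplot.fe_fit <- function(object, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  td <- tidy(object) %>% filter(.data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - z * .data$std.error,
      xmax = .data$estimate + z * .data$std.error)) +
    ggplot2::labs(
      x = "Percentage-point change in prevalence per predictor unit",
      y = NULL,
      title = sprintf("Policy coefficients (%s)", object$gender)
    )
}
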