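# Canonical country and cancer-site vocabularies for the EMR analysis.

# variants -> canonical; supplementary tables and figure captions mix forms
.country_aliases <- c(
  "uae"                  = "United Arab Emirates",
  "united arab emirates" = "United Arab Emirates",
  "emirates"             = "United Arab Emirates",
  "iran"                 = "Iran",
  "islamic republic of iran" = "Iran",
  "iran (islamic republic of)" = "Iran",
  "saudi arabia"         = "Saudi Arabia",
  "kingdom of saudi arabia" = "Saudi Arabia",
  "afghanistan"          = "Afghanistan",
  "bahrain"              = "Bahrain",
  "egypt"                = "Egypt",
  "iraq"                 = "Iraq",
  "jordan"               = "Jordan",
  "kuwait"               = "Kuwait",
  "lebanon"              = "Lebanon",
  "morocco"              = "Morocco",
  "oman"                 = "Oman",
  "pakistan"             = "Pakistan",
  "qatar"                = "Qatar",
  "tunisia"              = "Tunisia",
  "yemen"                = "Yemen"
)

#' The 16 Eastern Mediterranean analysis countries
#'
#' The countries retained in the regional analysis (Sudan, Somalia, Libya,
#' Syria and Djibouti are excluded for lack of recent smoking-prevalence
#' data; the loaders nevertheless accept any country set).
#'
#' @return Character vector of 16 canonical country names.
#' @export
#' @examples
#' emr_countries()
emr_countries <- function() {
  sort(unique(unname(.country_aliases)))
}

#' Canonicalize country names
#'
#' Maps common variants ("UAE", "Islamic Republic of Iran") to one canonical
#' spelling so tables from different sources join cleanly. Unknown names are
#' returned unchanged (trimmed), so non-EMR countries pass through.
#'
#' @param x Character vector of country names.
#' @return Character vector of canonical names, same length as `x`.
#' @export
#' @examples
#' canonicalize_country(c("UAE", "iran", "Kuwait"))
canonicalize_country <- function(x) {
  key <- tolower(trimws(as.character(x)))
  hit <- .country_aliases[key]
  out <- ifelse(is.na(hit), trimws(as.character(x)), hit)
  unname(out)
}

#' Human Development Index grouping of the analysis countries
#'
#' Fixed post-estimation grouping of the 16 countries into low, medium and
#' high HDI tiers. HDI enters aggregation only; it is never a regression
#' covariate.
#'
#' @return A tibble with columns `country` and `hdi_group`
#'   (factor: low, medium, high).
#' @export
#' @examples
#' emr_hdi_groups()
emr_hdi_groups <- function() {
  tibble(
    country = c(
      "Afghanistan", "Pakistan", "Iraq", "Morocco", "Yemen",
      "Egypt", "Iran", "Lebanon", "Tunisia", "Jordan",
      "Bahrain", "Kuwait", "Oman", "Qatar", "Saudi Arabia",
      "United Arab Emirates"
    ),
    hdi_group = factor(
      rep(c("low", "medium", "high"), times = c(5, 5, 6)),
      levels = c("low", "medium", "high")
    )
  )
}

#' Tobacco-related cancer sites
#'
#' The 13 anatomical sites causally linked to tobacco smoking that the
#' attribution model covers. Cervical cancer applies to women only.
#'
#' @return Character vector of 13 site names.
#' @export
tobacco_cancer_sites <- function() {
  c(
    "lung", "larynx", "pharynx", "esophagus", "oral cavity", "bladder",
    "leukemia", "stomach", "colorectal", "cervix", "pancreas", "liver",
    "kidney"
  )
}

# sites applicable to a gender (cervix is women-only)
applicable_sites <- function(gender) {
  if (identical(gender, "men")) setdiff(tobacco_cancer_sites(), "cervix")
  else tobacco_cancer_sites()
}

.anchor_years <- seq(2025, 2050, by = 5)
.fit_years_default <- seq(2010, 2020, by = 2)
.baseline_year <- 2025
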