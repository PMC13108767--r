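# I/O and validation for the four input tables: policy panel, incidence
# anchors, relative risks, and HDI grouping. All files are UTF-8 CSV with a
# header row and period decimal separator. Prevalence and literacy are stored
# as percent (0-100) everywhere in the package; conversion to proportions
# happens only inside Levin's formula.

.panel_cols <- c("country", "year", "gender", "prevalence", "mpower",
                 "affordability", "literacy")
.anchor_cols <- c("country", "gender", "site", "year", "cases")
.rr_cols <- c("site", "gender", "rr")

assert_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = "pifcast_schema_error"
    )
  }
  invisible(df)
}

row_label <- function(df) {
  paste0("(", df$country, ", ", df$year,
         if ("gender" %in% names(df)) paste0(", ", df$gender) else "", ")")
}

#' Validate a policy panel
#'
#' Checks the panel invariants: prevalence and literacy in \[0, 100\], MPOWER
#' score in \[7, 34\], affordability non-negative, gender one of men/women,
#' and `(country, year, gender)` unique. Country names are canonicalized.
#' Rows violating an invariant are reported with their `(country, year,
#' gender)` key.
#'
#' @param panel A data frame with columns `country`, `year`, `gender`,
#'   `prevalence`, `mpower`, `affordability`, `literacy`. Policy columns may
#'   be `NA` (the panel may be unbalanced); `prevalence` may not.
#' @return The validated panel as a tibble, with `gender` normalised to
#'   lower case and countries canonical.
#' @export
validate_policy_panel <- function(panel) {
  panel <- as_tibble(panel)
  assert_columns(panel, .panel_cols, "policy panel")
  panel <- panel %>%
    mutate(
      country = canonicalize_country(.data$country),
      gender = tolower(as.character(.data$gender)),
      year = as.integer(.data$year)
    )

  bad <- character(0)
  chk <- function(cond, what) {
    idx <- which(!is.na(cond) & !cond)
    if (length(idx) > 0) {
      bad <<- c(bad, sprintf("%s: %s", what,
                             paste(row_label(panel[idx, ]), collapse = "; ")))
    }
    invisible(NULL)
  }
  if (!all(panel$gender %in% c("men", "women"))) {
    abort("gender must be 'men' or 'women'", class = "pifcast_validation_error")
  }
  if (any(is.na(panel$prevalence))) {
    idx <- which(is.na(panel$prevalence))
    bad <- c(bad, sprintf("prevalence missing: %s",
                          paste(row_label(panel[idx, ]), collapse = "; ")))
  }
  chk(panel$prevalence >= 0 & panel$prevalence <= 100,
      "prevalence outside [0, 100]")
  chk(panel$mpower >= 7 & panel$mpower <= 34, "mpower outside [7, 34]")
  chk(panel$literacy >= 0 & panel$literacy <= 100,
      "literacy outside [0, 100]")
  chk(panel$affordability >= 0, "affordability negative")

  dup <- panel %>%
    count(.data$country, .data$year, .data$gender) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    bad <- c(bad, sprintf("duplicate (country, year, gender): %s",
                          paste(row_label(dup), collapse = "; ")))
  }
  if (length(bad) > 0) {
    abort(c("policy panel failed validation", bad),
          class = "pifcast_validation_error")
  }
  panel
}

#' Read a policy panel from CSV
#'
#' @param path Path to a CSV file with header.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(prevalence = "prev_pct")`. Unmapped columns are used as-is.
#' @return A validated policy panel tibble (see [validate_policy_panel()]).
#' @export
read_policy_panel <- function(path, col_map = NULL) {
  df <- read_input_csv(path, col_map)
  validate_policy_panel(df)
}

read_input_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "pifcast_io_error")
  }
  # base parser: exact (correctly rounded) double parsing for round-trips
  df <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      src <- col_map[[canonical]]
      if (!src %in% names(df)) {
        abort(sprintf("mapped column '%s' (for '%s') not in file",
                      src, canonical),
              class = "pifcast_schema_error")
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  df
}

#' Validate incidence projection anchors
#'
#' Anchors carry projected incident case counts at the six five-year anchor
#' years 2025, 2030, ..., 2050 per `(country, gender, site)` stratum. The
#' grid must be complete: every stratum present must have exactly the six
#' anchor years. Cervix rows must be women-only and counts non-negative.
#'
#' @param anchors Data frame with columns `country`, `gender`, `site`,
#'   `year`, `cases`.
#' @return Validated tibble of anchors.
#' @export
validate_incidence_anchors <- function(anchors) {
  anchors <- as_tibble(anchors)
  assert_columns(anchors, .anchor_cols, "incidence anchors")
  anchors <- anchors %>%
    mutate(
      country = canonicalize_country(.data$country),
      gender = tolower(as.character(.data$gender)),
      site = tolower(as.character(.data$site)),
      year = as.integer(.data$year)
    )
  if (!all(anchors$gender %in% c("men", "women"))) {
    abort("gender must be 'men' or 'women'", class = "pifcast_validation_error")
  }
  if (any(!anchors$year %in% .anchor_years)) {
    abort("anchor years must be in {2025, 2030, 2035, 2040, 2045, 2050}",
          class = "pifcast_validation_error")
  }
  if (any(is.na(anchors$cases) | anchors$cases < 0)) {
    idx <- which(is.na(anchors$cases) | anchors$cases < 0)
    abort(c("negative or missing case counts",
            paste(row_label(anchors[idx, ]), collapse = "; ")),
          class = "pifcast_validation_error")
  }
  cervix_men <- anchors %>%
    filter(.data$site == "cervix", .data$gender == "men")
  if (nrow(cervix_men) > 0) {
    abort("cervix anchors must be women-only",
          class = "pifcast_validation_error")
  }
  missing <- anchor_completeness(anchors)
  if (nrow(missing) > 0) {
    abort(
      c("incomplete anchor grid (all six anchor years required per stratum)",
        sprintf("%s / %s / %s missing year(s) %s",
                missing$country, missing$gender, missing$site,
                missing$missing_years)),
      class = "pifcast_completeness_error"
    )
  }
  anchors
}

# strata with fewer than the six anchor years; empty tibble when complete
anchor_completeness <- function(anchors) {
  anchors %>%
    group_by(.data$country, .data$gender, .data$site) %>%
    summarise(
      missing_years = paste(setdiff(.anchor_years, .data$year),
                            collapse = ", "),
      n_years = n_distinct(.data$year),
      .groups = "drop"
    ) %>%
    filter(.data$n_years != length(.anchor_years)) %>%
    select(-"n_years")
}

#' Read incidence anchors from CSV
#'
#' @inheritParams read_policy_panel
#' @return Validated anchors tibble (see [validate_incidence_anchors()]).
#' @export
read_incidence_anchors <- function(path, col_map = NULL) {
  validate_incidence_anchors(read_input_csv(path, col_map))
}

#' Validate a relative-risk table
#'
#' One row per `(site, gender)` giving the relative risk of that cancer for
#' current versus non-current smoking, with optional 95% CI bounds used by
#' the lognormal RR bootstrap.
#'
#' @param rr Data frame with columns `site`, `gender`, `rr`, and optionally
#'   `ci_low`, `ci_high`.
#' @return Validated tibble.
#' @export
validate_rr_table <- function(rr) {
  rr <- as_tibble(rr)
  assert_columns(rr, .rr_cols, "relative-risk table")
  rr <- rr %>%
    mutate(site = tolower(as.character(.data$site)),
           gender = tolower(as.character(.data$gender)))
  if (!all(rr$gender %in% c("men", "women"))) {
    abort("gender must be 'men' or 'women'", class = "pifcast_validation_error")
  }
  if (any(is.na(rr$rr) | rr$rr <= 0)) {
    abort("relative risks must be > 0", class = "pifcast_validation_error")
  }
  dup <- rr %>% count(.data$site, .data$gender) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(c("duplicate (site, gender) rows in RR table",
            paste(dup$site, dup$gender, sep = "/", collapse = "; ")),
          class = "pifcast_validation_error")
  }
  if (all(c("ci_low", "ci_high") %in% names(rr))) {
    ok <- is.na(rr$ci_low) | is.na(rr$ci_high) |
      (rr$ci_low <= rr$rr & rr$rr <= rr$ci_high)
    if (!all(ok)) {
      abort("RR confidence bounds must bracket the point estimate",
            class = "pifcast_validation_error")
    }
  }
  rr
}

#' Read a relative-risk table from CSV
#'
#' @inheritParams read_policy_panel
#' @return Validated RR tibble (see [validate_rr_table()]).
#' @export
read_rr_table <- function(path, col_map = NULL) {
  validate_rr_table(read_input_csv(path, col_map))
}

#' Look up a relative risk for a stratum
#'
#' Returns `NA` (a "not applicable" signal, not an error) for strata that do
#' not exist by construction, i.e., cervix in men, so aggregation code can
#' skip them.
#'
#' @param rr A validated RR table.
#' @param site,gender Scalar site and gender.
#' @return The relative risk, or `NA_real_` for (cervix, men).
#' @export
rr_lookup <- function(rr, site, gender) {
  site <- tolower(site); gender <- tolower(gender)
  if (site == "cervix" && gender == "men") return(NA_real_)
  hit <- rr$rr[rr$site == site & rr$gender == gender]
  if (length(hit) == 0) {
    abort(sprintf("no relative risk for (%s, %s)", site, gender),
          class = "pifcast_lookup_error")
  }
  hit[[1]]
}

#' Read an HDI grouping table from CSV
#'
#' @inheritParams read_policy_panel
#' @return Tibble with columns `country`, `hdi_group`.
#' @export
read_hdi_groups <- function(path, col_map = NULL) {
  df <- read_input_csv(path, col_map)
  assert_columns(df, c("country", "hdi_group"), "HDI grouping")
  df <- df %>%
    mutate(country = canonicalize_country(.data$country),
           hdi_group = factor(tolower(as.character(.data$hdi_group)),
                              levels = c("low", "medium", "high")))
  if (any(is.na(df$hdi_group))) {
    abort("hdi_group must be one of low/medium/high",
          class = "pifcast_validation_error")
  }
  df
}

#' Write an analysis table to CSV at full precision
#'
#' Numeric fields are serialized with the shortest representation that
#' round-trips bit-for-bit, so `write_table()` then [read_policy_panel()]
#' reproduces a panel exactly.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  out <- x
  for (col in names(out)) {
    v <- out[[col]]
    if (is.double(v)) {
      # 17 significant digits guarantee exact double round-trips
      out[[col]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(x)
}
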