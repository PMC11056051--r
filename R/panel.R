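#' Construct a validated county-year panel
#'
#' A panel is a long-format tibble with one row per county and year and the
#' canonical columns `county_id`, `year`, `category`, `population`, `beds`,
#' `doctors`, `nurses`, `health_practitioners`, `income`, `gdp_per_capita`,
#' `altitude`. `as_panel()` coerces a data frame to this layout, sorts rows by
#' county and year, and aborts on any structural violation (see
#' [validate_panel()] for a non-throwing report).
#'
#' Covariates (`income`, `gdp_per_capita`, `altitude`) may be `NA`: such rows
#' are excluded from regression fits only, never from density or Theil series.
#'
#' @param x A data frame with the canonical columns (extra columns dropped).
#' @param strict If `TRUE` (default) abort when [validate_panel()] finds any
#'   violation; if `FALSE` return the panel with a warning.
#' @return A tibble of class `equipanel_panel`, sorted by `(county_id, year)`.
#' @examples
#' p <- as_panel(data.frame(
#'   county_id = rep(c("a", "b"), each = 2), year = rep(2009:2010, 2),
#'   category = rep(c("Yi", "NMC"), each = 2), population = 1e4,
#'   beds = 30, doctors = 10, nurses = 12, health_practitioners = 30,
#'   income = 3e4, gdp_per_capita = 2e4, altitude = 1500
#' ))
#' nrow(p)
#' @export
as_panel <- function(x, strict = TRUE) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame", class = "equipanel_schema_error")
  }
  missing_cols <- setdiff(PANEL_COLS, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("panel is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "equipanel_schema_error"
    )
  }
  out <- tibble::as_tibble(x)[PANEL_COLS]
  out$county_id <- as.character(out$county_id)
  out$year <- as.integer(out$year)
  out$category <- as.character(out$category)
  bad_cat <- setdiff(unique(out$category), CATEGORY_LEVELS)
  if (length(bad_cat) > 0) {
    abort(
      paste0(
        "unknown category label(s): ", paste(bad_cat, collapse = ", "),
        " (expected ", paste(CATEGORY_LEVELS, collapse = ", "), ")"
      ),
      class = "equipanel_schema_error"
    )
  }
  out <- dplyr::arrange(out, .data$county_id, .data$year)
  report <- validate_panel(out)
  if (nrow(report) > 0) {
    msg <- paste0(
      "panel fails validation (", nrow(report), " finding(s)):\n",
      paste(utils::head(report$message, 5), collapse = "\n")
    )
    if (strict) abort(msg, class = "equipanel_validation_error") else warn(msg)
  }
  class(out) <- c("equipanel_panel", class(out))
  out
}

#' Read a county-year panel from CSV
#'
#' Reads a UTF-8 CSV with a header row, one row per county-year, optionally
#' renaming columns via `schema`, and returns a validated panel.
#'
#' @param path Path to the panel CSV.
#' @param schema Optional named character vector or list mapping canonical
#'   column names to the names used in the file, e.g.
#'   `c(county_id = "county", population = "pop")`. Unmapped canonical names
#'   are looked up directly.
#' @param strict Passed to [as_panel()].
#' @return A validated `equipanel_panel` tibble.
#' @seealso [write_panel()], [read_category_scheme()]
#' @export
read_panel <- function(path, schema = NULL, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("panel file not found: ", path), class = "equipanel_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    schema <- unlist(schema)
    unknown <- setdiff(names(schema), PANEL_COLS)
    if (length(unknown) > 0) {
      abort(
        paste0("schema maps unknown canonical column(s): ", paste(unknown, collapse = ", ")),
        class = "equipanel_schema_error"
      )
    }
    missing_src <- schema[!schema %in% names(raw)]
    if (length(missing_src) > 0) {
      abort(
        paste0(
          "column(s) named in schema not present in file: ",
          paste(missing_src, collapse = ", ")
        ),
        class = "equipanel_schema_error"
      )
    }
    for (canon in names(schema)) names(raw)[names(raw) == schema[[canon]]] <- canon
  }
  missing_cols <- setdiff(PANEL_COLS, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("panel file is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "equipanel_schema_error"
    )
  }
  as_panel(raw, strict = strict)
}

#' Write a panel to CSV with canonical column names
#'
#' @param panel A panel tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(tibble::as_tibble(panel)[PANEL_COLS], path, progress = FALSE)
  invisible(path)
}

#' Read a county-to-category scheme
#'
#' The scheme file is a two-column CSV `county_id, category`. Categories must
#' be drawn from the five-way classification (Yi, Zang, OMC, PSC, NMC) and
#' each county may appear only once (mutual exclusivity; counties that are
#' both ethnic-minority and poverty-stricken are listed under their minority
#' category).
#'
#' @param path Path to the scheme CSV.
#' @return A tibble `(county_id, category)` of class `equipanel_scheme`.
#' @examples
#' f <- system.file("extdata", "sichuan_scheme_synthetic.csv", package = "equipanel")
#' scheme <- read_category_scheme(f)
#' table(scheme$category)
#' @export
read_category_scheme <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("scheme file not found: ", path), class = "equipanel_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("county_id", "category") %in% names(raw))) {
    abort("scheme file must have columns county_id, category",
      class = "equipanel_schema_error"
    )
  }
  out <- tibble::tibble(
    county_id = as.character(raw$county_id),
    category = as.character(raw$category)
  )
  dup <- unique(out$county_id[duplicated(out$county_id)])
  if (length(dup) > 0) {
    abort(
      paste0("county assigned to more than one category: ", paste(dup, collapse = ", ")),
      class = "equipanel_scheme_error"
    )
  }
  bad <- setdiff(unique(out$category), CATEGORY_LEVELS)
  if (length(bad) > 0) {
    abort(
      paste0("unknown category label(s): ", paste(bad, collapse = ", ")),
      class = "equipanel_scheme_error"
    )
  }
  class(out) <- c("equipanel_scheme", class(out))
  out
}

#' Category sizes of a scheme or panel
#'
#' @param x A scheme or panel tibble (anything with `county_id` and
#'   `category` columns).
#' @return A tibble `(category, n_counties)` ordered Yi, Zang, OMC, PSC, NMC.
#' @export
category_sizes <- function(x) {
  x |>
    dplyr::distinct(.data$county_id, .data$category) |>
    dplyr::count(
      category = factor(.data$category, levels = CATEGORY_LEVELS),
      name = "n_counties", .drop = FALSE
    ) |>
    dplyr::mutate(category = as.character(.data$category))
}

#' Validate a county-year panel
#'
#' Checks every structural invariant and returns a report instead of
#' throwing: balance (each county present exactly once in every year of the
#' panel's range), positivity of population, non-negativity and finiteness of
#' counts, practitioner consistency
#' (`health_practitioners >= doctors + nurses`; pharmacists and lab
#' technicians make up the remainder of the workforce), and constancy of each
#' county's category across years.
#'
#' @param panel A data frame with the canonical panel columns.
#' @return A tibble `(check, county_id, year, message)`, one row per finding;
#'   zero rows iff the panel is valid.
#' @export
validate_panel <- function(panel) {
  findings <- list()
  add <- function(check, county_id, year, message) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      check = check, county_id = as.character(county_id),
      year = as.integer(year), message = message
    )
  }

  years <- sort(unique(panel$year))
  full_years <- seq(min(years), max(years))
  counties <- unique(panel$county_id)
  have <- dplyr::count(panel, .data$county_id, .data$year)
  grid <- tidyr::expand_grid(county_id = counties, year = full_years)
  chk <- dplyr::left_join(grid, have, by = c("county_id", "year"))
  miss <- chk[is.na(chk$n), ]
  if (nrow(miss) > 0) {
    for (i in seq_len(nrow(miss))) {
      add(
        "balance", miss$county_id[i], miss$year[i],
        sprintf("county %s missing in year %d", miss$county_id[i], miss$year[i])
      )
    }
  }
  dup <- chk[!is.na(chk$n) & chk$n > 1, ]
  if (nrow(dup) > 0) {
    for (i in seq_len(nrow(dup))) {
      add(
        "balance", dup$county_id[i], dup$year[i],
        sprintf("county %s duplicated in year %d", dup$county_id[i], dup$year[i])
      )
    }
  }

  bad_pop <- which(!is.finite(panel$population) | panel$population <= 0)
  for (i in bad_pop) {
    add(
      "positivity", panel$county_id[i], panel$year[i],
      sprintf("county %s year %d: population must be > 0", panel$county_id[i], panel$year[i])
    )
  }
  for (col in RESOURCE_COLS) {
    v <- panel[[col]]
    bad <- which(!is.finite(v) | v < 0)
    for (i in bad) {
      add(
        "nonnegative_counts", panel$county_id[i], panel$year[i],
        sprintf(
          "county %s year %d: %s must be finite and >= 0",
          panel$county_id[i], panel$year[i], col
        )
      )
    }
  }

  hp_bad <- which(
    is.finite(panel$health_practitioners) & is.finite(panel$doctors) &
      is.finite(panel$nurses) &
      panel$health_practitioners < panel$doctors + panel$nurses
  )
  for (i in hp_bad) {
    add(
      "hp_consistency", panel$county_id[i], panel$year[i],
      sprintf(
        "county %s year %d: health_practitioners (%g) < doctors + nurses (%g)",
        panel$county_id[i], panel$year[i],
        panel$health_practitioners[i], panel$doctors[i] + panel$nurses[i]
      )
    )
  }

  drift <- panel |>
    dplyr::distinct(.data$county_id, .data$category) |>
    dplyr::count(.data$county_id) |>
    dplyr::filter(.data$n > 1)
  for (cid in drift$county_id) {
    add(
      "category_constancy", cid, NA_integer_,
      sprintf("county %s changes category across years", cid)
    )
  }

  if (length(findings) == 0) {
    tibble::tibble(
      check = character(), county_id = character(),
      year = integer(), message = character()
    )
  } else {
    dplyr::bind_rows(findings)
  }
}

#' @export
print.equipanel_panel <- function(x, ...) {
  yrs <- range(x$year)
  cat(sprintf(
    "# County-year panel: %d counties x %d years (%d-%d), %d rows\n",
    dplyr::n_distinct(x$county_id), yrs[2] - yrs[1] + 1, yrs[1], yrs[2], nrow(x)
  ))
  NextMethod()
}
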