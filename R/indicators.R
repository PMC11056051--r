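#' Resource density per 1000 residents
#'
#' @param count Resource count (beds, doctors, nurses or practitioners).
#' @param population Resident population; must be positive.
#' @return `1000 * count / population`, vectorised.
#' @examples
#' density_per_1000(50, 10000) # 5 beds per 1000
#' @export
density_per_1000 <- function(count, population) {
  if (any(!is.finite(population) | population <= 0)) {
    abort("population must be finite and > 0", class = "equipanel_domain_error")
  }
  if (any(is.finite(count) & count < 0)) {
    abort("count must be >= 0", class = "equipanel_domain_error")
  }
  1000 * count / population
}

#' Decade growth rate of a density
#'
#' Relative change `(h_end - h_start) / h_start` of a per-1000 indicator
#' between the first and last year of the study window. A zero starting
#' density has no defined growth and raises an error rather than returning
#' infinity.
#'
#' @param h_start,h_end Densities at the start and end of the window.
#' @return Dimensionless fraction (0.4 means +40%), vectorised.
#' @export
growth_rate <- function(h_start, h_end) {
  if (any(!is.finite(h_start) | h_start <= 0)) {
    abort("growth rate undefined: starting density must be > 0",
      class = "equipanel_domain_error"
    )
  }
  (h_end - h_start) / h_start
}

#' Doctors-and-nurses per bed (staffing intensity)
#'
#' @param doc,nur,bed Per-1000 densities of doctors, nurses and beds.
#' @return `(doc + nur) / bed`, vectorised.
#' @export
dnpb <- function(doc, nur, bed) {
  if (any(!is.finite(bed) | bed <= 0)) {
    abort("bed density must be > 0", class = "equipanel_domain_error")
  }
  (doc + nur) / bed
}

#' Clinical share of the health workforce
#'
#' Doctors plus nurses as a fraction of all health practitioners; at most 1
#' whenever the practitioner count includes the pharmacists and lab
#' technicians it should.
#'
#' @param doc,nur,hp Per-1000 densities of doctors, nurses and all health
#'   practitioners.
#' @return `(doc + nur) / hp`, vectorised.
#' @export
dn_hp <- function(doc, nur, hp) {
  if (any(!is.finite(hp) | hp <= 0)) {
    abort("practitioner density must be > 0", class = "equipanel_domain_error")
  }
  (doc + nur) / hp
}

#' Category density as a percentage of the province average
#'
#' @param category_value,province_value Densities on the same scale.
#' @return `100 * category_value / province_value`, vectorised.
#' @export
ratio_to_province <- function(category_value, province_value) {
  if (any(!is.finite(province_value) | province_value <= 0)) {
    abort("province density must be > 0", class = "equipanel_domain_error")
  }
  100 * category_value / province_value
}

#' Per-county density indicators
#'
#' Computes the four per-1000 densities and the two staffing ratios for every
#' county-year row of the panel.
#'
#' @param panel A panel tibble.
#' @return A tidy tibble `(county_id, category, year, indicator, value)` with
#'   indicators `Bed_p1000`, `Doc_p1000`, `Nur_p1000`, `HP_p1000`, `DNpB`,
#'   `DN_HP` (ratio rows are `NA` where their denominator is zero).
#' @export
county_densities <- function(panel) {
  base <- panel |>
    dplyr::transmute(
      .data$county_id, .data$category, .data$year,
      Bed_p1000 = density_per_1000(.data$beds, .data$population),
      Doc_p1000 = density_per_1000(.data$doctors, .data$population),
      Nur_p1000 = density_per_1000(.data$nurses, .data$population),
      HP_p1000 = density_per_1000(.data$health_practitioners, .data$population)
    ) |>
    dplyr::mutate(
      DNpB = ifelse(.data$Bed_p1000 > 0,
        (.data$Doc_p1000 + .data$Nur_p1000) / .data$Bed_p1000, NA_real_
      ),
      DN_HP = ifelse(.data$HP_p1000 > 0,
        (.data$Doc_p1000 + .data$Nur_p1000) / .data$HP_p1000, NA_real_
      )
    )
  tidyr::pivot_longer(base,
    cols = dplyr::all_of(c(DENSITY_INDICATORS, RATIO_INDICATORS)),
    names_to = "indicator", values_to = "value"
  )
}

# category + province aggregate counts and population per year
aggregate_slice <- function(panel) {
  by_cat <- panel |>
    dplyr::group_by(.data$category, .data$year) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c("population", RESOURCE_COLS)), sum
    ), .groups = "drop")
  prov <- panel |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c("population", RESOURCE_COLS)), sum
    ), .groups = "drop") |>
    dplyr::mutate(category = "Province")
  dplyr::bind_rows(by_cat, prov)
}

#' Category-level (and province) densities for one indicator
#'
#' Two estimands are available. `aggregate` is the population-weighted level:
#' 1000 times the summed counts over the category's counties divided by their
#' summed population (the province row uses all counties). `mean_of_counties`
#' is the unweighted mean of the county densities, the estimand behind
#' "mean growth rate" style summaries.
#'
#' @param panel A panel tibble.
#' @param indicator One of `"Bed_p1000"`, `"Doc_p1000"`, `"Nur_p1000"`,
#'   `"HP_p1000"`, `"DNpB"`, `"DN_HP"`.
#' @param years Years to include; default all panel years.
#' @param method `"aggregate"` (default) or `"mean_of_counties"`.
#' @return A tibble `(category, year, indicator, method, value)` including a
#'   `"Province"` pseudo-category.
#' @export
category_density <- function(panel, indicator = "Bed_p1000", years = NULL,
                             method = c("aggregate", "mean_of_counties")) {
  method <- match.arg(method)
  indicator <- match.arg(indicator, c(DENSITY_INDICATORS, RATIO_INDICATORS))
  if (is.null(years)) years <- sort(unique(panel$year))
  if (!all(years %in% panel$year)) {
    abort("requested year(s) outside panel range", class = "equipanel_domain_error")
  }
  panel <- dplyr::filter(panel, .data$year %in% years)

  if (method == "aggregate") {
    agg <- aggregate_slice(panel)
    value <- switch(indicator,
      DNpB = {
        if (any(agg$beds <= 0)) {
          abort("aggregate bed count is zero", class = "equipanel_domain_error")
        }
        (agg$doctors + agg$nurses) / agg$beds
      },
      DN_HP = {
        if (any(agg$health_practitioners <= 0)) {
          abort("aggregate practitioner count is zero", class = "equipanel_domain_error")
        }
        (agg$doctors + agg$nurses) / agg$health_practitioners
      },
      density_per_1000(agg[[indicator_resource(indicator)]], agg$population)
    )
    out <- tibble::tibble(
      category = agg$category, year = agg$year,
      indicator = indicator, method = method, value = value
    )
  } else {
    cd <- county_densities(panel) |>
      dplyr::filter(.data$indicator == !!indicator)
    by_cat <- cd |>
      dplyr::group_by(.data$category, .data$year) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
    prov <- cd |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(category = "Province")
    out <- dplyr::bind_rows(by_cat, prov) |>
      dplyr::mutate(indicator = indicator, method = method) |>
      dplyr::select("category", "year", "indicator", "method", "value")
  }
  dplyr::arrange(out, .data$year, .data$category)
}

#' Full indicator series at category and province level
#'
#' @param panel A panel tibble.
#' @param method Density method passed to [category_density()].
#' @return A tidy tibble `(category, year, indicator, method, value)` over
#'   all six indicators.
#' @export
indicator_series <- function(panel, method = c("aggregate", "mean_of_counties")) {
  method <- match.arg(method)
  purrr::map_dfr(
    c(DENSITY_INDICATORS, RATIO_INDICATORS),
    function(ind) category_density(panel, ind, method = method)
  )
}

#' Per-county decade growth of a density indicator
#'
#' @param panel A panel tibble spanning at least two years.
#' @param indicator A density indicator name.
#' @return A tibble `(county_id, category, h_start, h_end, growth)` using the
#'   panel's first and last year.
#' @export
county_growth <- function(panel, indicator = "Bed_p1000") {
  yrs <- range(panel$year)
  if (yrs[1] == yrs[2]) {
    abort("growth needs a panel spanning >= 2 years", class = "equipanel_domain_error")
  }
  res <- indicator_resource(indicator)
  wide <- panel |>
    dplyr::filter(.data$year %in% yrs) |>
    dplyr::mutate(density = density_per_1000(.data[[res]], .data$population)) |>
    dplyr::select("county_id", "category", "year", "density") |>
    tidyr::pivot_wider(names_from = "year", values_from = "density")
  h0 <- wide[[as.character(yrs[1])]]
  h1 <- wide[[as.character(yrs[2])]]
  tibble::tibble(
    county_id = wide$county_id, category = wide$category,
    h_start = h0, h_end = h1, growth = growth_rate(h0, h1)
  )
}

# strict "lower than the province average" with a tolerance so that exact
# ties do not flip on floating-point noise (ties count as not-lower)
strictly_below <- function(a, b) (b - a) > 1e-9 * pmax(1, abs(b))

#' Share of a category's counties satisfying a growth predicate
#'
#' For each category, the fraction of its counties whose county-level decade
#' growth in `indicator` is negative (`"negative_growth"`) or strictly lower
#' than the province aggregate growth (`"growth_below_province"`; ties count
#' as not-lower).
#'
#' @param panel A panel tibble spanning at least two years.
#' @param indicator A density indicator name.
#' @param predicate `"negative_growth"` or `"growth_below_province"`.
#' @return A tibble `(category, indicator, predicate, n_counties, n_true,
#'   share)` with `share` in `[0, 1]`.
#' @export
share_of_counties <- function(panel, indicator = "Doc_p1000",
                              predicate = c("negative_growth", "growth_below_province")) {
  predicate <- match.arg(predicate)
  cg <- county_growth(panel, indicator)
  if (predicate == "negative_growth") {
    cg$hit <- cg$growth < 0
  } else {
    prov <- category_density(panel, indicator, method = "aggregate") |>
      dplyr::filter(.data$category == "Province")
    yrs <- range(panel$year)
    g_prov <- growth_rate(
      prov$value[prov$year == yrs[1]], prov$value[prov$year == yrs[2]]
    )
    cg$hit <- strictly_below(cg$growth, g_prov)
  }
  cg |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_counties = dplyr::n(), n_true = sum(.data$hit),
      share = mean(.data$hit), .groups = "drop"
    ) |>
    dplyr::mutate(indicator = indicator, predicate = predicate) |>
    dplyr::select(
      "category", "indicator", "predicate", "n_counties", "n_true", "share"
    )
}

#' Growth summary per category
#'
#' For each density indicator and category: the decade growth of the
#' category aggregate density, the mean of county-level growths, and the
#' shares of counties with negative growth or growth strictly below the
#' province aggregate. Headline growth figures use the aggregate variant;
#' the county-mean variant backs distributional statements.
#'
#' @param panel A panel tibble spanning at least two years.
#' @param indicators Density indicators to summarise.
#' @return A tibble `(indicator, category, aggregate_growth,
#'   mean_county_growth, share_negative, share_below_province)` including a
#'   `"Province"` row (whose shares are computed over all counties).
#' @export
growth_summary <- function(panel,
                           indicators = c("Bed_p1000", "Doc_p1000", "Nur_p1000")) {
  yrs <- range(panel$year)
  purrr::map_dfr(indicators, function(ind) {
    agg <- category_density(panel, ind, method = "aggregate")
    agg_growth <- agg |>
      tidyr::pivot_wider(names_from = "year", values_from = "value") |>
      dplyr::mutate(aggregate_growth = growth_rate(
        .data[[as.character(yrs[1])]], .data[[as.character(yrs[2])]]
      )) |>
      dplyr::select("category", "aggregate_growth")
    cg <- county_growth(panel, ind)
    g_prov <- agg_growth$aggregate_growth[agg_growth$category == "Province"]
    per_cat <- cg |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(
        mean_county_growth = mean(.data$growth),
        share_negative = mean(.data$growth < 0),
        share_below_province = mean(strictly_below(.data$growth, g_prov)),
        .groups = "drop"
      )
    prov_row <- tibble::tibble(
      category = "Province",
      mean_county_growth = mean(cg$growth),
      share_negative = mean(cg$growth < 0),
      share_below_province = mean(strictly_below(cg$growth, g_prov))
    )
    dplyr::bind_rows(per_cat, prov_row) |>
      dplyr::left_join(agg_growth, by = "category") |>
      dplyr::mutate(indicator = ind) |>
      dplyr::select(
        "indicator", "category", "aggregate_growth", "mean_county_growth",
        "share_negative", "share_below_province"
      )
  })
}
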