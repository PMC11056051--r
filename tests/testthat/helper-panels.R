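# small in-code panel builders used across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

# balanced panel from explicit per-county densities (per 1000), constant population
make_panel <- function(counties, years = 2009:2010,
                       pop = 10000,
                       bed_dens = 3, doc_dens = 1.5, nur_dens = 1,
                       categories = NULL, hp_factor = 1.5) {
  n <- length(counties)
  rep_n <- function(x) rep(x, length.out = n)
  categories <- categories %||% rep_n(c("Yi", "NMC"))
  df <- tidyr::expand_grid(county_id = counties, year = years) |>
    dplyr::mutate(
      category = rep(categories, each = length(years)),
      population = rep(rep_n(pop), each = length(years)),
      beds = rep(rep_n(bed_dens), each = length(years)) * population / 1000,
      doctors = rep(rep_n(doc_dens), each = length(years)) * population / 1000,
      nurses = rep(rep_n(nur_dens), each = length(years)) * population / 1000,
      health_practitioners = (doctors + nurses) * hp_factor,
      income = 30000, gdp_per_capita = 20000, altitude = 1000
    )
  as_panel(df)
}

# homogeneous-category config: no category structure in densities, incomes
# or altitudes, so covariates are independent of densities under zero effects
flat_config <- function(years = 2009:2010, noise_cv = 0, frailty_sdlog = 0.25,
                        effects = list(
                          altitude = c(doctors = 0, nurses = 0),
                          income = c(doctors = 0, nurses = 0)
                        ),
                        ...) {
  eq <- function(v) setNames(rep(v, 5), c("Yi", "Zang", "OMC", "PSC", "NMC"))
  synthetic_config(
    years = years,
    baseline = list(beds = eq(3), doctors = eq(1.5), nurses = eq(1.2)),
    growth = list(beds = eq(0.5), doctors = eq(0.4), nurses = eq(0.6)),
    covariates = list(
      income = list(level = eq(30000), annual_growth = 0.08, sdlog = 0.15),
      gdp_per_capita = list(level = eq(20000), annual_growth = 0.09, sdlog = 0.25),
      altitude = list(level = eq(1500), sdlog = 0.20)
    ),
    noise_cv = noise_cv, frailty_sdlog = frailty_sdlog, effects = effects,
    ...
  )
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
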