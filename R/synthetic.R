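#' Configuration for the synthetic county-panel generator
#'
#' Describes a Sichuan-shaped balanced panel: five county categories with
#' fixed sizes, an eleven-year window, per-category baseline densities (per
#' 1000 residents) and total decade growth for beds, doctors and nurses,
#' log-normal county populations with a common annual growth rate, a
#' log-normal county frailty (a time-constant multiplier on each county's
#' densities), i.i.d. multiplicative year noise on counts, a practitioner
#' overhead share (pharmacists and lab technicians as a fraction of all
#' health practitioners), per-category covariate models (income, GDP per
#' capita, altitude), optional linear covariate-to-density effects, and an
#' optional negative-growth injection that forces a chosen fraction of a
#' category's counties to a fixed negative decade growth while compensating
#' the remaining counties so the category aggregate growth stays at its
#' configured value.
#'
#' Defaults encode the study conditions of the Sichuan 2009-2019 decade:
#' category sizes 12/32/23/32/82 (Yi/Zang/OMC/PSC/NMC), the published decade
#' growth percentages where available, and category mean altitudes of
#' 2139 m (Yi), 3656 m (Zang) and 1592 m (OMC).
#'
#' @param n_counties Named integer vector of counties per category.
#' @param years Integer vector of consecutive panel years.
#' @param baseline Named list `beds`/`doctors`/`nurses` of per-category
#'   2009 densities (per 1000).
#' @param growth Named list `beds`/`doctors`/`nurses` of per-category total
#'   decade growth fractions (0.4 = +40%); each must exceed -1.
#' @param population `list(meanlog, sdlog, annual_growth)` for county
#'   populations (log-normal baseline, common geometric growth).
#' @param frailty_sdlog Standard deviation (log scale) of the per-county,
#'   per-resource density multiplier; 0 disables county heterogeneity.
#' @param noise_cv Coefficient of variation of the mean-one log-normal
#'   multiplicative noise applied to each county-year-resource count.
#' @param hp_overhead Length-2 range of the pharmacist/technician share of
#'   all practitioners, drawn uniformly per county (default `c(0.16, 0.31)`).
#' @param covariates `list(income = list(level, annual_growth, sdlog),
#'   gdp_per_capita = list(level, annual_growth, sdlog),
#'   altitude = list(level, sdlog))`, levels being per-category vectors.
#' @param effects `list(altitude = c(doctors=, nurses=), income = c(...))`:
#'   linear density change per covariate unit. The altitude effect ramps
#'   linearly from zero in the first year to its full value in the last
#'   (altitude gradients in the study decade emerged over time); the income
#'   effect applies uniformly, on income centred within each year.
#' @param negative_growth Optional injection, e.g.
#'   `list(doctors = list(share = c(Yi = 1/3, Zang = 1/2), value = -0.10))`:
#'   per resource, the fraction of each named category's counties (rounded
#'   to a whole count) forced to decade growth `value`.
#' @param integer_counts Round counts to integers (default `TRUE`; yearbook
#'   counts are integers).
#' @param count_floor Minimum count after rounding for beds/doctors/nurses
#'   (default 1, which keeps the Theil index finite; set 0 to exercise the
#'   divergence path).
#' @return A validated list of class `equipanel_config`.
#' @seealso [paperlike_config()], [generate_panel()]
#' @export
synthetic_config <- function(
    n_counties = c(Yi = 12, Zang = 32, OMC = 23, PSC = 32, NMC = 82),
    years = 2009:2019,
    baseline = list(
      beds = c(Yi = 1.50, Zang = 2.00, OMC = 2.00, PSC = 2.20, NMC = 3.00),
      doctors = c(Yi = 0.90, Zang = 1.10, OMC = 1.20, PSC = 1.30, NMC = 1.80),
      nurses = c(Yi = 0.55, Zang = 0.70, OMC = 0.75, PSC = 0.90, NMC = 1.40)
    ),
    growth = list(
      beds = c(Yi = 1.40, Zang = 0.95, OMC = 1.27, PSC = 1.30, NMC = 1.21),
      doctors = c(Yi = 0.20, Zang = 0.11, OMC = 0.75, PSC = 0.70, NMC = 0.61),
      nurses = c(Yi = 2.40, Zang = 1.20, OMC = 3.16, PSC = 2.60, NMC = 1.98)
    ),
    population = list(meanlog = 12.4, sdlog = 0.5, annual_growth = 0.005),
    frailty_sdlog = 0.25,
    noise_cv = 0.05,
    hp_overhead = c(0.16, 0.31),
    covariates = list(
      income = list(
        level = c(Yi = 28000, Zang = 35000, OMC = 30000, PSC = 30000, NMC = 40000),
        annual_growth = 0.08, sdlog = 0.15
      ),
      gdp_per_capita = list(
        level = c(Yi = 12000, Zang = 14000, OMC = 15000, PSC = 13000, NMC = 30000),
        annual_growth = 0.09, sdlog = 0.25
      ),
      altitude = list(
        level = c(Yi = 2139, Zang = 3656, OMC = 1592, PSC = 900, NMC = 600),
        sdlog = 0.20
      )
    ),
    effects = list(
      altitude = c(doctors = 0, nurses = 0),
      income = c(doctors = 0, nurses = 0)
    ),
    negative_growth = list(),
    integer_counts = TRUE,
    count_floor = 1) {
  cfg <- list(
    n_counties = n_counties, years = as.integer(years), baseline = baseline,
    growth = growth, population = population, frailty_sdlog = frailty_sdlog,
    noise_cv = noise_cv, hp_overhead = hp_overhead, covariates = covariates,
    effects = effects, negative_growth = negative_growth,
    integer_counts = integer_counts, count_floor = count_floor
  )
  validate_config(cfg)
  structure(cfg, class = "equipanel_config")
}

validate_config <- function(cfg) {
  stop_cfg <- function(msg) abort(msg, class = "equipanel_config_error")
  if (is.null(names(cfg$n_counties)) ||
    !setequal(names(cfg$n_counties), CATEGORY_LEVELS)) {
    stop_cfg("n_counties must be named with the five categories")
  }
  if (any(cfg$n_counties < 1)) stop_cfg("every category needs >= 1 county")
  if (length(cfg$years) < 2 || any(diff(cfg$years) != 1)) {
    stop_cfg("years must be >= 2 consecutive integers")
  }
  for (r in c("beds", "doctors", "nurses")) {
    b <- cfg$baseline[[r]]
    g <- cfg$growth[[r]]
    if (is.null(b) || !setequal(names(b), CATEGORY_LEVELS) || any(b <= 0)) {
      stop_cfg(paste0("baseline$", r, " must be positive and cover all categories"))
    }
    if (is.null(g) || !setequal(names(g), CATEGORY_LEVELS) || any(g <= -1)) {
      stop_cfg(paste0("growth$", r, " must exceed -1 and cover all categories"))
    }
  }
  if (cfg$noise_cv < 0) stop_cfg("noise_cv must be >= 0")
  if (cfg$frailty_sdlog < 0) stop_cfg("frailty_sdlog must be >= 0")
  if (length(cfg$hp_overhead) != 2 || cfg$hp_overhead[1] > cfg$hp_overhead[2] ||
    cfg$hp_overhead[1] < 0 || cfg$hp_overhead[2] >= 1) {
    stop_cfg("hp_overhead must be an increasing range inside [0, 1)")
  }
  for (r in names(cfg$negative_growth)) {
    inj <- cfg$negative_growth[[r]]
    if (!r %in% c("beds", "doctors", "nurses")) stop_cfg("negative_growth: unknown resource")
    if (is.null(inj$share) || is.null(inj$value) || inj$value <= -1 || inj$value >= 0) {
      stop_cfg("negative_growth entries need share (named) and value in (-1, 0)")
    }
    if (!all(names(inj$share) %in% CATEGORY_LEVELS)) {
      stop_cfg("negative_growth share names must be categories")
    }
  }
  invisible(cfg)
}

#' Study-decade configuration with published growth figures
#'
#' The packaged configuration whose noise-free category aggregate growths
#' equal the published decade percentages (beds: Yi 140%, OMC 127%, NMC
#' 121%; doctors: Yi 20%, Zang 11%, NMC 61%; nurses: Yi 240%, OMC 316%, NMC
#' 198%) and which injects negative doctor growth into 1/3 of Yi and 1/2 of
#' Zang counties. Categories without a published figure carry values chosen
#' to match the decade's qualitative record (Zang lowest growth throughout;
#' OMC and PSC above the province average). Noise is off by default so a
#' single run reproduces the configured growths up to count rounding.
#'
#' @param noise_cv Count noise coefficient of variation (default 0).
#' @param ... Further overrides passed to [synthetic_config()].
#' @return An `equipanel_config`.
#' @export
paperlike_config <- function(noise_cv = 0, ...) {
  synthetic_config(
    noise_cv = noise_cv,
    negative_growth = list(
      doctors = list(share = c(Yi = 1 / 3, Zang = 1 / 2), value = -0.10)
    ),
    ...
  )
}

# deterministic per-county substream seed: depends only on the root seed,
# the category and the county's index within it, so adding counties to one
# category never perturbs another county's draws
county_seed <- function(root, cat_index, within_index) {
  (root + cat_index * 1000003 + within_index * 7919) %% 2147483562L + 1L
}

#' Generate a synthetic county-year panel with ground truth
#'
#' Deterministic for a fixed seed. County densities follow the category's
#' noise-free geometric trajectory times a county frailty, plus optional
#' covariate effects, times mean-one multiplicative year noise; counts are
#' rounded to integers with a floor (see [synthetic_config()]). Health
#' practitioners are doctors plus nurses inflated by the county's overhead
#' share. The returned ground truth records the noise-free category
#' aggregate densities and growths, the counties flagged for negative
#' growth, and the injected covariate effect slopes.
#'
#' @param config An `equipanel_config`.
#' @param seed Integer root seed; per-county substreams are derived from it.
#' @return A list of class `equipanel_synthesis` with elements `panel` (a
#'   validated panel tibble) and `truth` (list: `category_density`,
#'   `growth`, `negative_share`, `flags`, `effects`, `seed`).
#' @examples
#' syn <- generate_panel(paperlike_config(), seed = 42)
#' dplyr::n_distinct(syn$panel$county_id)
#' @export
generate_panel <- function(config, seed = 1) {
  validate_config(config)
  seed <- as.integer(seed)
  years <- config$years
  t0 <- years[1]
  span <- years[length(years)] - t0
  resources <- c("beds", "doctors", "nurses")

  counties <- purrr::imap_dfr(
    seq_along(CATEGORY_LEVELS) |> setNames(CATEGORY_LEVELS),
    function(ci, cat) {
      n <- config$n_counties[[cat]]
      tibble::tibble(
        county_id = sprintf("%s_%03d", cat, seq_len(n)),
        category = cat, cat_index = ci, within = seq_len(n)
      )
    }
  )

  # root-stream draws: negative-growth flag assignment
  flags <- tibble::tibble(
    resource = character(), county_id = character()
  )
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()),
    add = TRUE
  )
  set.seed(seed)
  for (r in names(config$negative_growth)) {
    inj <- config$negative_growth[[r]]
    for (cat in names(inj$share)) {
      ids <- counties$county_id[counties$category == cat]
      n_flag <- round(inj$share[[cat]] * length(ids))
      if (n_flag > 0) {
        flags <- dplyr::bind_rows(flags, tibble::tibble(
          resource = r, county_id = sort(sample(ids, n_flag))
        ))
      }
    }
  }

  # per-county substream draws, in a fixed order
  sigma_noise <- sqrt(log(1 + config$noise_cv^2))
  n_years <- length(years)
  draws <- purrr::pmap_dfr(
    counties,
    function(county_id, category, cat_index, within) {
      set.seed(county_seed(seed, cat_index, within))
      pop0 <- exp(stats::rnorm(1, config$population$meanlog, config$population$sdlog))
      frailty <- exp(stats::rnorm(3, 0, config$frailty_sdlog)) |> setNames(resources)
      overhead <- stats::runif(1, config$hp_overhead[1], config$hp_overhead[2])
      inc_jit <- exp(stats::rnorm(1, 0, config$covariates$income$sdlog))
      gdp_jit <- exp(stats::rnorm(1, 0, config$covariates$gdp_per_capita$sdlog))
      alt_jit <- exp(stats::rnorm(1, 0, config$covariates$altitude$sdlog))
      noise <- if (sigma_noise > 0) {
        exp(stats::rnorm(3 * n_years, -sigma_noise^2 / 2, sigma_noise))
      } else {
        rep(1, 3 * n_years)
      }
      tibble::tibble(
        county_id = county_id, category = category,
        pop0 = pop0, overhead = overhead,
        frailty_beds = frailty[["beds"]], frailty_doctors = frailty[["doctors"]],
        frailty_nurses = frailty[["nurses"]],
        inc_jit = inc_jit, gdp_jit = gdp_jit, alt_jit = alt_jit,
        noise = list(matrix(noise, nrow = n_years, ncol = 3,
          dimnames = list(NULL, resources)
        ))
      )
    }
  )

  # per-county decade growth, with aggregate-preserving compensation for
  # negative-growth injection (weights are baseline counts)
  county_growth_tbl <- purrr::map_dfr(resources, function(r) {
    out <- tibble::tibble(
      resource = r, county_id = draws$county_id,
      g = config$growth[[r]][draws$category]
    )
    inj <- config$negative_growth[[r]]
    if (!is.null(inj)) {
      flagged_ids <- flags$county_id[flags$resource == r]
      for (cat in names(inj$share)) {
        in_cat <- draws$category == cat
        w <- config$baseline[[r]][[cat]] *
          draws[[paste0("frailty_", r)]][in_cat] * draws$pop0[in_cat]
        ids <- draws$county_id[in_cat]
        is_f <- ids %in% flagged_ids
        if (any(is_f) && any(!is_f)) {
          G <- config$growth[[r]][[cat]]
          g_adj <- ((1 + G) * sum(w) - (1 + inj$value) * sum(w[is_f])) /
            sum(w[!is_f]) - 1
          if (g_adj <= -1) {
            abort("negative_growth injection infeasible: compensated growth <= -1",
              class = "equipanel_config_error"
            )
          }
          out$g[out$county_id %in% ids[is_f]] <- inj$value
          out$g[out$county_id %in% ids[!is_f]] <- g_adj
        }
      }
    }
    out
  })

  # assemble county-year rows
  grid <- tidyr::expand_grid(county_id = draws$county_id, year = years) |>
    dplyr::left_join(draws, by = "county_id") |>
    dplyr::mutate(
      frac = (.data$year - t0) / span,
      population = pmax(round(.data$pop0 *
        (1 + config$population$annual_growth)^(.data$year - t0)), 1),
      income = config$covariates$income$level[.data$category] * .data$inc_jit *
        (1 + config$covariates$income$annual_growth)^(.data$year - t0),
      gdp_per_capita = config$covariates$gdp_per_capita$level[.data$category] *
        .data$gdp_jit *
        (1 + config$covariates$gdp_per_capita$annual_growth)^(.data$year - t0),
      altitude = config$covariates$altitude$level[.data$category] * .data$alt_jit
    )

  alt_centered <- grid$altitude - mean(draws$alt_jit *
    config$covariates$altitude$level[draws$category])
  inc_center <- stats::ave(grid$income, grid$year)

  density_of <- function(r, noisy) {
    gw <- county_growth_tbl$g[county_growth_tbl$resource == r]
    names(gw) <- county_growth_tbl$county_id[county_growth_tbl$resource == r]
    d <- config$baseline[[r]][grid$category] *
      grid[[paste0("frailty_", r)]] *
      (1 + gw[grid$county_id])^grid$frac
    eff_a <- config$effects$altitude
    eff_i <- config$effects$income
    if (r %in% names(eff_a) && eff_a[[r]] != 0) {
      d <- d + eff_a[[r]] * alt_centered * grid$frac
    }
    if (r %in% names(eff_i) && eff_i[[r]] != 0) {
      d <- d + eff_i[[r]] * (grid$income - inc_center)
    }
    d <- pmax(d, 0.02) # density floor after additive effects
    if (noisy && sigma_noise > 0) {
      yi <- grid$year - t0 + 1
      d <- d * vapply(
        seq_len(nrow(grid)),
        function(k) grid$noise[[k]][yi[k], r], numeric(1)
      )
    }
    unname(d)
  }

  counts_of <- function(d) {
    cnt <- d * grid$population / 1000
    if (config$integer_counts) pmax(round(cnt), config$count_floor) else cnt
  }

  dens_free <- lapply(setNames(resources, resources), density_of, noisy = FALSE)
  cnt <- lapply(setNames(resources, resources), function(r) {
    counts_of(density_of(r, noisy = TRUE))
  })

  hp_raw <- (cnt$doctors + cnt$nurses) / (1 - grid$overhead)
  hp <- if (config$integer_counts) ceiling(hp_raw) else hp_raw

  panel <- tibble::tibble(
    county_id = grid$county_id, year = grid$year, category = grid$category,
    population = grid$population,
    beds = cnt$beds, doctors = cnt$doctors, nurses = cnt$nurses,
    health_practitioners = hp,
    income = grid$income, gdp_per_capita = grid$gdp_per_capita,
    altitude = grid$altitude
  ) |> as_panel()

  # ground truth from the noise-free, pre-rounding trajectories
  truth_cat <- purrr::map_dfr(resources, function(r) {
    tibble::tibble(
      resource = r, category = grid$category, year = grid$year,
      cnt = dens_free[[r]] * grid$population / 1000, pop = grid$population
    ) |>
      dplyr::group_by(.data$resource, .data$category, .data$year) |>
      dplyr::summarise(
        value = 1000 * sum(.data$cnt) / sum(.data$pop), .groups = "drop"
      )
  })
  truth_growth <- truth_cat |>
    dplyr::filter(.data$year %in% range(years)) |>
    tidyr::pivot_wider(names_from = "year", values_from = "value") |>
    dplyr::mutate(growth = growth_rate(
      .data[[as.character(years[1])]], .data[[as.character(years[length(years)])]]
    )) |>
    dplyr::select("resource", "category", "growth")
  truth_share <- purrr::map_dfr(resources, function(r) {
    fl <- flags$county_id[flags$resource == r]
    counties |>
      dplyr::group_by(category = .data$category) |>
      dplyr::summarise(
        n_counties = dplyr::n(),
        n_flagged = sum(.data$county_id %in% fl),
        share = mean(.data$county_id %in% fl), .groups = "drop"
      ) |>
      dplyr::mutate(resource = r) |>
      dplyr::select("resource", "category", "n_counties", "n_flagged", "share")
  })

  structure(
    list(
      panel = panel,
      truth = list(
        seed = seed,
        category_density = truth_cat,
        growth = truth_growth,
        negative_share = truth_share,
        flags = flags,
        effects = config$effects
      ),
      config = config
    ),
    class = "equipanel_synthesis"
  )
}

#' @export
print.equipanel_synthesis <- function(x, ...) {
  cat(sprintf(
    "Synthetic panel (seed %d): %d counties x %d years\n",
    x$truth$seed, dplyr::n_distinct(x$panel$county_id),
    dplyr::n_distinct(x$panel$year)
  ))
  invisible(x)
}
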