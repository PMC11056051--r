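test_that("generation is deterministic for a fixed seed", {
  a <- generate_panel(paperlike_config(noise_cv = 0.05), seed = 42)
  b <- generate_panel(paperlike_config(noise_cv = 0.05), seed = 42)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$growth, b$truth$growth)
  c <- generate_panel(paperlike_config(noise_cv = 0.05), seed = 43)
  expect_false(identical(a$panel, c$panel))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(generate_panel(flat_config(), seed = 5))
  expect_identical(runif(1), before)
})

test_that("noise-free densities follow the ground-truth trajectories", {
  cfg <- flat_config(years = 2009:2019, noise_cv = 0, frailty_sdlog = 0)
  syn <- generate_panel(cfg, seed = 10)
  cd <- county_densities(syn$panel)
  beds <- cd[cd$indicator == "Bed_p1000", ]
  pop <- syn$panel$population[match(
    paste(beds$county_id, beds$year),
    paste(syn$panel$county_id, syn$panel$year)
  )]
  expected <- 3 * 1.5^((beds$year - 2009) / 10)
  # counts are integer-rounded: densities match within 1 count's worth
  expect_true(all(abs(beds$value - expected) <= 1000 / pop))
})

test_that("aggregate growth equals the configured value exactly when noise is off", {
  syn <- generate_panel(paperlike_config(), seed = 6)
  gs <- growth_summary(syn$panel)
  cfg <- paperlike_config()
  for (ind in c("Bed_p1000", "Doc_p1000", "Nur_p1000")) {
    res <- c(Bed_p1000 = "beds", Doc_p1000 = "doctors", Nur_p1000 = "nurses")[[ind]]
    for (cat in names(cfg$growth[[res]])) {
      got <- gs$aggregate_growth[gs$indicator == ind & gs$category == cat]
      expect_equal(got, cfg$growth[[res]][[cat]], tolerance = 0.01, info = paste(ind, cat))
    }
  }
  # recorded ground truth matches the configured value up to the integer
  # rounding of yearly populations
  tg <- syn$truth$growth
  expect_equal(
    tg$growth[tg$resource == "beds" & tg$category == "Yi"], 1.40,
    tolerance = 1e-4
  )
})

test_that("practitioner overhead share stays inside the configured band", {
  syn <- generate_panel(paperlike_config(noise_cv = 0.05), seed = 12)
  p <- syn$panel
  share <- 1 - (p$doctors + p$nurses) / p$health_practitioners
  # ceiling-rounding of practitioner counts can only push the share up a hair
  expect_true(all(share >= 0.16 - 1e-9))
  expect_true(all(share <= 0.31 + p$health_practitioners^-1 + 1e-9))
})

test_that("negative-growth flags are honoured and compensated", {
  syn <- generate_panel(paperlike_config(), seed = 3)
  flags <- syn$truth$flags
  expect_equal(sum(flags$resource == "doctors"), 4 + 16)
  cg <- county_growth(syn$panel, "Doc_p1000")
  flagged <- cg$growth[cg$county_id %in% flags$county_id]
  unflagged_yi <- cg$growth[cg$category == "Yi" & !cg$county_id %in% flags$county_id]
  expect_true(all(flagged < 0))
  expect_true(all(unflagged_yi > 0))
})

test_that("county substreams are stable when another category grows", {
  base <- generate_panel(flat_config(), seed = 9)$panel
  bigger_cfg <- flat_config()
  bigger_cfg$n_counties[["NMC"]] <- 90
  bigger <- generate_panel(bigger_cfg, seed = 9)$panel
  yi_base <- base[base$category == "Yi", ]
  yi_big <- bigger[bigger$category == "Yi", ]
  expect_identical(yi_base, yi_big)
})

test_that("identical per-capita densities give a numerically zero Theil series", {
  cfg <- flat_config(
    years = 2009:2019, noise_cv = 0, frailty_sdlog = 0,
    integer_counts = FALSE
  )
  syn <- generate_panel(cfg, seed = 14)
  s <- theil_series(syn$panel)
  expect_true(all(s$ti < 1e-6))
})

test_that("count floor keeps the Theil series finite, and floor 0 exposes divergence", {
  cfg <- flat_config(noise_cv = 0.05)
  cfg$baseline <- lapply(cfg$baseline, function(x) x * 0 + 0.05) # sparse counts
  cfg$population$meanlog <- 8.5 # small counties so counts round to 0 or 1
  syn <- generate_panel(cfg, seed = 2)
  expect_true(all(syn$panel$doctors >= 1))
  expect_error(theil_series(syn$panel, "doctors"), NA)

  cfg0 <- cfg
  cfg0$count_floor <- 0
  syn0 <- generate_panel(cfg0, seed = 2)
  expect_true(any(syn0$panel$doctors == 0))
  expect_error(theil_series(syn0$panel, "doctors"),
    class = "equipanel_divergence_error"
  )
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(synthetic_config(noise_cv = -0.1), class = "equipanel_config_error")
  expect_error(synthetic_config(hp_overhead = c(0.4, 0.2)), class = "equipanel_config_error")
  expect_error(
    synthetic_config(growth = list(
      beds = c(Yi = -1.5, Zang = 1, OMC = 1, PSC = 1, NMC = 1),
      doctors = c(Yi = 1, Zang = 1, OMC = 1, PSC = 1, NMC = 1),
      nurses = c(Yi = 1, Zang = 1, OMC = 1, PSC = 1, NMC = 1)
    )),
    class = "equipanel_config_error"
  )
  expect_error(
    synthetic_config(negative_growth = list(doctors = list(share = c(Yi = 0.5), value = 0.2))),
    class = "equipanel_config_error"
  )
  cfg <- flat_config()
  cfg$years <- c(2009L, 2011L)
  expect_error(generate_panel(cfg, seed = 1), class = "equipanel_config_error")
})

test_that("an injected altitude effect is recovered by the cross-section fit", {
  # homogeneous categories, additive negative altitude slope at full ramp
  ok <- vapply(1:10, function(s) {
    cfg <- flat_config(
      years = 2009:2010, noise_cv = 0.02,
      effects = list(
        altitude = c(doctors = -4e-4, nurses = 0),
        income = c(doctors = 0, nurses = 0)
      )
    )
    syn <- generate_panel(cfg, seed = 100 + s)
    f <- cross_section_fit(syn$panel, 2010, "altitude", "Doc_p1000",
      diagnostics = FALSE
    )
    abs(f$slope - (-4e-4)) < 3 * f$slope_se
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("an injected income effect is recovered by the pooled fit", {
  cfg <- flat_config(
    years = 2009:2010, noise_cv = 0.02,
    effects = list(
      altitude = c(doctors = 0, nurses = 0),
      income = c(doctors = 0, nurses = 2e-5)
    )
  )
  # hold densities and incomes level over time so the pooled fit sees only
  # the cross-sectional income signal, not a shared secular trend
  cfg$growth <- lapply(cfg$growth, function(x) x * 0)
  cfg$covariates$income$annual_growth <- 0
  syn <- generate_panel(cfg, seed = 31)
  f <- pooled_panel_fit(syn$panel, "income", "Nur_p1000", diagnostics = FALSE)
  expect_lt(abs(f$slope - 2e-5), 3 * f$slope_se)
  expect_true(f$significant)
})
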