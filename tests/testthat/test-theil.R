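# direct evaluation of the index definition, kept deliberately naive so it
# stays independent of the package implementation
theil_oracle <- function(pop, res) {
  p <- pop / sum(pop)
  y <- res / sum(res)
  s <- 0
  for (i in seq_along(p)) s <- s + p[i] * log(p[i] / y[i])
  s
}

test_that("worked two-county index matches the hand-derived value", {
  # p = (1/2, 1/2), y = (1/4, 3/4): 0.5 ln 2 + 0.5 ln(2/3)
  expect_equal(theil(c(100, 100), c(10, 30)), 0.14384103622589042, tolerance = 1e-12)
  expect_equal(theil(c(100, 100), c(20, 20)), 0)
  # symmetry under county permutation
  set.seed(4)
  pop <- runif(6, 10, 100)
  res <- runif(6, 1, 50)
  perm <- sample(6)
  expect_equal(theil(pop, res), theil(pop[perm], res[perm]), tolerance = 1e-14)
})

test_that("worked four-county decomposition puts all inequality within groups", {
  d <- theil_decompose(
    populations = c(100, 100, 100, 100),
    resources = c(10, 30, 20, 20),
    categories = c("A", "A", "B", "B")
  )
  expect_equal(d$ti_inter, 0, tolerance = 1e-15)
  expect_equal(d$ti_intra, 0.07192051811294521, tolerance = 1e-12)
  expect_equal(d$ti, 0.07192051811294521, tolerance = 1e-12)
  expect_equal(d$intra_share, 1, tolerance = 1e-12)
})

test_that("degenerate partitions collapse onto one component", {
  set.seed(9)
  pop <- runif(7, 50, 500)
  res <- runif(7, 5, 80)
  all_one <- theil_decompose(pop, res, rep("all", 7))
  expect_equal(all_one$ti_inter, 0, tolerance = 1e-14)
  expect_equal(all_one$ti_intra, all_one$ti, tolerance = 1e-14)
  singletons <- theil_decompose(pop, res, paste0("c", 1:7))
  expect_equal(singletons$ti_intra, 0, tolerance = 1e-14)
  expect_equal(singletons$ti_inter, singletons$ti, tolerance = 1e-14)
})

test_that("decomposition agrees with the brute-force oracle and is additive", {
  set.seed(1234)
  for (rep_i in 1:200) {
    n <- sample(2:8, 1)
    k <- sample(1:3, 1)
    pop <- runif(n, 10, 1000)
    res <- runif(n, 0.5, 100)
    cats <- sample(paste0("g", 1:k), n, replace = TRUE)
    d <- theil_decompose(pop, res, cats)
    expect_equal(d$ti, theil_oracle(pop, res), tolerance = 1e-12)
    expect_lte(abs(d$ti - (d$ti_intra + d$ti_inter)), 1e-12 * max(1, abs(d$ti)))
    expect_gte(d$ti, 0)
    expect_gte(d$ti_intra, -1e-15)
    # shares sum to 1
    per <- tidy(d)
    expect_equal(sum(per$p_j), 1, tolerance = 1e-12)
    expect_equal(sum(per$y_j), 1, tolerance = 1e-12)
    if (d$ti > 0) expect_equal(d$intra_share + d$inter_share, 1, tolerance = 1e-9)
  }
})

test_that("index is invariant to replication and to resource rescaling", {
  set.seed(21)
  for (rep_i in 1:20) {
    n <- sample(2:8, 1)
    pop <- runif(n, 10, 1000)
    res <- runif(n, 0.5, 100)
    ti <- theil(pop, res)
    expect_equal(theil(c(pop, pop), c(res, res)), ti, tolerance = 1e-12)
    expect_equal(theil(pop, res * runif(1, 0.01, 100)), ti, tolerance = 1e-12)
  }
})

test_that("equalising transfers never increase the index", {
  set.seed(33)
  for (rep_i in 1:50) {
    n <- sample(3:8, 1)
    pop <- runif(n, 10, 1000)
    res <- runif(n, 1, 100)
    percap <- res / pop
    rich <- which.max(percap)
    poor <- which.min(percap)
    # move a sliver of resources from the per-capita richest to the poorest
    delta <- 0.2 * res[rich]
    res2 <- res
    res2[rich] <- res2[rich] - delta
    res2[poor] <- res2[poor] + delta
    # only a progressive transfer (not past the crossing point) must not increase TI
    if (res2[rich] / pop[rich] >= res2[poor] / pop[poor]) {
      expect_lte(theil(pop, res2), theil(pop, res) + 1e-12)
    }
  }
})

test_that("zero-resource counties abort with the county named unless epsilon is set", {
  expect_error(
    theil(c(100, 200), c(0, 30), names = c("alpha", "beta")),
    "alpha",
    class = "equipanel_divergence_error"
  )
  expect_error(theil(c(100, 200), c(10, 30), epsilon = 1e-6), NA)
  ti_eps <- theil(c(100, 200), c(0, 30), epsilon = 1e-6)
  expect_true(is.finite(ti_eps) && ti_eps > 0)
  expect_error(theil(c(100, 100), c(10, 20, 30)), class = "equipanel_domain_error")
  expect_error(theil(c(100, -1), c(10, 20)), class = "equipanel_domain_error")
  expect_error(theil(c(100, 100), c(0, 0)), class = "equipanel_domain_error")
})

test_that("contributions are undefined (NA), not 0/0, at perfect equality", {
  d <- theil_decompose(c(100, 300), c(10, 30), c("A", "B"))
  expect_equal(d$ti, 0, tolerance = 1e-15)
  expect_true(is.na(d$intra_share))
  expect_true(is.na(d$inter_share))
})

test_that("theil_series is flat zero when resources track population exactly", {
  df <- tidyr::expand_grid(county_id = c("a", "b", "c"), year = 2009:2011) |>
    dplyr::mutate(
      category = rep(c("Yi", "Zang", "NMC"), each = 3),
      population = rep(c(1000, 2000, 4000), each = 3),
      beds = population * 0.003, doctors = population * 0.0015,
      nurses = population * 0.001,
      health_practitioners = (doctors + nurses) * 1.4,
      income = 3e4, gdp_per_capita = 2e4, altitude = 1000
    )
  s <- theil_series(as_panel(df))
  expect_equal(nrow(s), 9)
  expect_true(all(abs(s$ti) < 1e-14))
})

test_that("a widening category gap raises the inter component monotonically", {
  years <- 2009:2014
  df <- tidyr::expand_grid(county_id = c("a", "b"), year = years) |>
    dplyr::mutate(
      category = ifelse(county_id == "a", "Yi", "NMC"),
      population = 10000,
      # b's per-capita beds outgrow a's by 10% per year
      beds = ifelse(county_id == "a", 30, 30 * 1.1^(year - 2009)),
      doctors = 15, nurses = 10,
      health_practitioners = (doctors + nurses) * 1.4,
      income = 3e4, gdp_per_capita = 2e4, altitude = 1000
    )
  s <- theil_series(as_panel(df), resources = "beds")
  expect_true(all(diff(s$ti_inter) > 0))
  # reversing the trajectory gives a falling overall index
  s_rev <- s[order(-s$year), ]
  expect_true(all(diff(s_rev$ti) < 0))
})

test_that("series errors are tagged with year and resource", {
  df <- tidyr::expand_grid(county_id = c("a", "b"), year = 2009:2010) |>
    dplyr::mutate(
      category = c("Yi", "Yi", "NMC", "NMC"), population = 10000,
      beds = c(30, 30, 30, 0), doctors = 10, nurses = 10,
      health_practitioners = 30, income = 3e4, gdp_per_capita = 2e4, altitude = 1000
    )
  p <- as_panel(df)
  expect_error(theil_series(p, resources = "beds"), "2010",
    class = "equipanel_divergence_error"
  )
  expect_error(theil_series(p, resources = "pharmacists"),
    class = "equipanel_domain_error"
  )
})
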