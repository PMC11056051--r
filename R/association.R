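#' Bivariate least-squares fit with slope test and residual diagnostics
#'
#' Ordinary least squares of `y` on `x` with the F-test of zero slope (for a
#' simple regression this is the same object as a one-way ANOVA on the
#' slope), evaluated at significance level `alpha`. Residual diagnostics —
#' normality, homoscedasticity, independence — are advisory and never block
#' the fit.
#'
#' @param x Predictor values.
#' @param y Response values.
#' @param predictor,response Names used in output tables.
#' @param scope Free-text tag describing which observations were pooled
#'   (e.g. `"pooled 2009-2019"` or `"cross-section 2019"`).
#' @param alpha Significance level for the slope test flag (default 0.05).
#' @param diagnostics Compute residual diagnostics (default `TRUE`).
#' @return An object of class `equipanel_fit`: a list with `slope`,
#'   `intercept`, `r_squared`, `f_statistic`, `p_value`, `significant`, `n`,
#'   `n_excluded` (rows dropped for missing values), `diagnostics` (tibble,
#'   see [residual_diagnostics()]) and the underlying `stats::lm` object in
#'   `$model`. Use [tidy()] / [glance()] for tibble views.
#' @export
ols_fit <- function(x, y, predictor = "x", response = "y", scope = "",
                    alpha = 0.05, diagnostics = TRUE) {
  keep <- is.finite(x) & is.finite(y)
  n_excluded <- sum(!keep)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("at least 3 complete observations are required",
      class = "equipanel_insufficient_data_error"
    )
  }
  if (var(x) == 0) {
    abort("predictor is constant: slope undefined",
      class = "equipanel_degenerate_predictor_error"
    )
  }
  if (var(y) == 0) {
    abort("response is constant: R-squared undefined (zero total sum of squares)",
      class = "equipanel_degenerate_response_error"
    )
  }
  model <- lm(y ~ x, data = data.frame(x = x, y = y))
  # summary.lm warns on an exactly linear relation; a perfect fit is valid here
  sm <- suppressWarnings(summary(model))
  fstat <- unname(sm$fstatistic[1])
  p_value <- unname(pf(fstat, 1, n - 2, lower.tail = FALSE))

  fit <- structure(
    list(
      predictor = predictor, response = response, scope = scope,
      n = n, n_excluded = n_excluded,
      slope = unname(coef(model)[2]), intercept = unname(coef(model)[1]),
      slope_se = unname(sm$coefficients[2, 2]),
      r_squared = sm$r.squared,
      f_statistic = fstat, p_value = p_value,
      alpha = alpha, significant = p_value < alpha,
      model = model, diagnostics = NULL
    ),
    class = "equipanel_fit"
  )
  if (diagnostics) fit$diagnostics <- residual_diagnostics(fit)
  fit
}

#' Residual diagnostics for a fitted bivariate model
#'
#' Advisory checks of the linear-model assumptions: normality of residuals
#' (Shapiro-Wilk for n <= 5000, Anderson-Darling beyond), equal residual
#' variance (Breusch-Pagan), and independence (Durbin-Watson). A diagnostic
#' is `flagged` when its p-value falls below `alpha`; with zero residual
#' variance (perfectly linear data) all three are reported as not applicable.
#'
#' @param fit An `equipanel_fit` (or a bare `lm` object).
#' @param alpha Flagging level (default 0.05).
#' @return A tibble `(diagnostic, test, statistic, p_value, flagged)`.
#' @export
residual_diagnostics <- function(fit, alpha = 0.05) {
  model <- if (inherits(fit, "equipanel_fit")) fit$model else fit
  res <- stats::residuals(model)
  n <- length(res)
  if (sd(res) < 1e-12 * max(1, sd(stats::fitted(model)))) {
    return(tibble::tibble(
      diagnostic = c("normality", "homoscedasticity", "independence"),
      test = NA_character_, statistic = NA_real_, p_value = NA_real_,
      flagged = NA
    ))
  }
  if (n <= 5000) {
    nt <- shapiro.test(res)
    norm_row <- tibble::tibble(
      diagnostic = "normality", test = "shapiro_wilk",
      statistic = unname(nt$statistic), p_value = nt$p.value
    )
  } else {
    nt <- nortest::ad.test(res)
    norm_row <- tibble::tibble(
      diagnostic = "normality", test = "anderson_darling",
      statistic = unname(nt$statistic), p_value = nt$p.value
    )
  }
  bp <- lmtest::bptest(model)
  dw <- lmtest::dwtest(model, alternative = "two.sided")
  out <- dplyr::bind_rows(
    norm_row,
    tibble::tibble(
      diagnostic = "homoscedasticity", test = "breusch_pagan",
      statistic = unname(bp$statistic), p_value = bp$p.value
    ),
    tibble::tibble(
      diagnostic = "independence", test = "durbin_watson",
      statistic = unname(dw$statistic), p_value = dw$p.value
    )
  )
  out$flagged <- out$p_value < alpha
  out
}

#' Pooled county-year regression of a density on an economic covariate
#'
#' Pools every county-year row of the panel (treating county-years as
#' independent observations, as the decade-long scatter design implies; no
#' clustering or deflation is applied, and incomes are nominal) and fits the
#' chosen density on `income` or `gdp_per_capita`. Rows with a missing
#' predictor are excluded and counted in `n_excluded`.
#'
#' @param panel A panel tibble.
#' @param predictor `"income"` or `"gdp_per_capita"`.
#' @param response A density indicator (`"Doc_p1000"`, `"Nur_p1000"`, ...).
#' @param ... Passed to [ols_fit()].
#' @return An `equipanel_fit`.
#' @export
pooled_panel_fit <- function(panel, predictor = c("income", "gdp_per_capita"),
                             response = "Doc_p1000", ...) {
  predictor <- match.arg(predictor)
  res <- indicator_resource(response)
  yrs <- range(panel$year)
  ols_fit(
    x = panel[[predictor]],
    y = density_per_1000(panel[[res]], panel$population),
    predictor = predictor, response = response,
    scope = sprintf("pooled %d-%d", yrs[1], yrs[2]), ...
  )
}

#' Single-year regression of a density on altitude
#'
#' One row per county for the chosen year; the geography proxy is the county
#' mean altitude in metres above sea level.
#'
#' @param panel A panel tibble.
#' @param year Panel year to slice.
#' @param predictor Covariate column (default `"altitude"`).
#' @param response A density indicator.
#' @param ... Passed to [ols_fit()].
#' @return An `equipanel_fit`.
#' @export
cross_section_fit <- function(panel, year, predictor = "altitude",
                              response = "Doc_p1000", ...) {
  if (!year %in% panel$year) {
    abort(paste0("year ", year, " not in panel"), class = "equipanel_domain_error")
  }
  slice <- panel[panel$year == year, ]
  res <- indicator_resource(response)
  ols_fit(
    x = slice[[predictor]],
    y = density_per_1000(slice[[res]], slice$population),
    predictor = predictor, response = response,
    scope = sprintf("cross-section %d", year), ...
  )
}

#' @export
print.equipanel_fit <- function(x, ...) {
  cat(sprintf(
    "OLS %s ~ %s (%s): n = %d%s\n",
    x$response, x$predictor, x$scope, x$n,
    if (x$n_excluded > 0) sprintf(" (%d excluded)", x$n_excluded) else ""
  ))
  cat(sprintf(
    "slope %.4g (SE %.3g), intercept %.4g, R^2 = %.3f, F = %.2f, p = %.3g%s\n",
    x$slope, x$slope_se, x$intercept, x$r_squared, x$f_statistic, x$p_value,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' @describeIn ols_fit Coefficient-level tibble (term, estimate, std.error).
#' @param x An `equipanel_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.equipanel_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("(Intercept)", x$predictor),
    estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p.value = unname(sm[, 4])
  )
}

#' @describeIn ols_fit One-row model-level tibble, including diagnostic flags.
#' @exportS3Method generics::glance
glance.equipanel_fit <- function(x, ...) {
  diag_flags <- if (is.null(x$diagnostics)) {
    tibble::tibble(
      normality_flagged = NA, homoscedasticity_flagged = NA,
      independence_flagged = NA
    )
  } else {
    d <- x$diagnostics
    tibble::tibble(
      normality_flagged = d$flagged[d$diagnostic == "normality"],
      homoscedasticity_flagged = d$flagged[d$diagnostic == "homoscedasticity"],
      independence_flagged = d$flagged[d$diagnostic == "independence"]
    )
  }
  dplyr::bind_cols(
    tibble::tibble(
      predictor = x$predictor, response = x$response, scope = x$scope,
      n = x$n, n_excluded = x$n_excluded,
      slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
      f_statistic = x$f_statistic, p_value = x$p_value,
      significant = x$significant
    ),
    diag_flags
  )
}
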