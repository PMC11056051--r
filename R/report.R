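#' Run the full equity pipeline from a configuration
#'
#' Config-driven end-to-end run: obtain a panel (from CSV paths or from the
#' synthetic generator), then compute the indicator series (density trends),
#' the growth summary, the staffing-ratio series, the per-year Theil
#' decompositions, and the regression table (pooled income and GDP fits for
#' doctor/nurse/bed densities; first- and last-year altitude
#' cross-sections), and optionally write everything as CSV plus a JSON run
#' manifest and a log. Identical config and inputs produce byte-identical
#' CSV outputs.
#'
#' @param config A list (or path to a YAML file) with exactly one of
#'   * `input`: `list(panel = "panel.csv", scheme = "scheme.csv"` (optional),
#'     `schema = list(...)` (optional column mapping)`)`, or
#'   * `synthetic`: `list(seed = 1, config = "paperlike"` or `"default"`,
#'     `noise_cv = ...)` (optional override);
#'   plus optional `method` (`"aggregate"`/`"mean_of_counties"`), `epsilon`
#'   (Theil share floor), and `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`); `NULL` for
#'   an in-memory run with no files written.
#' @return Invisibly, a list of class `equipanel_report`: `panel`,
#'   `indicators`, `growth_summary`, `theil`, `theil_categories`,
#'   `regressions`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  out_dir <- out_dir %||% config$out_dir
  has_input <- !is.null(config$input)
  has_syn <- !is.null(config$synthetic)
  if (has_input == has_syn) {
    abort("config must set exactly one of `input` or `synthetic`",
      class = "equipanel_config_error"
    )
  }
  method <- config$method %||% "aggregate"
  epsilon <- config$epsilon
  log_lines <- character()
  log_add <- function(level, msg) {
    log_lines <<- c(log_lines, paste0("[", level, "] ", msg))
  }

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = "equipanel_pipeline_error"
      )
    })
    log_add("INFO", sprintf("stage %s done in %.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  truth <- NULL
  panel <- stage("load_panel", {
    if (has_syn) {
      base <- switch(config$synthetic$config %||% "paperlike",
        paperlike = paperlike_config(),
        default = synthetic_config(),
        abort("synthetic$config must be 'paperlike' or 'default'",
          class = "equipanel_config_error"
        )
      )
      if (!is.null(config$synthetic$noise_cv)) base$noise_cv <- config$synthetic$noise_cv
      syn <- generate_panel(base, seed = config$synthetic$seed %||% 1)
      truth <- syn$truth
      syn$panel
    } else {
      p <- read_panel(config$input$panel, schema = config$input$schema)
      if (!is.null(config$input$scheme)) {
        scheme <- read_category_scheme(config$input$scheme)
        extra <- setdiff(p$county_id, scheme$county_id)
        if (length(extra) > 0) {
          abort(paste0(
            "scheme does not cover panel county(ies): ",
            paste(head(extra, 5), collapse = ", ")
          ), class = "equipanel_scheme_error")
        }
        p$category <- scheme$category[match(p$county_id, scheme$county_id)]
        p <- as_panel(p)
      }
      p
    }
  })
  log_add("INFO", sprintf(
    "panel: %d rows, %d counties, years %d-%d",
    nrow(panel), dplyr::n_distinct(panel$county_id),
    min(panel$year), max(panel$year)
  ))

  indicators <- stage("indicators", indicator_series(panel, method = method))
  growth <- stage("growth", growth_summary(panel))
  theil_overall <- stage(
    "theil",
    theil_series(panel, epsilon = epsilon, level = "overall")
  )
  theil_cats <- stage(
    "theil_categories",
    theil_series(panel, epsilon = epsilon, level = "category")
  )

  regressions <- stage("regressions", {
    yrs <- range(panel$year)
    fits <- list(
      pooled_panel_fit(panel, "income", "Doc_p1000"),
      pooled_panel_fit(panel, "income", "Nur_p1000"),
      pooled_panel_fit(panel, "gdp_per_capita", "Doc_p1000"),
      pooled_panel_fit(panel, "gdp_per_capita", "Nur_p1000"),
      pooled_panel_fit(panel, "gdp_per_capita", "Bed_p1000"),
      cross_section_fit(panel, yrs[2], "altitude", "Doc_p1000"),
      cross_section_fit(panel, yrs[1], "altitude", "Doc_p1000"),
      cross_section_fit(panel, yrs[2], "altitude", "Nur_p1000"),
      cross_section_fit(panel, yrs[1], "altitude", "Nur_p1000")
    )
    excl <- sum(purrr::map_int(fits, "n_excluded"))
    if (excl > 0) log_add("WARN", sprintf("%d rows excluded from fits (missing covariates)", excl))
    purrr::map_dfr(fits, glance)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("equipanel")),
    mode = if (has_syn) "synthetic" else "input",
    seed = if (has_syn) config$synthetic$seed %||% 1 else NULL,
    method = method,
    epsilon = epsilon,
    config_hash = rlang::hash(config),
    n_rows = nrow(panel),
    n_counties = dplyr::n_distinct(panel$county_id),
    years = as.integer(range(panel$year))
  )

  bundle <- structure(
    list(
      panel = panel, truth = truth, indicators = indicators,
      growth_summary = growth, theil = theil_overall,
      theil_categories = theil_cats, regressions = regressions,
      manifest = manifest, log = log_lines
    ),
    class = "equipanel_report"
  )

  if (!is.null(out_dir)) {
    # stage outputs in a temp dir first so failures leave nothing partial
    staging <- tempfile("equipanel_report_")
    dir.create(staging)
    on.exit(unlink(staging, recursive = TRUE), add = TRUE)
    wr <- function(x, name) {
      readr::write_csv(x, file.path(staging, name), progress = FALSE)
    }
    if (has_syn) wr(panel, "panel.csv")
    wr(indicators, "indicators.csv")
    wr(growth, "growth_summary.csv")
    wr(theil_overall, "theil.csv")
    wr(theil_cats, "theil_categories.csv")
    wr(regressions, "regressions.csv")
    jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
    )
    writeLines(log_lines, file.path(staging, "run.log"))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (f in list.files(staging)) {
      file.copy(file.path(staging, f), file.path(out_dir, f), overwrite = TRUE)
    }
  }
  invisible(bundle)
}

#' Compare a pipeline report against published values
#'
#' Checks each row of a reference table of printed values against the
#' corresponding quantity recomputed in the report bundle, under the stated
#' rounding rule. Supported quantities: `aggregate_growth_pct`,
#' `mean_growth_pct`, `share_negative_pct`, `share_below_province_pct`
#' (per `indicator` and `category`), and `ratio_to_province_pct` (also per
#' `year`). Rounding rules: `"int"` (nearest integer) or `"1dp"`.
#'
#' @param bundle An `equipanel_report` from [run_pipeline()].
#' @param reference A tibble or CSV path with columns `quantity`,
#'   `indicator`, `category`, `year` (may be `NA`), `value`, `rounding`.
#' @return A tibble with the reference columns plus `computed`, `delta`
#'   (computed minus printed, after rounding) and `match`; attribute
#'   `n_mismatch` carries the mismatch count.
#' @export
compare_to_reference <- function(bundle, reference) {
  if (is.character(reference)) {
    reference <- readr::read_csv(reference, show_col_types = FALSE, progress = FALSE)
  }
  reference <- tibble::as_tibble(reference)
  needed <- c("quantity", "indicator", "category", "value", "rounding")
  missing_cols <- setdiff(needed, names(reference))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "reference table missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "equipanel_schema_error")
  }
  if (!"year" %in% names(reference)) reference$year <- NA_integer_
  if (nrow(reference) == 0) {
    out <- reference
    out$computed <- numeric(0)
    out$delta <- numeric(0)
    out$match <- logical(0)
    attr(out, "n_mismatch") <- 0L
    return(out)
  }

  gs <- bundle$growth_summary
  lookup_one <- function(quantity, indicator, category, year) {
    pick <- function(col) {
      v <- gs[[col]][gs$indicator == indicator & gs$category == category]
      if (length(v) != 1) {
        abort(sprintf(
          "no %s entry for indicator %s, category %s", quantity, indicator, category
        ), class = "equipanel_reference_error")
      }
      v
    }
    switch(quantity,
      aggregate_growth_pct = 100 * pick("aggregate_growth"),
      mean_growth_pct = 100 * pick("mean_county_growth"),
      share_negative_pct = 100 * pick("share_negative"),
      share_below_province_pct = 100 * pick("share_below_province"),
      ratio_to_province_pct = {
        ind <- bundle$indicators
        sub <- ind[ind$indicator == indicator & ind$year == year, ]
        cv <- sub$value[sub$category == category]
        pv <- sub$value[sub$category == "Province"]
        if (length(cv) != 1 || length(pv) != 1) {
          abort(sprintf(
            "no indicator series entry for %s, %s, year %s", indicator, category, year
          ), class = "equipanel_reference_error")
        }
        ratio_to_province(cv, pv)
      },
      abort(paste0("unknown reference quantity: ", quantity),
        class = "equipanel_reference_error"
      )
    )
  }

  computed <- purrr::pmap_dbl(
    reference[c("quantity", "indicator", "category", "year")],
    lookup_one
  )
  rounded <- purrr::map2_dbl(computed, reference$rounding, function(v, rule) {
    switch(rule,
      int = round(v),
      `1dp` = round(v, 1),
      abort(paste0("unknown rounding rule: ", rule),
        class = "equipanel_reference_error"
      )
    )
  })
  out <- reference
  out$computed <- computed
  out$delta <- rounded - reference$value
  out$match <- rounded == reference$value
  attr(out, "n_mismatch") <- sum(!out$match)
  out
}
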