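#' Population-weighted Theil index
#'
#' The inequality of a resource's distribution across counties, measured as
#' \deqn{TI = \sum_i p_i \ln(p_i / y_i)}{TI = sum_i p_i ln(p_i/y_i)}
#' where \eqn{p_i} is county \eqn{i}'s share of total population and
#' \eqn{y_i} its share of the total resource. This is the population-share
#' weighted mean log deviation: zero iff every county holds resources in
#' exact proportion to its population, strictly positive otherwise, invariant
#' to county order, to replication, and to rescaling all resources by a
#' positive constant.
#'
#' A county with positive population but zero resources makes the index
#' diverge; such input is rejected with a diagnostic naming the county unless
#' an explicit `epsilon` floor is supplied for exploratory use.
#'
#' @param populations Positive population per county.
#' @param resources Non-negative resource count per county; positive total.
#' @param epsilon Optional floor: resource shares are replaced by
#'   `pmax(y_i, epsilon)` and renormalised. Default `NULL` (off); silent
#'   regularisation would distort an equity series, so the floor is always an
#'   explicit choice.
#' @param names Optional county names used in diagnostics.
#' @return The Theil index, a non-negative scalar.
#' @examples
#' theil(c(100, 100), c(10, 30)) # 0.5*ln2 + 0.5*ln(2/3)
#' @export
theil <- function(populations, resources, epsilon = NULL, names = NULL) {
  shares <- theil_shares(populations, resources, epsilon, names)
  sum(shares$p * log(shares$p / shares$y))
}

# validated (p_i, y_i) share vectors
theil_shares <- function(populations, resources, epsilon = NULL, names = NULL) {
  if (length(populations) != length(resources)) {
    abort("populations and resources must have the same length",
      class = "equipanel_domain_error"
    )
  }
  if (any(!is.finite(populations) | populations <= 0)) {
    abort("all populations must be finite and > 0", class = "equipanel_domain_error")
  }
  if (any(!is.finite(resources) | resources < 0)) {
    abort("all resources must be finite and >= 0", class = "equipanel_domain_error")
  }
  if (sum(resources) <= 0) {
    abort("total resources must be > 0", class = "equipanel_domain_error")
  }
  p <- populations / sum(populations)
  y <- resources / sum(resources)
  if (is.null(epsilon)) {
    zero <- which(y == 0 & p > 0)
    if (length(zero) > 0) {
      who <- if (is.null(names)) paste0("#", zero) else names[zero]
      abort(
        paste0(
          "Theil index diverges: zero resources with positive population in ",
          paste(who, collapse = ", "),
          " (supply `epsilon` to floor resource shares explicitly)"
        ),
        class = "equipanel_divergence_error"
      )
    }
  } else {
    y <- pmax(y, epsilon)
    y <- y / sum(y)
  }
  list(p = p, y = y)
}

#' Decompose the Theil index into intra- and inter-category components
#'
#' Splits the county-level index additively over a county partition:
#' \deqn{TI = TI_{intra} + TI_{inter}}
#' with \eqn{TI_{intra} = \sum_j p_j TI_j} (each \eqn{TI_j} the within-group
#' index on within-group shares, weighted by the group's population share)
#' and \eqn{TI_{inter} = \sum_j p_j \ln(p_j / y_j)}, the between-group mean
#' log deviation on group-level shares. The identity is exact, which the
#' implementation asserts to 1e-12 relative tolerance.
#'
#' @inheritParams theil
#' @param categories Group label per county.
#' @return An object of class `theil_decomposition`: a list with `ti`,
#'   `ti_intra`, `ti_inter`, `intra_share`/`inter_share` (contribution
#'   fractions of `ti`; `NA` when `ti` is 0), and `per_category`, a tibble
#'   `(category, n, p_j, y_j, ti_j)`. Use [tidy()] / [glance()] for tibble
#'   views.
#' @examples
#' d <- theil_decompose(
#'   populations = c(100, 100, 100, 100),
#'   resources = c(10, 30, 20, 20),
#'   categories = c("A", "A", "B", "B")
#' )
#' glance(d)
#' @export
theil_decompose <- function(populations, resources, categories,
                            epsilon = NULL, names = NULL) {
  if (length(categories) != length(populations)) {
    abort("categories must have the same length as populations",
      class = "equipanel_domain_error"
    )
  }
  shares <- theil_shares(populations, resources, epsilon, names)
  p <- shares$p
  y <- shares$y
  cats <- unique(categories)

  per <- purrr::map_dfr(cats, function(g) {
    idx <- which(categories == g)
    p_j <- sum(p[idx])
    y_j <- sum(y[idx])
    # within-group index on within-group shares
    ti_j <- if (y_j > 0) {
      pw <- p[idx] / p_j
      yw <- y[idx] / y_j
      sum(pw * log(pw / yw))
    } else {
      NA_real_ # whole group floored to zero resources: no within term
    }
    tibble::tibble(category = g, n = length(idx), p_j = p_j, y_j = y_j, ti_j = ti_j)
  })

  ti_intra <- sum(per$p_j * per$ti_j)
  ti_inter <- sum(per$p_j * ifelse(per$y_j > 0, log(per$p_j / per$y_j), NA_real_))
  ti <- sum(p * log(p / y))
  if (abs(ti - (ti_intra + ti_inter)) > 1e-12 * max(1, abs(ti))) {
    abort("internal error: Theil decomposition lost additivity",
      class = "equipanel_internal_error"
    )
  }

  structure(
    list(
      ti = ti, ti_intra = ti_intra, ti_inter = ti_inter,
      intra_share = if (ti > 0) ti_intra / ti else NA_real_,
      inter_share = if (ti > 0) ti_inter / ti else NA_real_,
      per_category = per
    ),
    class = "theil_decomposition"
  )
}

#' @export
print.theil_decomposition <- function(x, ...) {
  cat(sprintf(
    "Theil decomposition: TI = %.6f (intra %.6f + inter %.6f)\n",
    x$ti, x$ti_intra, x$ti_inter
  ))
  if (!is.na(x$intra_share)) {
    cat(sprintf(
      "contributions: intra %.1f%%, inter %.1f%%\n",
      100 * x$intra_share, 100 * x$inter_share
    ))
  }
  print(x$per_category)
  invisible(x)
}

#' @describeIn theil_decompose Per-category tibble `(category, n, p_j, y_j, ti_j)`.
#' @param x A `theil_decomposition`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.theil_decomposition <- function(x, ...) x$per_category

#' @describeIn theil_decompose One-row tibble of the overall index, its
#'   components and contribution shares.
#' @exportS3Method generics::glance
glance.theil_decomposition <- function(x, ...) {
  tibble::tibble(
    ti = x$ti, ti_intra = x$ti_intra, ti_inter = x$ti_inter,
    intra_share = x$intra_share, inter_share = x$inter_share
  )
}

#' Cross-sectional Theil decomposition per year
#'
#' One population-weighted Theil decomposition per panel year and resource,
#' using that year's populations and counts and the panel's category scheme.
#'
#' @param panel A panel tibble.
#' @param resources Resource columns to analyse.
#' @param epsilon Optional resource-share floor, see [theil()].
#' @param level `"overall"` (default) for one row per year and resource, or
#'   `"category"` for the per-category long table.
#' @return A tibble: `(year, resource, ti, ti_intra, ti_inter, intra_share,
#'   inter_share)` or, at `level = "category"`, `(year, resource, category,
#'   n, p_j, y_j, ti_j)`.
#' @export
theil_series <- function(panel, resources = c("beds", "doctors", "nurses"),
                         epsilon = NULL, level = c("overall", "category")) {
  level <- match.arg(level)
  bad <- setdiff(resources, RESOURCE_COLS)
  if (length(bad) > 0) {
    abort(paste0("unknown resource column(s): ", paste(bad, collapse = ", ")),
      class = "equipanel_domain_error"
    )
  }
  years <- sort(unique(panel$year))
  grid <- tidyr::expand_grid(year = years, resource = resources)
  purrr::pmap_dfr(grid, function(year, resource) {
    slice <- panel[panel$year == year, ]
    dec <- tryCatch(
      theil_decompose(
        slice$population, slice[[resource]], slice$category,
        epsilon = epsilon, names = slice$county_id
      ),
      error = function(e) e
    )
    if (inherits(dec, "error")) {
      abort(sprintf("year %d, %s: %s", year, resource, conditionMessage(dec)),
        class = "equipanel_divergence_error"
      )
    }
    if (level == "overall") {
      dplyr::bind_cols(tibble::tibble(year = year, resource = resource), glance(dec))
    } else {
      dplyr::bind_cols(tibble::tibble(year = year, resource = resource), tidy(dec))
    }
  })
}
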