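#' Run the full factorial ensemble
#'
#' Computes one national attributable-case total for every combination of
#' modeling system (exposure delta), population projection and C-R
#' function: the "many answers" whose spread is the object of the
#' sensitivity analysis. The run is deterministic given its inputs.
#'
#' @param systems Named list of `o3_delta` objects, one per modeling system.
#' @param populations Named list, one element per projection, each a list
#'   with `projection` (county age-structure tibble) and `weights`
#'   (county-to-cell weights).
#' @param crfs A C-R tibble with one row per study (shared endpoint,
#'   metric MDA8), or a named list of one-row [crf()] tibbles.
#' @param rates Incidence table covering the endpoint.
#' @param season An [o3_season()].
#' @param regions Optional region mask; when supplied, regional totals are
#'   attached as extra columns.
#' @return A tibble of class `o3_ensemble` with columns `system`, `study`,
#'   `population`, `deaths` (national attributable cases, unrounded), one
#'   row per factorial combination.
#' @export
run_factorial <- function(systems, populations, crfs, rates,
                          season = o3_season(), regions = NULL) {
  if (is.data.frame(crfs)) {
    crfs <- stats::setNames(
      lapply(seq_len(nrow(crfs)), function(i) crfs[i, , drop = FALSE]),
      crfs$study
    )
  }
  stopifnot(length(systems) >= 1, length(populations) >= 1, length(crfs) >= 1)
  combos <- tidyr::expand_grid(
    system = names(systems),
    study = names(crfs),
    population = names(populations)
  )
  rows <- purrr::pmap(combos, function(system, study, population) {
    res <- tryCatch(
      cell_impacts(systems[[system]],
                   populations[[population]]$projection,
                   populations[[population]]$weights,
                   rates, crfs[[study]], season),
      error = function(e) {
        stop("factorial run failed at (", system, ", ", study, ", ",
             population, "): ", conditionMessage(e), call. = FALSE)
      }
    )
    out <- tibble::tibble(system = system, study = study,
                          population = population,
                          deaths = sum(res$delta_cases))
    if (!is.null(regions)) {
      reg <- aggregate_impacts(res, regions)
      reg <- reg[reg$region != "National", , drop = FALSE]
      wide <- stats::setNames(as.list(reg$delta_cases), reg$region)
      out <- dplyr::bind_cols(out, tibble::as_tibble(wide))
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("o3_ensemble", class(out))
  out
}

#' Balanced three-way ANOVA variance decomposition of an ensemble table
#'
#' Decomposes the total variability of the factorial ensemble into the
#' three main effects (modeling system, study, population projection),
#' the three two-way interactions and the three-way interaction. With one
#' observation per factorial cell there is no residual term; the
#' three-way interaction is reported as its own source. The sums of
#' squares are the standard balanced fixed-effects decomposition (computed
#' via [stats::aov()]); percentages are each source's share of the total
#' SS.
#'
#' @param table An `o3_ensemble` (or tibble with `system`, `study`,
#'   `population` and a response column). Must be balanced: every
#'   combination present exactly once.
#' @param response Name of the response column (default `"deaths"`).
#' @return A tibble of class `o3_anova` with columns `source`, `df`,
#'   `sumsq`, `percent`; attribute `total_ss`. `df` sums to `n - 1` and
#'   `sumsq` to the total SS.
#' @export
anova_decompose <- function(table, response = "deaths") {
  fac <- c("system", "study", "population")
  stopifnot(all(c(fac, response) %in% names(table)))
  counts <- dplyr::count(table, !!!rlang::syms(fac))
  n_expected <- prod(vapply(table[fac], dplyr::n_distinct, numeric(1)))
  if (nrow(counts) != n_expected || any(counts$n != 1)) {
    stop("ensemble table must be balanced with exactly one observation per ",
         "system x study x population combination", call. = FALSE)
  }
  df <- data.frame(
    system = factor(table$system),
    study = factor(table$study),
    population = factor(table$population),
    y = table[[response]]
  )
  total_ss <- sum((df$y - mean(df$y))^2)
  fit <- stats::aov(y ~ system * study * population, data = df)
  s <- summary(fit)[[1]]
  src <- trimws(rownames(s))
  out <- tibble::tibble(
    source = gsub(":", " x ", src, fixed = TRUE),
    df = as.integer(s[["Df"]]),
    sumsq = s[["Sum Sq"]]
  )
  if (total_ss > 0) {
    out$percent <- out$sumsq / total_ss * 100
  } else {
    warning("total sum of squares is 0; percentages reported as 0", call. = FALSE)
    out$percent <- 0
  }
  attr(out, "total_ss") <- total_ss
  attr(out, "n") <- nrow(df)
  class(out) <- c("o3_anova", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.o3_anova <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.o3_anova <- function(x, ...) {
  tibble::tibble(
    total_ss = attr(x, "total_ss"),
    n = attr(x, "n"),
    df_total = sum(x$df),
    largest_source = x$source[which.max(x$sumsq)]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.o3_anova <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$source <- factor(df$source, levels = df$source[order(df$sumsq)])
  ggplot2::ggplot(df, ggplot2::aes(.data$source, .data$percent)) +
    ggplot2::geom_col(fill = "#4575b4") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Percent of total sum of squares") +
    ggplot2::theme_minimal()
}

#' Range of ensemble estimates
#'
#' Returns the smallest and largest estimates in the ensemble with the
#' factor combinations producing them. Invariant under row permutation.
#'
#' @param table An ensemble tibble with a `deaths` column.
#' @param response Response column name.
#' @return A two-row tibble (`extreme` = "min", "max") with the factor
#'   labels and value of each extremum.
#' @export
summarize_range <- function(table, response = "deaths") {
  stopifnot(nrow(table) >= 1, response %in% names(table))
  y <- table[[response]]
  idx <- c(min = which.min(y), max = which.max(y))
  out <- table[idx, intersect(c("system", "study", "population"), names(table)),
               drop = FALSE]
  out <- dplyr::bind_cols(tibble::tibble(extreme = names(idx)), out)
  out[[response]] <- y[idx]
  tibble::as_tibble(out)
}

#' Population-weighted CDF of exposure change
#'
#' The weighted empirical cumulative distribution of per-cell ozone
#' changes, with weights proportional to the cell population: the fraction
#' of the population experiencing a change of at most each observed delta.
#' The share of the population subject to an ozone increase is
#' `1 - CDF(0)`, stored in the `fraction_increase` attribute.
#'
#' @param delta An `o3_delta` (or tibble with `cell_id`, `delta`).
#' @param pop_field Population field `cell_id`, `value` on the same grid;
#'   total must be > 0.
#' @return A tibble of class `o3_cdf` with columns `delta` (sorted ppb
#'   breakpoints) and `cum_fraction` (nondecreasing, ending at 1);
#'   attribute `fraction_increase`.
#' @export
population_weighted_cdf <- function(delta, pop_field) {
  stopifnot(all(c("cell_id", "delta") %in% names(delta)),
            all(c("cell_id", "value") %in% names(pop_field)))
  joined <- dplyr::inner_join(delta[c("cell_id", "delta")],
                              pop_field[c("cell_id", "value")], by = "cell_id")
  total <- sum(joined$value)
  if (total <= 0) stop("total population must be > 0", call. = FALSE)
  agg <- dplyr::summarise(dplyr::group_by(joined, .data$delta),
                          w = sum(.data$value), .groups = "drop")
  agg <- dplyr::arrange(agg, .data$delta)
  out <- tibble::tibble(delta = agg$delta, cum_fraction = cumsum(agg$w) / total)
  attr(out, "fraction_increase") <- sum(joined$value[joined$delta > 0]) / total
  class(out) <- c("o3_cdf", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.o3_cdf <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$delta, .data$cum_fraction)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = expression(Delta * O[3] ~ "(ppb)"),
                  y = "Cumulative population fraction") +
    ggplot2::theme_minimal()
}

#' Published national mortality ensemble table
#'
#' The 105-entry table of published national summertime ozone-related
#' nonaccidental mortality changes ca. 2050 attributable to simulated
#' climate change: 7 climate-air quality modeling systems x 3
#' epidemiological studies x 5 population projections, values rounded to
#' the nearest 10 deaths as printed. Shipped as plain CSV; used to
#' exercise the ensemble-analysis layer ([anova_decompose()],
#' [summarize_range()]) on real published numbers.
#'
#' @return An `o3_ensemble` tibble with columns `system`, `study`,
#'   `population`, `deaths`.
#' @export
national_mortality_ensemble <- function() {
  path <- system.file("extdata", "national_mortality_ensemble.csv",
                      package = "o3hia", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble::as_tibble(out)
  class(out) <- c("o3_ensemble", class(out))
  out
}
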