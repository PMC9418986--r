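range_label <- function(r) paste0(r[1], "-", r[2])

# Life-table route for one stratum: observed rates 0-89, Kannisto-Makeham
# extrapolation 90-110, closed life table, cause-split decrements.
stratum_lifetable <- function(deaths_s, population_s, fit_ages, pool_from) {
  sched <- estimate_rates(deaths_s, population_s, ages = 0:89)
  km <- fit_kannisto_makeham(sched, fit_ages = fit_ages)
  rates <- bind_rows(
    sched |> select("age", "mx"),
    extrapolate_rates(km, ages = 90:110)
  )
  lt <- build_lifetable(rates)
  mdlt <- build_multidecrement(lt, deaths_s |> count(.data$age, .data$cause, name = "deaths"),
                               pool_from = pool_from)
  list(lifetable = lt, mdlt = mdlt, km = km)
}

#' Join diversity values with matching ASMRs
#'
#' @param diversity Diversity table with columns `year`, `sex`, `quintile`,
#'   `age_range` (as produced by [run_pipeline()]).
#' @param asmr_tbl ASMR table with the same subcommunity columns.
#' @return The diversity table with an `asmr` column joined on.
#' @export
diversity_vs_asmr <- function(diversity, asmr_tbl) {
  diversity |>
    inner_join(asmr_tbl |> select("year", "sex", "quintile", "age_range", "asmr"),
               by = c("year", "sex", "quintile", "age_range"))
}

#' Run the full mortality-diversity pipeline
#'
#' Orchestrates every stage: (optionally) simulate a synthetic registry,
#' assign population-weighted deprivation quintiles, compute directly
#' age-standardised mortality rates, build per-stratum life tables with
#' Kannisto-Makeham old-age extrapolation and their multiple-decrement
#' cause splits, compute Hill-number diversity per subcommunity, and fit
#' descriptive linear trends of diversity against calendar year and against
#' ASMR. Everything is deterministic given the scenario seed.
#'
#' Subcommunities are defined by `grouping`: each element is a character
#' vector of stratifiers (subsets of `"sex"`, `"quintile"`) crossed with
#' year and age range. The default computes sex-stratified (quintiles
#' pooled) and quintile-stratified (sexes pooled) grids independently; pass
#' `list(c("sex", "quintile"))` for the fully crossed grid. Pooled
#' dimensions are reported as `"all"`.
#'
#' @param scenario A [scenario_config()]; used to simulate a registry when
#'   `deaths`/`population`/`zones` are not supplied.
#' @param deaths,population,zones Registry tables (see
#'   [simulate_registry()]); override the simulated ones.
#' @param q Diversity viewpoint parameters (default 0 and 1).
#' @param age_ranges List of inclusive age ranges (default premature 0-74
#'   and older-age 75-110).
#' @param grouping List of stratifier sets (see above).
#' @param source `"lifetable"` (diversity from multiple-decrement life-table
#'   decrements, the primary route) and/or `"observed"` (raw observed cause
#'   counts).
#' @param fit_ages Ages informing the Kannisto-Makeham fit.
#' @param pool_from First age using the pooled old-age cause mix in the
#'   decrement split.
#' @param out_dir Optional directory; when given, writes `quintiles.csv`,
#'   `asmr.csv`, `diversity.csv`, `trends.csv`, `lifetables.csv`,
#'   `decrements.csv` and `manifest.json`.
#' @param force Overwrite a non-empty `out_dir`.
#' @return A list with tibbles `zones`, `quintiles`, `asmr`, `diversity`,
#'   `trends`, `lifetables`, `decrements` and the `manifest` list.
#' @export
run_pipeline <- function(scenario = NULL,
                         deaths = NULL, population = NULL, zones = NULL,
                         q = c(0, 1),
                         age_ranges = list(c(0, 74), c(75, 110)),
                         grouping = list("sex", "quintile"),
                         source = "lifetable",
                         fit_ages = 70:89,
                         pool_from = 90,
                         out_dir = NULL,
                         force = FALSE) {
  stopifnot(length(q) >= 1, length(age_ranges) >= 1)
  source <- match.arg(source, c("lifetable", "observed"), several.ok = TRUE)
  if (length(unique(map(age_ranges, range_label))) < length(age_ranges)) {
    abort("Duplicate age ranges.")
  }
  starts <- map_dbl(age_ranges, 1)
  ends <- map_dbl(age_ranges, 2)
  o <- order(starts)
  if (length(o) > 1 && any(starts[o][-1] <= ends[o][-length(o)])) {
    abort("Age ranges overlap within a run.")
  }

  if (is.null(deaths) || is.null(population) || is.null(zones)) {
    if (is.null(scenario)) abort("Supply either a scenario or all three registry tables.")
    reg <- simulate_registry(scenario)
    deaths <- deaths %||% reg$deaths
    population <- population %||% reg$population
    zones <- zones %||% reg$zones
  }

  quintiles <- assign_quintiles(zones)
  deaths <- deaths |> inner_join(quintiles, by = "zone_id")
  population <- population |> inner_join(quintiles, by = "zone_id")

  with_all <- function(tbl) {
    if (!"sex" %in% names(tbl)) tbl$sex <- "all"
    if (!"quintile" %in% names(tbl)) tbl$quintile <- "all"
    tbl |> mutate(sex = as.character(.data$sex),
                  quintile = as.character(.data$quintile))
  }

  # --- ASMR over every grouping set and age range ---------------------------
  asmr_tbl <- map(grouping, function(g) {
    map(age_ranges, function(ar) {
      asmr(deaths, population, by = c("year", g), age_range = ar) |>
        mutate(age_range = range_label(ar), cause = "all") |>
        with_all()
    }) |> list_rbind()
  }) |>
    list_rbind() |>
    select("year", "sex", "quintile", "age_range", "cause", "asmr") |>
    arrange(.data$year, .data$sex, .data$quintile, .data$age_range)

  # --- diversity per subcommunity -------------------------------------------
  lifetables <- list()
  decrements <- list()
  div_rows <- list()

  for (g in grouping) {
    strata <- deaths |> distinct(across(all_of(c("year", g)))) |>
      arrange(across(all_of(c("year", g))))
    for (i in seq_len(nrow(strata))) {
      key <- strata[i, ]
      deaths_s <- deaths |> semi_join(key, by = c("year", g))
      population_s <- population |> semi_join(key, by = c("year", g))

      if ("lifetable" %in% source) {
        res <- stratum_lifetable(deaths_s, population_s, fit_ages, pool_from)
        lab <- with_all(key)
        lifetables[[length(lifetables) + 1]] <-
          bind_cols(lab[rep(1, nrow(res$lifetable)), ], as_tibble(res$lifetable))
        decr <- as_tibble(res$mdlt)
        decrements[[length(decrements) + 1]] <-
          bind_cols(lab[rep(1, nrow(decr)), ], decr)
        for (ar in age_ranges) {
          dist <- cause_distribution(res$mdlt, ar)
          div_rows[[length(div_rows) + 1]] <-
            bind_cols(lab,
                      diversity_series(dist, q = q) |>
                        mutate(age_range = range_label(ar), source = "lifetable"))
        }
      }
      if ("observed" %in% source) {
        lab <- with_all(key)
        for (ar in age_ranges) {
          dist <- deaths_s |>
            filter(.data$age >= ar[1], .data$age <= ar[2]) |>
            count(.data$cause, name = "n")
          div_rows[[length(div_rows) + 1]] <-
            bind_cols(lab,
                      diversity_series(dist, q = q) |>
                        mutate(age_range = range_label(ar), source = "observed"))
        }
      }
    }
  }

  diversity <- list_rbind(div_rows) |>
    select("year", "sex", "quintile", "age_range", "q", value = "diversity",
           "source") |>
    arrange(.data$source, .data$q, .data$sex, .data$quintile,
            .data$age_range, .data$year)

  # --- descriptive trends ----------------------------------------------------
  # a trend is only reported for subcommunities with >= 3 points and a
  # non-constant predictor
  sub_cols <- c("sex", "quintile", "age_range", "q", "source")
  fitable <- function(tbl) {
    tbl |>
      group_by(across(all_of(sub_cols))) |>
      filter(n() >= 3, n_distinct(.data$predictor_value) > 1) |>
      ungroup()
  }
  div_asmr <- diversity_vs_asmr(diversity, asmr_tbl)
  trends <- bind_rows(
    fit_trends(fitable(diversity |> rename(predictor_value = "year")),
               x = "predictor_value", y = "value", by = sub_cols) |>
      mutate(predictor = "year"),
    fit_trends(fitable(div_asmr |> rename(predictor_value = "asmr")),
               x = "predictor_value", y = "value", by = sub_cols) |>
      mutate(predictor = "asmr")
  ) |>
    select("sex", "quintile", "age_range", "q", "source", "predictor",
           "slope", "intercept", "r_squared", "n_points") |>
    arrange(.data$predictor, .data$source, .data$q, .data$sex,
            .data$quintile, .data$age_range)

  lifetables <- if (length(lifetables)) list_rbind(lifetables) else NULL
  decrements <- if (length(decrements)) list_rbind(decrements) else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("causediv")),
    scenario = if (!is.null(scenario)) unclass(scenario) else NULL,
    settings = list(q = q, age_ranges = map(age_ranges, range_label),
                    grouping = grouping, source = source,
                    fit_ages = range(fit_ages), pool_from = pool_from),
    rows = list(
      deaths = nrow(deaths), population = nrow(population),
      zones = nrow(zones), asmr = nrow(asmr_tbl),
      diversity = nrow(diversity), trends = nrow(trends)
    )
  )

  result <- list(zones = zones, quintiles = quintiles, asmr = asmr_tbl,
                 diversity = diversity, trends = trends,
                 lifetables = lifetables, decrements = decrements,
                 manifest = manifest)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir, force = force)
  result
}

#' Write pipeline outputs to a run directory
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory.
#' @param force Overwrite existing files.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort("`out_dir` is non-empty; use `force = TRUE` to overwrite.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$quintiles, file.path(out_dir, "quintiles.csv"))
  readr::write_csv(result$asmr, file.path(out_dir, "asmr.csv"))
  readr::write_csv(result$diversity, file.path(out_dir, "diversity.csv"))
  readr::write_csv(result$trends, file.path(out_dir, "trends.csv"))
  if (!is.null(result$lifetables)) {
    readr::write_csv(result$lifetables, file.path(out_dir, "lifetables.csv"))
  }
  if (!is.null(result$decrements)) {
    readr::write_csv(result$decrements, file.path(out_dir, "decrements.csv"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
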