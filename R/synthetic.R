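#' Scenario configuration for the synthetic registry generator
#'
#' Bundles every parameter of the synthetic vital-registration scenario:
#' calendar span, areal units, the Gompertz-Makeham baseline hazard and its
#' sex / deprivation / calendar-time multipliers, and the cause-distribution
#' dynamics (the summed probability of the `k_leading` leading causes moves
#' linearly from `leading_share_start` in the first year to
#' `leading_share_end` in the last, so the scenario encodes a diversifying
#' cause profile when the share falls).
#'
#' Defaults describe a small country with ~1% crude death rate, mortality
#' improving at 1.5%/year, men at 1.5 times the female hazard, a
#' most-to-least-deprived hazard ratio of about 2.4, and the five leading
#' causes shrinking from 40% to 25% of deaths over the period.
#'
#' @param years Inclusive calendar-year range (integer vector; only the range
#'   is used).
#' @param n_zones Number of small-area zones (>= 5, so quintiles exist).
#' @param n_causes Number of synthetic ICD-10-like three-character codes.
#' @param mean_population Mean zone population; zone sizes are log-normal
#'   around this value.
#' @param makeham_c Age-independent background hazard (per person-year).
#' @param gompertz_A Hazard level at age 0 of the senescent component.
#' @param gompertz_B Log-hazard slope per year of age.
#' @param sex_ratio Male:female hazard multiplier (>= 1).
#' @param deprivation_gradient Hazard multiplier per deprivation-quintile
#'   step (> 0; values above 1 make deprived areas deadlier).
#' @param improvement_rate Proportional annual hazard decline (delta >= 0);
#'   the hazard in year t is multiplied by exp(-delta * (t - first year)).
#' @param leading_share_start,leading_share_end Summed probability of the
#'   `k_leading` leading causes in the first / last year; start >= end.
#' @param k_leading Number of leading causes per age group.
#' @param seed Integer seed governing every random draw of the generator.
#'
#' @return A list of class `scenario_config`.
#' @export
#' @examples
#' cfg <- scenario_config(years = 2001:2003, n_zones = 10, seed = 1)
#' cfg$k_leading
scenario_config <- function(years = 2001:2019,
                            n_zones = 200,
                            n_causes = 60,
                            mean_population = 783,
                            makeham_c = 3e-4,
                            gompertz_A = 3e-5,
                            gompertz_B = 0.1,
                            sex_ratio = 1.5,
                            deprivation_gradient = 1.25,
                            improvement_rate = 0.015,
                            leading_share_start = 0.40,
                            leading_share_end = 0.25,
                            k_leading = 5,
                            seed = 1L) {
  years <- as.integer(seq(min(years), max(years)))
  stopifnot(
    n_zones >= 5, n_causes > k_leading, k_leading >= 1,
    mean_population > 0,
    makeham_c >= 0, gompertz_A >= 0, gompertz_B >= 0,
    sex_ratio >= 1, deprivation_gradient > 0, improvement_rate >= 0,
    leading_share_start > 0, leading_share_start < 1,
    leading_share_end > 0, leading_share_end < 1
  )
  if (leading_share_start < leading_share_end) {
    abort("`leading_share_start` must be >= `leading_share_end` (diversification scenario).")
  }
  structure(
    list(
      years = years, n_zones = as.integer(n_zones),
      n_causes = as.integer(n_causes), mean_population = mean_population,
      makeham_c = makeham_c, gompertz_A = gompertz_A, gompertz_B = gompertz_B,
      sex_ratio = sex_ratio, deprivation_gradient = deprivation_gradient,
      improvement_rate = improvement_rate,
      leading_share_start = leading_share_start,
      leading_share_end = leading_share_end,
      k_leading = as.integer(k_leading), seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from a plain-text key = value file
#'
#' Lines look like `n_zones = 100` or `years = 2001:2019`; `#` starts a
#' comment. Keys must match [scenario_config()] arguments; unknown keys are
#' an error.
#'
#' @param path Path to the configuration file.
#' @param ... Overrides applied after the file is read (e.g. `seed = 7`).
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) abort(paste0("Malformed config line: ", lines[bad][1]))
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  allowed <- names(formals(scenario_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0) {
    abort(paste0("Unknown scenario key(s): ", paste(unknown, collapse = ", ")))
  }
  parse_val <- function(v) {
    if (grepl("^-?\\d+\\s*[:–-]\\s*-?\\d+$", v)) {
      ends <- as.numeric(strsplit(v, "[:–-]")[[1]])
      return(seq(ends[1], ends[2]))
    }
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) num else v
  }
  args <- setNames(lapply(vals, parse_val), keys)
  args[names(list(...))] <- list(...)
  do.call(scenario_config, args)
}

#' Generate synthetic small-area zones
#'
#' Each zone gets an income-deprivation rate drawn from a right-skewed Beta
#' distribution on (0, 1) and a population drawn log-normally around
#' `mean_population` (the default mirrors a mean small-area population of
#' 783 persons). Output is deterministic given `seed`.
#'
#' @param n_zones Number of zones (>= 5).
#' @param seed Integer seed.
#' @param mean_population Target mean zone population.
#' @param sdlog Log-scale standard deviation of zone populations.
#' @return A tibble with columns `zone_id`, `income_rate`, `base_population`.
#' @export
#' @examples
#' generate_datazones(5, seed = 1)
generate_datazones <- function(n_zones, seed, mean_population = 783,
                               sdlog = 0.4) {
  if (n_zones < 5) abort("`n_zones` must be >= 5 (cannot form quintiles).")
  withr::with_seed(as.integer(seed), {
    income <- rbeta(n_zones, 1.5, 6)
    pop <- pmax(1L, as.integer(round(
      rlnorm(n_zones, meanlog = log(mean_population) - sdlog^2 / 2, sdlog = sdlog)
    )))
  })
  tibble(
    zone_id = sprintf("Z%05d", seq_len(n_zones)),
    income_rate = income,
    base_population = pop
  )
}

# Stylised population pyramid weight at a single year of age: roughly flat
# through midlife, then a logistic roll-off so counts are monotone
# non-increasing at older ages (centre 82, scale 7 years).
pyramid_weight <- function(age) plogis((82 - age) / 7)

# Largest-remainder (Hamilton) apportionment: integer allocation of `total`
# proportional to `w`, exact in total, deterministic (ties by index order).
largest_remainder <- function(total, w) {
  shares <- total * w / sum(w)
  base <- floor(shares)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    idx <- order(shares - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Spread zone populations over age and sex for every calendar year
#'
#' Each zone's `base_population` is apportioned across single years of age
#' 0-110 by a stylised pyramid (monotone non-increasing at older ages) and
#' split evenly between the sexes, using largest-remainder rounding so the
#' zone total is conserved exactly in every year. The age structure is held
#' fixed over calendar time.
#'
#' @param zones Tibble from [generate_datazones()].
#' @param config A [scenario_config()].
#' @return A tibble of mid-year counts: `year`, `age`, `sex`, `zone_id`,
#'   `count`, one row per combination, sorted by (year, age, sex, zone_id).
#' @export
generate_population <- function(zones, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (nrow(zones) == 0) abort("`zones` must be non-empty.")
  ages <- 0:110
  sexes <- c("female", "male")
  cell_w <- rep(pyramid_weight(ages), times = 2) / 2 # female block then male
  per_zone <- map(zones$base_population, largest_remainder, w = cell_w)
  base <- tibble(
    zone_id = rep(zones$zone_id, each = length(cell_w)),
    age = rep(rep(ages, times = 2), times = nrow(zones)),
    sex = rep(rep(sexes, each = length(ages)), times = nrow(zones)),
    count = unlist(per_zone)
  )
  tidyr::crossing(year = config$years, base) |>
    arrange(.data$year, .data$age, .data$sex, .data$zone_id) |>
    select("year", "age", "sex", "zone_id", "count")
}

# Synthetic ICD-10-like three-character codes: ten codes per letter chapter.
cause_codes <- function(n_causes) {
  i <- seq_len(n_causes) - 1L
  sprintf("%s%02d", LETTERS[i %/% 10 + 1], i %% 10)
}

# Age-group specific cause distributions. Each broad age group has its own
# set of k leading causes (disjoint blocks of the code list) whose summed
# probability interpolates linearly from `leading_share_start` to
# `leading_share_end` across the scenario years; remaining mass is spread
# over the other causes with fixed uneven relative weights.
cause_model <- function(config) {
  codes <- cause_codes(config$n_causes)
  k <- config$k_leading
  groups <- c("0-39", "40-74", "75+")
  lead_idx <- lapply(seq_along(groups), function(g) {
    idx <- ((g - 1) * k + seq_len(k) - 1) %% config$n_causes + 1
    idx
  })
  names(lead_idx) <- groups
  list(codes = codes, groups = groups, lead_idx = lead_idx)
}

cause_probs <- function(model, config, group, year) {
  y0 <- min(config$years)
  y1 <- max(config$years)
  frac <- if (y1 > y0) (year - y0) / (y1 - y0) else 0
  share <- config$leading_share_start +
    frac * (config$leading_share_end - config$leading_share_start)
  n <- length(model$codes)
  lead <- model$lead_idx[[group]]
  p <- numeric(n)
  w_lead <- rev(seq_along(lead)) # declining weights among leaders
  p[lead] <- share * w_lead / sum(w_lead)
  others <- setdiff(seq_len(n), lead)
  w_other <- 1 / sqrt(seq_along(others)) # uneven tail, heavier early codes
  p[others] <- (1 - share) * w_other / sum(w_other)
  p
}

age_group_of <- function(age) {
  cut(age, breaks = c(-1, 39, 74, 111), labels = c("0-39", "40-74", "75+"))
}

# Per-cell death hazard: proportional-hazards Gompertz-Makeham baseline with
# sex, deprivation-quintile and calendar-improvement multipliers.
cell_hazard <- function(age, sex, quintile, year, config) {
  base <- config$makeham_c + config$gompertz_A * exp(config$gompertz_B * age)
  base *
    ifelse(sex == "male", config$sex_ratio, 1) *
    config$deprivation_gradient^(3 - quintile) *
    exp(-config$improvement_rate * (year - min(config$years)))
}

#' Simulate individual death records from a population table
#'
#' Death counts in each (year, age, sex, zone) cell are Poisson with mean
#' `count * mu`, where `mu` is a Gompertz-Makeham hazard scaled by sex,
#' deprivation-quintile and calendar-improvement multipliers (see
#' [scenario_config()]). A hazard above 1 is clipped to 1 with a warning.
#' Each death is then assigned an ICD-10-like cause from an age-group
#' specific categorical distribution whose leading-cause share interpolates
#' across years. Cells are processed in (year, age, sex, zone) order so a
#' given seed reproduces the registry exactly.
#'
#' @param population Tibble from [generate_population()].
#' @param zones Tibble from [generate_datazones()].
#' @param config A [scenario_config()].
#' @return A tibble of death records: `year`, `age`, `sex`, `cause`,
#'   `zone_id`.
#' @export
generate_deaths <- function(population, zones, config) {
  stopifnot(inherits(config, "scenario_config"))
  quintiles <- assign_quintiles(zones)
  model <- cause_model(config)
  cells <- population |>
    inner_join(quintiles, by = "zone_id") |>
    arrange(.data$year, .data$age, .data$sex, .data$zone_id) |>
    mutate(mu = cell_hazard(.data$age, .data$sex, .data$quintile,
                            .data$year, config))
  if (any(cells$mu > 1)) {
    warn(sprintf("Hazard exceeded 1 in %d cell(s); Poisson mean clipped at the cell count.",
                 sum(cells$mu > 1)))
    cells$mu <- pmin(cells$mu, 1)
  }
  deaths <- withr::with_seed(config$seed, {
    cells$n_deaths <- rpois(nrow(cells), cells$count * cells$mu)
    if (sum(cells$n_deaths) == 0) {
      tibble(year = integer(0), age = integer(0), sex = character(0),
             zone_id = character(0), cause = character(0))
    } else {
      cells |>
        filter(.data$n_deaths > 0) |>
        select("year", "age", "sex", "zone_id", "n_deaths") |>
        tidyr::uncount(.data$n_deaths) |>
        mutate(age_group = age_group_of(.data$age)) |>
        group_by(.data$year, .data$age_group) |>
        mutate(cause = sample(model$codes, n(), replace = TRUE,
                              prob = cause_probs(model, config,
                                                 as.character(.data$age_group[1]),
                                                 .data$year[1]))) |>
        ungroup()
    }
  })
  deaths |>
    select("year", "age", "sex", "cause", "zone_id") |>
    arrange(.data$year, .data$age, .data$sex, .data$zone_id, .data$cause)
}

#' Simulate a complete synthetic registry
#'
#' Convenience wrapper running [generate_datazones()],
#' [generate_population()] and [generate_deaths()] for one scenario.
#'
#' @param config A [scenario_config()].
#' @return A list with tibbles `zones`, `population`, `deaths`.
#' @export
#' @examples
#' reg <- simulate_registry(scenario_config(years = 2001:2002, n_zones = 6,
#'                                          mean_population = 300, seed = 2))
#' nrow(reg$zones)
simulate_registry <- function(config) {
  zones <- generate_datazones(config$n_zones, config$seed,
                              mean_population = config$mean_population)
  population <- generate_population(zones, config)
  deaths <- generate_deaths(population, zones, config)
  list(zones = zones, population = population, deaths = deaths)
}

#' Write a synthetic registry to CSV files
#'
#' Writes `deaths.csv`, `population.csv` and `zones.csv` (UTF-8, comma
#' separated, no row names) under `dir`.
#'
#' @param registry List from [simulate_registry()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(registry$deaths, file.path(dir, "deaths.csv"))
  readr::write_csv(registry$population, file.path(dir, "population.csv"))
  readr::write_csv(registry$zones, file.path(dir, "zones.csv"))
  invisible(dir)
}

#' Read a registry from CSV files
#'
#' @param dir Directory containing `deaths.csv`, `population.csv`,
#'   `zones.csv` as written by [write_registry()].
#' @return A list with tibbles `zones`, `population`, `deaths`.
#' @export
read_registry <- function(dir) {
  list(
    zones = readr::read_csv(file.path(dir, "zones.csv"),
                            col_types = "cdi"),
    population = readr::read_csv(file.path(dir, "population.csv"),
                                 col_types = "iicci") |>
      mutate(age = as.integer(.data$age)),
    deaths = readr::read_csv(file.path(dir, "deaths.csv"),
                             col_types = "iiccc")
  )
}
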