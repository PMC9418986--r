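# Small scenario used across tests: 3 years, 8 zones, quiet hazard clipping.
tiny_scenario <- function(seed = 1, ...) {
  scenario_config(years = 2001:2003, n_zones = 8, mean_population = 400,
                  seed = seed, ...)
}

tiny_registry <- function(seed = 1, ...) {
  suppressWarnings(simulate_registry(tiny_scenario(seed = seed, ...)))
}

# Death counts simulated from a known Kannisto-Makeham law, the
# parameter-recovery oracle for the fitting routine.
km_schedule <- function(a, b, c, ages = 70:89, exposure = 1e6, seed = 1) {
  params <- list(a = a, b = b, c = c, age_offset = min(ages))
  mu <- km_hazard(params, ages + 0.5)
  withr::with_seed(seed, deaths <- rpois(length(ages), exposure * mu))
  tibble::tibble(age = ages, deaths = deaths, exposure = exposure,
                 mx = deaths / exposure)
}

# Random full-age rate schedule and cause counts for conservation checks.
random_rates <- function(seed) {
  withr::with_seed(seed, mx <- stats::runif(111, 0, 0.5))
  tibble::tibble(age = 0:110, mx = mx)
}

random_cause_counts <- function(seed, n_causes = 6, p_empty_age = 0.2) {
  withr::with_seed(seed, {
    keep <- stats::runif(111) > p_empty_age
    counts <- tidyr::crossing(age = (0:110)[keep],
                              cause = paste0("C", seq_len(n_causes))) |>
      dplyr::mutate(deaths = stats::rpois(dplyr::n(), 4))
  })
  counts |> dplyr::filter(deaths > 0)
}

# Random relative-abundance vectors for diversity property tests.
random_abundances <- function(seed, max_types = 50) {
  withr::with_seed(seed, {
    k <- sample(2:max_types, 1)
    stats::rexp(k)
  })
}
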