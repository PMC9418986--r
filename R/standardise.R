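#' The 2013 European Standard Population
#'
#' Weights of the 2013 European Standard Population in the 5-year age bands
#' 0-4, 5-9, ..., 85-89 and an open 90+ band (the published under-1 and 1-4
#' weights are pooled into 0-4, and 90-94 with 95+ into 90+). The weights
#' sum to exactly 100,000, asserted at load.
#'
#' @return A tibble with columns `band` (label), `lower` (lowest age in the
#'   band) and `weight` (standard persons).
#' @export
#' @examples
#' sum(esp2013()$weight)
esp2013 <- function() {
  path <- system.file("extdata", "esp2013.csv", package = "causediv",
                      mustWork = TRUE)
  std <- readr::read_csv(path, col_types = "ci")
  std$lower <- as.integer(sub("[-+].*$", "", std$band))
  if (sum(std$weight) != 100000L) {
    abort("ESP 2013 weights do not sum to 100,000; standard table corrupted.")
  }
  std[, c("band", "lower", "weight")]
}

band_lower <- function(age) pmin(5L * (age %/% 5L), 90L)

check_age_range <- function(age_range) {
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2])
  if (age_range[1] %% 5 != 0 ||
      (age_range[2] < 110 && (age_range[2] + 1) %% 5 != 0)) {
    abort("`age_range` must align with 5-year band boundaries (e.g. c(0, 74), c(75, 110)).")
  }
  age_range
}

#' Directly age-standardised mortality rates
#'
#' Computes ASMRs per 100,000 standard population by direct standardisation:
#' deaths and mid-year counts are pooled into the standard's 5-year age
#' bands within each group defined by `by`, band rates `r_g = D_g / E_g` are
#' weighted by the standard weights, and the result is renormalised by the
#' weight sum of the bands inside `age_range` — so an ASMR restricted to
#' ages 0-74 is per 100,000 of the 0-74 standard population. Bands with no
#' population and no deaths contribute zero; a band with deaths but no
#' population is an error.
#'
#' @param deaths Data frame of death records with columns `year`, `age`,
#'   plus any columns named in `by` (e.g. `sex`, `quintile`) and optionally
#'   `cause`.
#' @param population Data frame of mid-year counts with columns `year`,
#'   `age`, `count`, plus the `by` columns.
#' @param by Character vector of grouping columns present in both tables
#'   (default `c("year", "sex")`).
#' @param age_range Inclusive age limits aligned with band boundaries;
#'   `c(0, 74)` for premature mortality, `c(75, 110)` for older ages.
#' @param causes Optional character vector restricting deaths to a cause
#'   set (cause-specific ASMR).
#' @param standard Standard population tibble, by default [esp2013()].
#' @return A tibble with the `by` columns and an `asmr` column (deaths per
#'   100,000 standard population per year).
#' @export
asmr <- function(deaths, population, by = c("year", "sex"),
                 age_range = c(0, 110), causes = NULL,
                 standard = esp2013()) {
  check_age_range(age_range)
  stopifnot(all(by %in% names(deaths)), all(by %in% names(population)))
  bands <- standard |> filter(.data$lower >= age_range[1],
                              .data$lower <= age_range[2])
  if (nrow(bands) == 0) abort("`age_range` covers no standard band.")

  if (!is.null(causes)) deaths <- deaths |> filter(.data$cause %in% causes)
  d <- deaths |>
    filter(.data$age >= age_range[1], .data$age <= age_range[2]) |>
    mutate(lower = band_lower(.data$age)) |>
    count(across(all_of(c(by, "lower"))), name = "deaths")
  e <- population |>
    filter(.data$age >= age_range[1], .data$age <= age_range[2]) |>
    mutate(lower = band_lower(.data$age)) |>
    group_by(across(all_of(c(by, "lower")))) |>
    summarise(exposure = sum(.data$count), .groups = "drop")

  grid <- tidyr::crossing(
    distinct(bind_rows(d[by], e[by])),
    bands |> select("lower", "weight")
  )
  cells <- grid |>
    left_join(e, by = c(by, "lower")) |>
    left_join(d, by = c(by, "lower")) |>
    mutate(
      exposure = tidyr::replace_na(.data$exposure, 0),
      deaths = tidyr::replace_na(.data$deaths, 0)
    )
  bad <- cells |> filter(.data$exposure == 0, .data$deaths > 0)
  if (nrow(bad) > 0) {
    abort(sprintf("Band starting at age %d has deaths but zero population.",
                  bad$lower[1]))
  }
  cells |>
    mutate(rate = ifelse(.data$exposure > 0, .data$deaths / .data$exposure, 0)) |>
    group_by(across(all_of(by))) |>
    summarise(asmr = 1e5 * sum(.data$weight * .data$rate) / sum(.data$weight),
              .groups = "drop")
}

#' Percent reduction between two rates
#'
#' Returns `100 * (rate_start - rate_end) / rate_start`, rounded to the
#' nearest whole percent (halves away from zero). Positive values are
#' reductions; negative values mean the rate increased.
#'
#' @param rate_start,rate_end Rates on the same scale (e.g. per 100,000);
#'   `rate_start` must be positive. Vectorised.
#' @return Integer percent reduction(s).
#' @export
#' @examples
#' percent_change(749, 497) # 34
percent_change <- function(rate_start, rate_end) {
  if (any(rate_start <= 0)) abort("`rate_start` must be positive.")
  x <- 100 * (rate_start - rate_end) / rate_start
  as.integer(sign(x) * floor(abs(x) + 0.5))
}
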