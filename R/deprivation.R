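#' Population-weighted income-deprivation quintiles
#'
#' Zones are ranked by income-deprivation rate, most deprived first, and cut
#' into five groups each holding as close to 20% of the total population as
#' the zone sizes allow: quintile 1 holds the fifth of the population living
#' in the zones with the highest deprivation rates, quintile 5 the fifth
#' with the lowest. A zone straddling a 20% boundary is allocated by where
#' the midpoint of its population block falls (`ceiling(5 * midpoint /
#' total)`), which is deterministic and keeps each quintile's population
#' share within one zone of 0.20. Ties in `income_rate` are broken by
#' `zone_id` so the assignment never depends on input order.
#'
#' @param zones A data frame with columns `zone_id`, `income_rate` and a
#'   population column (`base_population` or `population`).
#' @return A tibble with columns `zone_id` and `quintile` (1 = most
#'   deprived), carrying a `"shares"` attribute: the population share of
#'   each quintile.
#' @export
#' @examples
#' z <- tibble::tibble(zone_id = c("a", "b", "c"),
#'                     income_rate = c(0.9, 0.5, 0.1),
#'                     base_population = c(30, 30, 40))
#' assign_quintiles(z)
assign_quintiles <- function(zones) {
  zones <- as_tibble(zones)
  if (!"base_population" %in% names(zones) && "population" %in% names(zones)) {
    zones$base_population <- zones$population
  }
  stopifnot(all(c("zone_id", "income_rate", "base_population") %in% names(zones)))
  if (nrow(zones) == 0) abort("No zones supplied.")
  if (anyNA(zones$income_rate)) abort("`income_rate` must have no missing values.")
  total <- sum(zones$base_population)
  if (total <= 0) abort("Total population is zero; quintiles undefined.")

  out <- zones |>
    arrange(desc(.data$income_rate), .data$zone_id) |>
    mutate(
      midpoint = cumsum(.data$base_population) - .data$base_population / 2,
      quintile = pmin(5L, pmax(1L, as.integer(ceiling(5 * .data$midpoint / total))))
    )
  shares <- out |>
    group_by(.data$quintile) |>
    summarise(share = sum(.data$base_population) / total, .groups = "drop")
  res <- out |>
    arrange(.data$zone_id) |>
    select("zone_id", "quintile")
  attr(res, "shares") <- shares
  res
}
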