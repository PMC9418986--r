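#' Plot survivors and decrements of a life table
#'
#' @param object A [build_lifetable()] result.
#' @param ... Unused.
#' @return A ggplot: `lx` and `dx` against age, facetted.
#' @method autoplot lifetable
#' @export
autoplot.lifetable <- function(object, ...) {
  long <- object |>
    select("age", "lx", "dx") |>
    tidyr::pivot_longer(c("lx", "dx"), names_to = "column")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~column, scales = "free_y") +
    ggplot2::labs(x = "age", y = NULL, title = "Period life table")
}

#' Diversity of mortality causes over calendar time
#'
#' Points per subcommunity-year with the descriptive OLS line, facetted by
#' age range.
#'
#' @param diversity Diversity table from [run_pipeline()] (columns `year`,
#'   `value`, `age_range` and the `colour` column).
#' @param colour Column mapped to colour (default `"sex"`).
#' @return A ggplot.
#' @export
plot_diversity_trend <- function(diversity, colour = "sex") {
  ggplot2::ggplot(diversity,
                  ggplot2::aes(x = .data$year, y = .data$value,
                               colour = .data[[colour]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~age_range, scales = "free_y") +
    ggplot2::labs(x = "year", y = "effective number of causes (q = 1)")
}

#' Diversity of mortality causes against the age-standardised mortality rate
#'
#' @param diversity_asmr Output of [diversity_vs_asmr()].
#' @param colour Column mapped to colour (default `"sex"`).
#' @return A ggplot.
#' @export
plot_diversity_asmr <- function(diversity_asmr, colour = "sex") {
  ggplot2::ggplot(diversity_asmr,
                  ggplot2::aes(x = .data$asmr, y = .data$value,
                               colour = .data[[colour]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~age_range, scales = "free") +
    ggplot2::labs(x = "ASMR (per 100,000)",
                  y = "effective number of causes (q = 1)")
}
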