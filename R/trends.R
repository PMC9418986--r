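#' Descriptive linear trend of a diversity (or rate) series
#'
#' Ordinary least-squares line through `(x, y)` with its coefficient of
#' determination — the solid regression lines drawn through per-year
#' diversity values or diversity-vs-ASMR scatters. Purely descriptive: no
#' standard errors or p-values are attached.
#'
#' @param x Predictor values (calendar years or ASMRs); at least 3, not all
#'   equal.
#' @param y Response values, same length as `x`.
#' @param predictor Label stored with the fit (e.g. `"year"` or `"asmr"`).
#' @return An object of class `trend_fit`: `slope`, `intercept`,
#'   `r_squared` (0 for a constant response), `n_points`, `predictor`.
#' @export
#' @examples
#' fit_trend(1:3, c(1, 2, 2))
fit_trend <- function(x, y, predictor = "x") {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 points to fit a trend.")
  if (diff(range(x)) == 0) abort("`x` values are all equal; slope undefined.")
  fit <- lm(y ~ x)
  res <- unname(coef(fit))
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(slope = res[2], intercept = res[1],
         r_squared = if (sst > 0) 1 - sse / sst else 0,
         n_points = length(x), predictor = predictor),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Linear trend on %s: slope = %.6g, intercept = %.6g, r^2 = %.4f (n = %d)\n",
              x$predictor, x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", x$predictor),
         estimate = c(x$intercept, x$slope))
}

#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_points)
}

#' Trend fits for every subcommunity in a table
#'
#' Grouped wrapper around [fit_trend()]: one OLS line per combination of the
#' `by` columns.
#'
#' @param data Data frame holding predictor, response and grouping columns.
#' @param x,y Names of the predictor and response columns.
#' @param by Character vector of grouping columns (`NULL` for one fit).
#' @return A tibble with the `by` columns plus `predictor`, `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
fit_trends <- function(data, x, y, by = NULL) {
  if (nrow(data) == 0) {
    empty <- data[, by %||% character(0), drop = FALSE]
    return(bind_cols(as_tibble(empty),
                     tibble(predictor = character(0), slope = numeric(0),
                            intercept = numeric(0), r_squared = numeric(0),
                            n_points = integer(0))))
  }
  x_col <- x
  y_col <- y
  data |>
    group_by(across(all_of(by))) |>
    reframe({
      ft <- fit_trend(.data[[x_col]], .data[[y_col]], predictor = x_col)
      tibble(predictor = x_col, slope = ft$slope, intercept = ft$intercept,
             r_squared = ft$r_squared, n_points = ft$n_points)
    })
}
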