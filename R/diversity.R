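#' Hill-number diversity (effective number of causes)
#'
#' The diversity of order `q` of a relative-abundance vector `p` is
#' `D = (sum p_i^q)^(1/(1-q))` for `q != 1` and `exp(-sum p_i log p_i)`
#' (the exponential of Shannon entropy) at `q = 1`. It reads as the number
#' of equally prevalent types that would give the same diversity: `q = 0`
#' counts types present (richness), `q = 1` weights each type exactly by its
#' prevalence, larger `q` leans on the dominant types (`q = 2` is inverse
#' Simpson concentration). Values run from 1 (all mass on one type) to the
#' number of types present (all equally prevalent). Zero-abundance types are
#' excluded from the sums (`0 log 0 := 0`); abundances may be real-valued
#' (life-table decrements are) — only their proportions matter.
#'
#' `q` within 1e-12 of 1 is evaluated with the Shannon limit form; the power
#' form is numerically exact for any other `q`, including `1 +/- 1e-6`.
#'
#' @param n Non-negative abundances (at least one positive); names optional.
#' @param q Viewpoint parameter, a single number >= 0.
#' @return The effective number of types, a single number.
#' @export
#' @examples
#' hill_diversity(c(1, 1, 1, 1), q = 1) # 4: uniform gives richness
#' hill_diversity(c(2, 1, 1), q = 2)    # 8/3: inverse Simpson
hill_diversity <- function(n, q = 1) {
  if (length(q) != 1 || is.na(q) || q < 0) abort("`q` must be a single number >= 0.")
  n <- as.numeric(n)
  if (any(n < 0)) abort("Abundances must be non-negative.")
  p <- n[n > 0]
  if (length(p) == 0) abort("All abundances are zero; diversity undefined.")
  p <- p / sum(p)
  if (abs(q - 1) < 1e-12) {
    exp(-sum(p * log(p)))
  } else {
    exp(log(sum(p^q)) / (1 - q))
  }
}

#' Diversity of cause distributions across subcommunities
#'
#' Computes [hill_diversity()] within each group of a long table of cause
#' abundances — one subcommunity (e.g. a year x sex x age-group cell) per
#' group. Abundances can be observed death counts or real-valued life-table
#' decrements.
#'
#' @param counts Data frame with a `cause` column, an abundance column, and
#'   the grouping columns.
#' @param q Viewpoint parameters (one output row per group per `q`).
#' @param by Character vector of grouping columns; `NULL` treats the whole
#'   table as one subcommunity.
#' @param abundance Name of the abundance column (default `"n"`).
#' @return A tibble with the `by` columns, `q` and `diversity`.
#' @export
#' @examples
#' x <- tibble::tibble(year = rep(1:2, each = 3), cause = rep(letters[1:3], 2),
#'                     n = c(2, 1, 1, 1, 1, 1))
#' diversity_series(x, q = c(0, 1), by = "year")
diversity_series <- function(counts, q = 1, by = NULL, abundance = "n") {
  stopifnot(abundance %in% names(counts), "cause" %in% names(counts))
  if (!is.null(by)) {
    missing_by <- setdiff(by, names(counts))
    if (length(missing_by) > 0) {
      abort(paste0("Missing grouping column(s): ", paste(missing_by, collapse = ", ")))
    }
  }
  # a cause appearing on several rows of a subcommunity is one type
  pooled <- counts |>
    group_by(across(all_of(c(by, "cause")))) |>
    summarise(.n = sum(.data[[abundance]]), .groups = "drop")
  one_q <- function(qq) {
    pooled |>
      group_by(across(all_of(by))) |>
      summarise(q = qq,
                diversity = hill_diversity(.data$.n, qq),
                .groups = "drop")
  }
  map(q, one_q) |> list_rbind()
}
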