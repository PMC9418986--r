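#' Age-specific central death rates for one stratum
#'
#' Aggregates deaths and mid-year counts over every column except age
#' (filter the inputs to a single stratum — e.g. one year, sex and quintile
#' — before calling) and returns the central rate `mx = deaths / exposure`
#' at each single year of age.
#'
#' @param deaths Death records with an `age` column.
#' @param population Mid-year counts with `age` and `count` columns.
#' @param ages Ages to report (default 0:89, the reliably observed range).
#' @return A tibble with columns `age`, `deaths`, `exposure`, `mx`.
#' @export
estimate_rates <- function(deaths, population, ages = 0:89) {
  d <- deaths |>
    filter(.data$age %in% ages) |>
    count(.data$age, name = "deaths")
  e <- population |>
    filter(.data$age %in% ages) |>
    group_by(.data$age) |>
    summarise(exposure = sum(.data$count), .groups = "drop")
  out <- tibble(age = as.integer(ages)) |>
    left_join(e, by = "age") |>
    left_join(d, by = "age") |>
    mutate(
      exposure = tidyr::replace_na(.data$exposure, 0),
      deaths = tidyr::replace_na(.data$deaths, 0L)
    )
  starved <- out$exposure == 0 & out$deaths > 0
  if (any(starved)) {
    abort(sprintf("Age %d has deaths but zero exposure.",
                  out$age[starved][1]))
  }
  if (any(out$exposure == 0)) {
    warn(sprintf("%d age(s) have zero exposure and zero deaths; rate recorded as 0.",
                 sum(out$exposure == 0)))
  }
  out$mx <- ifelse(out$exposure > 0, out$deaths / out$exposure, 0)
  out
}

#' Kannisto-Makeham hazard
#'
#' The logistic old-age mortality law `mu(x) = c + a e^{b (x - x0)} / (1 + a
#' e^{b (x - x0)})`: a plateauing senescent component bounded above by
#' `c + 1`, plus an age-independent background hazard `c`.
#'
#' @param params A `kannisto_makeham` fit or a list with elements `a`, `b`,
#'   `c`, `age_offset`.
#' @param x Exact ages (use `age + 0.5` for mid-interval rates).
#' @return Hazard values.
#' @export
km_hazard <- function(params, x) {
  params$c + plogis(log(params$a) + params$b * (x - params$age_offset))
}

km_negloglik <- function(theta, t, D, E) {
  # theta = (log a, log b, log c); Poisson likelihood with exposure offsets
  mu <- exp(theta[3]) + plogis(theta[1] + exp(theta[2]) * t)
  if (any(!is.finite(mu)) || any(mu <= 0)) return(Inf)
  -sum(D * log(mu) - E * mu)
}

#' Fit the Kannisto-Makeham law to old-age death rates
#'
#' Maximises the Poisson log-likelihood
#' `sum(D_x log mu(x + 0.5) - E_x mu(x + 0.5))` over `(log a, log b, log c)`
#' with the age offset fixed at the lower end of the fit window, starting
#' from a small grid of initial values and returning the best optimum
#' (Nelder-Mead followed by a BFGS polish, relative tolerance 1e-12). If no
#' start converges to a finite optimum the fit falls back to a pure Kannisto
#' law (`c = 0`) and flags the result.
#'
#' @param schedule Tibble from [estimate_rates()] (columns `age`, `deaths`,
#'   `exposure`).
#' @param fit_ages Ages informing the fit; default 70:89, the widest old-age
#'   window below the extrapolation region.
#' @return An object of class `kannisto_makeham`: parameters `a`, `b`, `c`,
#'   `age_offset`, plus `loglik`, `fallback` and the fit window.
#' @export
fit_kannisto_makeham <- function(schedule, fit_ages = 70:89) {
  dat <- schedule |>
    filter(.data$age %in% fit_ages, .data$exposure > 0)
  if (nrow(dat) < 5) abort("Need >= 5 ages with positive exposure in the fit window.")
  if (sum(dat$deaths) == 0) abort("All death counts are zero; the law is unidentifiable.")
  offset <- min(fit_ages)
  t <- dat$age + 0.5 - offset
  D <- dat$deaths
  E <- dat$exposure

  starts <- expand.grid(
    la = log(c(0.02, 0.08, 0.3)),
    lb = log(c(0.08, 0.13)),
    lc = log(c(1e-4, 5e-3))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch({
      nm <- optim(as.numeric(starts[i, ]), km_negloglik, t = t, D = D, E = E,
                  method = "Nelder-Mead",
                  control = list(maxit = 1000, reltol = 1e-12))
      suppressWarnings(
        optim(nm$par, km_negloglik, t = t, D = D, E = E,
              method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
      )
    }, error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }

  fallback <- FALSE
  if (is.null(best)) {
    # pure Kannisto: drop the background term
    nll2 <- function(th) km_negloglik(c(th, -Inf), t, D, E)
    best2 <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(
        optim(as.numeric(starts[i, 1:2]), nll2, method = "Nelder-Mead",
              control = list(maxit = 1000, reltol = 1e-12)),
        error = function(e) NULL
      )
      if (!is.null(fit) && is.finite(fit$value) &&
          (is.null(best2) || fit$value < best2$value)) best2 <- fit
    }
    if (is.null(best2)) abort("Kannisto-Makeham fit failed from every start.")
    warn("Kannisto-Makeham fit did not converge; falling back to pure Kannisto (c = 0).")
    best <- list(par = c(best2$par, -Inf), value = best2$value)
    fallback <- TRUE
  }

  structure(
    list(
      a = exp(best$par[1]), b = exp(best$par[2]),
      c = if (fallback) 0 else exp(best$par[3]),
      age_offset = offset,
      loglik = -best$value, fit_ages = fit_ages, fallback = fallback
    ),
    class = "kannisto_makeham"
  )
}

#' @export
print.kannisto_makeham <- function(x, ...) {
  cat("Kannisto-Makeham fit (offset age ", x$age_offset, ")\n", sep = "")
  cat(sprintf("  a = %.5g, b = %.5g, c = %.5g\n", x$a, x$b, x$c))
  cat(sprintf("  log-likelihood = %.4f%s\n", x$loglik,
              if (x$fallback) " [fallback: pure Kannisto]" else ""))
  invisible(x)
}

#' @method tidy kannisto_makeham
#' @export
tidy.kannisto_makeham <- function(x, ...) {
  tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' @method glance kannisto_makeham
#' @export
glance.kannisto_makeham <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = length(x$fit_ages),
         age_offset = x$age_offset, fallback = x$fallback)
}

#' Extrapolate death rates to the oldest ages
#'
#' Evaluates a fitted Kannisto-Makeham law at mid-interval ages `x + 0.5` to
#' extend a rate schedule beyond the reliably observed range (by default to
#' ages 90-110).
#'
#' @param params A `kannisto_makeham` fit.
#' @param ages Ages to extrapolate (default 90:110).
#' @return A tibble with columns `age`, `mx`.
#' @export
extrapolate_rates <- function(params, ages = 90:110) {
  tibble(age = as.integer(ages), mx = km_hazard(params, ages + 0.5))
}

#' Build a single-year-of-age period life table
#'
#' Converts central rates to interval death probabilities with the standard
#' actuarial relation `qx = mx / (1 + (1 - ax) mx)` (capped at 1), using
#' `ax = 0.5` at all ages except `a0 = 0.1` (infant deaths are concentrated
#' early in the first year). The terminal age is an open interval with
#' `qx = 1`, so the cohort of `radix` closes exactly: `sum(dx) = radix`.
#'
#' @param rates Tibble with columns `age` (a complete run 0..terminal) and
#'   `mx >= 0`.
#' @param a0 Mean fraction of the first year lived by infants who die.
#' @param ax Mean fraction of the interval lived at all other ages.
#' @param radix Cohort size at exact age 0 (conventionally 100,000).
#' @return A tibble of class `lifetable` with columns `age`, `mx`, `ax`,
#'   `qx`, `lx`, `dx`.
#' @export
#' @examples
#' lt <- build_lifetable(tibble::tibble(age = 0:110, mx = 0.01))
#' sum(lt$dx)
build_lifetable <- function(rates, a0 = 0.1, ax = 0.5, radix = 1e5) {
  rates <- rates |> arrange(.data$age)
  n <- nrow(rates)
  if (!identical(as.integer(rates$age), seq(rates$age[1], length.out = n))) {
    abort("`rates` must cover a complete run of single years of age.")
  }
  if (any(rates$mx < 0)) abort("Negative central rates are not allowed.")
  a <- c(if (rates$age[1] == 0) a0 else ax, rep(ax, n - 1))
  q <- pmin(1, rates$mx / (1 + (1 - a) * rates$mx))
  q[n] <- 1 # open terminal interval
  l <- radix * cumprod(c(1, 1 - q[-n]))
  d <- l * q
  structure(
    tibble(age = as.integer(rates$age), mx = rates$mx, ax = a,
           qx = q, lx = l, dx = d),
    class = c("lifetable", class(tibble())))
}

# Observed cause-count matrix (ages 0..max_age in rows, causes in columns)
# and the per-age share rules: an age with observed deaths uses its own mix;
# ages >= pool_from use the pooled old-age mix (rates there come from
# extrapolation, with no reliable single-year cause splits); a younger age
# with no deaths borrows a symmetric window x-2..x+2, widened until deaths
# are found.
cause_share_matrix <- function(counts, causes, max_age, pool_from) {
  M <- matrix(0, nrow = max_age + 1, ncol = length(causes),
              dimnames = list(NULL, causes))
  M[cbind(counts$age + 1, match(counts$cause, causes))] <- counts$deaths
  row_tot <- rowSums(M)

  pooled_rows <- seq(min(pool_from, max_age) + 1, max_age + 1)
  pooled <- colSums(M[pooled_rows, , drop = FALSE])
  if (sum(pooled) == 0) pooled <- colSums(M) # degenerate old-age stratum
  pooled <- pooled / sum(pooled)

  shares <- matrix(0, nrow = max_age + 1, ncol = length(causes),
                   dimnames = list(NULL, causes))
  for (x in 0:max_age) {
    if (x >= pool_from) {
      shares[x + 1, ] <- pooled
    } else if (row_tot[x + 1] > 0) {
      shares[x + 1, ] <- M[x + 1, ] / row_tot[x + 1]
    } else {
      width <- 2
      repeat {
        rows <- seq(max(0, x - width), min(max_age, x + width)) + 1
        win <- colSums(M[rows, , drop = FALSE])
        if (sum(win) > 0) break
        width <- width + 1
      }
      shares[x + 1, ] <- win / sum(win)
    }
  }
  shares
}

#' Multiple-decrement life table
#'
#' Splits each life-table decrement `dx` across causes in proportion to the
#' observed cause-specific death counts at that age:
#' `d_{x,i} = dx * D_{x,i} / D_x`. Ages at or above `pool_from` (where rates
#' come from extrapolation, not single-year observation) all use the pooled
#' observed cause mix of deaths aged `pool_from`+; a younger age with no
#' observed deaths borrows the pooled mix of ages x-2..x+2, widening until
#' deaths are found.
#'
#' @param lt A [build_lifetable()] result.
#' @param cause_counts Observed deaths by age and cause for the same
#'   stratum: columns `age`, `cause` and either `deaths` or one row per
#'   death record.
#' @param pool_from First age of the pooled old-age cause mix (default 90).
#' @return A tibble of class `multidecrement_lifetable` with columns `age`,
#'   `cause`, `dxi`; the underlying life table is kept in the `"lifetable"`
#'   attribute.
#' @export
build_multidecrement <- function(lt, cause_counts, pool_from = 90) {
  if (!"deaths" %in% names(cause_counts)) {
    cause_counts <- cause_counts |> count(.data$age, .data$cause, name = "deaths")
  }
  counts <- cause_counts |>
    group_by(.data$age, .data$cause) |>
    summarise(deaths = sum(.data$deaths), .groups = "drop")
  if (sum(counts$deaths) == 0) abort("Stratum has zero observed deaths at every age.")
  causes <- sort(unique(counts$cause))
  max_age <- max(lt$age)
  if (any(counts$age > max_age) || any(counts$age < 0)) {
    abort("Observed cause counts fall outside the life table's age range.")
  }

  shares <- cause_share_matrix(counts, causes, max_age, pool_from)
  out <- tibble(
    age = rep(lt$age, each = length(causes)),
    cause = rep(causes, times = nrow(lt)),
    dxi = as.numeric(t(shares[lt$age + 1, , drop = FALSE])) *
      rep(lt$dx, each = length(causes))
  )
  structure(out, lifetable = lt,
            class = c("multidecrement_lifetable", class(tibble())))
}

#' Cause-of-death distribution over an age range
#'
#' Sums the cause-specific life-table decrements `d_{x,i}` over an age range
#' and drops causes with zero mass, yielding the abundance vector that feeds
#' [hill_diversity()].
#'
#' @param mdlt A [build_multidecrement()] result.
#' @param age_range Inclusive ages, e.g. `c(0, 74)` or `c(75, 110)`.
#' @return A tibble with columns `cause`, `n` (real-valued abundances).
#' @export
cause_distribution <- function(mdlt, age_range = c(0, 110)) {
  stopifnot(length(age_range) == 2)
  if (age_range[1] > age_range[2]) abort("Empty age range.")
  mdlt |>
    filter(.data$age >= age_range[1], .data$age <= age_range[2]) |>
    group_by(.data$cause) |>
    summarise(n = sum(.data$dxi), .groups = "drop") |>
    filter(.data$n > 0)
}
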