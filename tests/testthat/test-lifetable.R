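test_that("central rates are death/exposure ratios, scale-free, and guarded", {
  d <- tibble::tibble(age = rep(10L, 10))
  p <- tibble::tibble(age = 10L, count = 1000L)
  sched <- suppressWarnings(estimate_rates(d, p, ages = 10))
  expect_equal(sched$mx, 0.01)

  sched2 <- suppressWarnings(
    estimate_rates(d |> tidyr::uncount(2), p |> dplyr::mutate(count = count * 2),
                   ages = 10)
  )
  expect_equal(sched2$mx, sched$mx)

  reg <- tiny_registry()
  zero <- estimate_rates(reg$deaths[0, ], reg$population, ages = 0:89)
  expect_true(all(zero$mx == 0))

  expect_error(estimate_rates(d, p |> dplyr::mutate(count = 0L), ages = 10),
               "zero exposure")
  expect_warning(estimate_rates(d[0, ], p |> dplyr::mutate(count = 0L), ages = 10),
                 "zero exposure")
})

test_that("rates aggregate across zones within a stratum", {
  p <- tibble::tibble(age = c(10L, 10L), zone_id = c("a", "b"),
                      count = c(400L, 600L))
  d <- tibble::tibble(age = rep(10L, 5), zone_id = c("a", "a", "b", "b", "b"))
  expect_equal(suppressWarnings(estimate_rates(d, p, ages = 10))$mx, 5 / 1000)
})

test_that("the Kannisto-Makeham fit recovers generating parameters", {
  sched <- km_schedule(a = 0.08, b = 0.11, c = 0.01, seed = 101)
  fit <- fit_kannisto_makeham(sched, fit_ages = 70:89)
  expect_lt(abs(fit$a - 0.08) / 0.08, 0.10)
  expect_lt(abs(fit$b - 0.11) / 0.11, 0.10)
  expect_lt(abs(fit$c - 0.01) / 0.01, 0.10)
  expect_false(fit$fallback)
})

test_that("constant-hazard data collapses to the Makeham term", {
  ages <- 70:89
  withr::with_seed(5, deaths <- rpois(20, 1e6 * 0.02))
  sched <- tibble::tibble(age = ages, deaths = deaths, exposure = 1e6)
  fit <- fit_kannisto_makeham(sched)
  mu <- km_hazard(fit, ages + 0.5)
  expect_true(all(abs(mu - 0.02) / 0.02 < 0.01))
})

test_that("the chosen optimum beats every grid start", {
  sched <- km_schedule(a = 0.05, b = 0.09, c = 0.005, seed = 7)
  fit <- fit_kannisto_makeham(sched)
  dat <- sched[sched$exposure > 0, ]
  t <- dat$age + 0.5 - 70
  starts <- expand.grid(la = log(c(0.02, 0.08, 0.3)),
                        lb = log(c(0.08, 0.13)),
                        lc = log(c(1e-4, 5e-3)))
  for (i in seq_len(nrow(starts))) {
    start_ll <- -causediv:::km_negloglik(as.numeric(starts[i, ]),
                                         t, dat$deaths, dat$exposure)
    expect_gte(fit$loglik, start_ll)
  }
})

test_that("fit preconditions are enforced", {
  sched <- km_schedule(0.08, 0.11, 0.01, seed = 1)
  expect_error(fit_kannisto_makeham(sched |> dplyr::mutate(deaths = 0L)),
               "unidentifiable")
  expect_error(fit_kannisto_makeham(sched[1:4, ], fit_ages = 70:73), ">= 5 ages")
})

test_that("extrapolated rates follow the logistic law's shape", {
  flat <- list(a = 0, b = 0.1, c = 0.05, age_offset = 70)
  ext <- extrapolate_rates(flat)
  expect_equal(ext$mx, rep(0.05, 21))

  rising <- list(a = 0.08, b = 0.11, c = 0.01, age_offset = 70)
  ext2 <- extrapolate_rates(rising)
  expect_equal(ext2$age, 90:110)
  expect_true(all(diff(ext2$mx) > 0))
  expect_true(all(ext2$mx >= rising$c & ext2$mx < rising$c + 1))
  # logistic asymptote: the hazard approaches c + 1 from below at extreme ages
  expect_lt(abs(km_hazard(rising, 1000) - (rising$c + 1)), 1e-8)
})

test_that("a zero-mortality table survives everyone until the open interval", {
  lt <- build_lifetable(tibble::tibble(age = 0:110, mx = 0))
  expect_true(all(lt$lx == 1e5))
  expect_equal(lt$dx, c(rep(0, 110), 1e5))
  expect_equal(lt$qx[111], 1)
})

test_that("the m-to-q conversion and infant exception are applied", {
  lt <- build_lifetable(tibble::tibble(age = 0:110, mx = 0.1))
  expect_equal(lt$qx[2], 0.1 / 1.05)         # ax = 0.5
  expect_equal(lt$qx[1], 0.1 / (1 + 0.9 * 0.1)) # a0 = 0.1
  expect_equal(lt$ax, c(0.1, rep(0.5, 110)))
  lt2 <- build_lifetable(tibble::tibble(age = 0:110, mx = 0.1), a0 = 0.5)
  expect_equal(lt2$qx[1], 0.1 / 1.05)
})

test_that("every life table closes to the radix", {
  for (seed in 1:10) {
    lt <- build_lifetable(random_rates(seed))
    expect_lt(abs(sum(lt$dx) - 1e5) / 1e5, 1e-6)
    expect_true(all(diff(lt$lx) <= 0))
    expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  }
  expect_error(build_lifetable(tibble::tibble(age = 0:110, mx = -0.01)),
               "Negative")
})

test_that("constant hazard matches the closed-form survival curve", {
  m <- 0.07
  lt <- build_lifetable(tibble::tibble(age = 0:110, mx = m), a0 = 0.5)
  q <- m / (1 + 0.5 * m)
  expect_equal(lt$lx, 1e5 * (1 - q)^(0:110))
})

test_that("decrement splits respect observed cause mixes", {
  lt <- build_lifetable(random_rates(3))
  one <- tibble::tibble(age = 0:110, cause = "A00", deaths = 5L)
  md1 <- build_multidecrement(lt, one)
  expect_equal(md1$dxi, lt$dx)

  two <- dplyr::bind_rows(one, one |> dplyr::mutate(cause = "B00"))
  md2 <- build_multidecrement(lt, two)
  halves <- md2 |> tidyr::pivot_wider(names_from = cause, values_from = dxi)
  expect_equal(halves$A00, halves$B00)
  expect_equal(halves$A00 + halves$B00, lt$dx)
})

test_that("empty ages borrow neighbouring cause mixes; old ages use the pooled mix", {
  lt <- build_lifetable(tibble::tibble(age = 0:110, mx = 0.05))
  counts <- tibble::tibble(
    age = c(38L, 42L, rep(95L, 3)),
    cause = c("A00", "B00", "A00", "A00", "B00"),
    deaths = c(3L, 1L, 2L, 2L, 2L)
  )
  md <- build_multidecrement(lt, counts)
  # age 40 has no deaths: widening from +/-2 reaches ages 38 and 42 -> 3:1 mix
  at40 <- md |> dplyr::filter(age == 40) |> dplyr::arrange(cause)
  expect_equal(at40$dxi / sum(at40$dxi), c(0.75, 0.25))
  # all ages >= 90 share the pooled old-age mix (4 A00 : 2 B00)
  old <- md |> dplyr::filter(age >= 90) |>
    dplyr::group_by(age) |>
    dplyr::summarise(share = dxi[cause == "A00"] / sum(dxi))
  expect_true(all(abs(old$share - 4 / 6) < 1e-12))
  expect_error(build_multidecrement(lt, counts |> dplyr::mutate(deaths = 0L)),
               "zero observed deaths")
})

test_that("cause distributions conserve and decompose the decrements", {
  lt <- build_lifetable(random_rates(8))
  counts <- random_cause_counts(8)
  md <- build_multidecrement(lt, counts)
  full <- cause_distribution(md, c(0, 110))
  expect_equal(sum(full$n), 1e5, tolerance = 1e-9)
  young <- cause_distribution(md, c(0, 74))
  old <- cause_distribution(md, c(75, 110))
  merged <- dplyr::full_join(young, old, by = "cause") |>
    dplyr::mutate(total = tidyr::replace_na(n.x, 0) + tidyr::replace_na(n.y, 0))
  expect_equal(
    merged$total[order(merged$cause)],
    full$n[order(full$cause)]
  )
  expect_error(cause_distribution(md, c(80, 20)), "Empty age range")

  single <- build_multidecrement(lt, tibble::tibble(age = 50L, cause = "X99",
                                                    deaths = 1L))
  dist <- cause_distribution(single, c(0, 110))
  expect_equal(dist$cause, "X99")
  expect_equal(dist$n, 1e5)
})

test_that("fitted-then-extrapolated rates track the generating law at old ages", {
  true <- list(a = 0.08, b = 0.11, c = 0.01, age_offset = 70)
  sched <- km_schedule(0.08, 0.11, 0.01, seed = 55)
  fit <- fit_kannisto_makeham(sched)
  ext <- extrapolate_rates(fit, ages = 90:110)
  truth <- km_hazard(true, 90:110 + 0.5)
  expect_true(all(abs(ext$mx - truth) / truth < 0.02))
})
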