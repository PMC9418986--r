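---
title: "Measuring the diversity of mortality causes across subpopulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the diversity of mortality causes across subpopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causediv)
library(dplyr)
```

## The question and the measure

In high-income countries, falls in all-cause mortality have been driven
disproportionately by the historically dominant causes — cardiovascular
disease and cancers. As the leading causes shrink faster than the rest, the
distribution of deaths across causes becomes more even: mortality causes
*diversify*. causediv quantifies that process for subpopulations (sex,
broad age group, area-deprivation quintile) from individual-level death
records and mid-year population counts, and relates it to the
age-standardised mortality rate (ASMR).

The central quantity is the Hill number of order `q` of a cause-of-death
distribution with relative prevalences $p_i$:

$$ {}^qD = \Big(\sum_i p_i^q\Big)^{1/(1-q)}, \qquad
   {}^1D = \exp\Big(-\sum_i p_i \ln p_i\Big). $$

This is an *effective number of causes*: it equals the number of equally
prevalent causes that would produce the same diversity. At `q = 0` it counts
causes present; at `q = 1` (the headline measure here) each cause is
weighted exactly by its prevalence, so the value is the exponential of
Shannon entropy; larger `q` emphasises dominant causes (`q = 2` is inverse
Simpson). Values run from 1 (every death from one cause) to the number of
causes present (a perfectly even distribution). Because only proportions
enter, abundances may be real-valued, which is what allows life-table
decrements to be used directly.

```{r hill}
hill_diversity(c(1, 1, 1, 1), q = 1)   # uniform: richness
hill_diversity(c(1/2, 1/4, 1/4), q = 1) # 2^(3/2)
```

## Why life tables, and how they are built

Comparing raw cause counts between subpopulations confounds the cause
distribution with the age structure: older populations die of different
things. The package therefore extracts cause distributions from
**multiple-decrement period life tables**, which push a synthetic cohort of
100,000 through the observed age-specific mortality of one stratum
(year × sex, or year × quintile), so every stratum is measured on the same
age footing. Raw observed distributions are also supported
(`source = "observed"`) as a sensitivity route.

The life-table machinery follows standard demographic practice:

* **Central rates** $m_x = D_x / E_x$ are estimated at single years of age
  0–89 from deaths and mid-year counts (`estimate_rates()`).
* **Old-age extrapolation.** A single open 90+ interval would be too coarse
  given how many deaths occur there, so rates for ages 90–110+ come from a
  **Kannisto–Makeham** logistic hazard
  $\mu(x) = c + a e^{b(x - x_0)} / (1 + a e^{b(x - x_0)})$
  fitted to ages 70–89 (`fit_kannisto_makeham()`). The logistic term
  plateaus below $c + 1$, matching the observed deceleration of mortality at
  extreme ages; $c$ is an age-independent background hazard. The fit
  maximises the Poisson log-likelihood
  $\sum_x D_x \log \mu(x+0.5) - E_x \mu(x+0.5)$ over
  $(\log a, \log b, \log c)$ — robust at small counts, unlike least squares
  on log rates — from a 12-point grid of starts (Nelder–Mead then a BFGS
  polish, relative tolerance $10^{-12}$), keeping the best optimum. If no
  start yields a finite optimum the fit falls back to pure Kannisto
  ($c = 0$) and flags the result.
* **Table construction.** $q_x = m_x / (1 + (1-a_x) m_x)$ with $a_x = 0.5$
  except $a_0 = 0.1$ (infant deaths cluster early in the first year); the
  terminal age 110+ is an open interval with $q = 1$, so the table closes
  exactly: $\sum_x d_x = 100{,}000$. Both $a$ values are arguments of
  `build_lifetable()`.
* **Cause splits.** $d_{x,i} = d_x \, D_{x,i} / D_x$. Ages 90+ have
  extrapolated rates but no reliable single-year cause splits, so they all
  share the pooled observed cause mix of deaths at 90+; a younger age with
  no observed deaths borrows the pooled mix of ages $x\pm2$, widening until
  deaths are found. This keeps cause totals anchored to data while the
  all-cause level comes from the fitted law.

Several of these are genuine design choices the underlying methods
literature leaves open: the fit window (70–89 was chosen as the widest
old-age window wholly below the extrapolation region), the $a_x$
convention, and the pooled-90+ cause mix. All are exposed as arguments so a
user can vary them.

## Standardisation and trends

ASMRs use direct standardisation to the 2013 European Standard Population
in 5-year bands 0–4 … 85–89, 90+ (weights ship with the package and are
asserted to total 100,000). Age-restricted ASMRs (premature mortality 0–74;
older ages 75+) are renormalised by the weight sum of the included bands,
so a 0–74 ASMR is per 100,000 of the 0–74 standard population; this matches
usual premature-mortality practice and makes the full-range ASMR the
weight-sum combination of the two restricted ones. Percent reductions
between two years are reported as whole percents, rounded half away from
zero.

Trends are purely descriptive ordinary least-squares lines — diversity
against calendar year and against ASMR — reported as slope, intercept and
$r^2$ with no inferential statistics, since they summarise a complete
annual series rather than a sample. A trend is only reported for
subcommunities with at least three points and a non-constant predictor.

## The synthetic registry

Real vital-registration microdata cannot be redistributed, so the package
ships a seeded generator (`scenario_config()`, `simulate_registry()`)
producing the three tables the analysis consumes: zones, mid-year
population counts, and individual death records. It emulates the
statistical structure the analysis relies on:

* **Zones.** Income-deprivation rates are right-skewed Beta(1.5, 6) draws on
  (0, 1); zone populations are log-normal around a mean of 783 persons (the
  documented mean small-area population in the motivating setting).
* **Population.** Each zone's total is spread over ages 0–110 by a stylised
  pyramid (logistic roll-off centred at 82 with scale 7 years — monotone
  non-increasing at older ages) and split evenly between sexes, using
  largest-remainder rounding so zone totals are conserved exactly.
* **Deaths.** Cell counts are Poisson with mean `count × μ`, where μ is a
  Gompertz–Makeham baseline ($c + A e^{Bx}$, defaults $A = 3\times10^{-5}$,
  $B = 0.1$, $c = 3\times10^{-4}$, a realistic adult schedule giving a
  crude death rate near 1%) multiplied by a male:female ratio (1.5), a
  deprivation-quintile multiplier ($1.25^{\,3-q}$, so the most-deprived
  fifth faces ≈2.4 times the least-deprived hazard, echoing reported
  most-vs-least-deprived gaps above 100%), and a calendar improvement
  $e^{-\delta t}$ with $\delta = 0.015$/year (≈24% ASMR decline over 18
  years, inside the 17–34% range of published sex/age-group reductions).
  The multipliers act proportionally on the whole baseline hazard. Poisson
  (rather than binomial) cell counts are standard for rates and
  indistinguishable at $\mu \ll 1$; a cell with $\mu > 1$ is clipped with a
  warning.
* **Causes.** Codes are synthetic letter+two-digit strings spanning several
  letters to mimic ICD-10 chapters (no real ICD semantics). Each of three
  broad age groups (0–39, 40–74, 75+) has its own five leading causes whose
  summed probability interpolates linearly from 0.40 in the first year to
  0.25 in the last — the diversification scenario: leading causes
  contributing ≈40% at baseline and shrinking proportionally faster than
  the rest. Remaining mass is spread unevenly ($\propto 1/\sqrt{rank}$)
  over the other causes. Draws are ordered deterministically by
  (year, age, sex, zone) so a seed reproduces the registry byte-for-byte.

What the generator does **not** emulate: real ICD-10 code semantics and
chapter structure, migration and cohort effects in the population pyramid,
coding-practice discontinuities, geographic correlation between
neighbouring zones, or the two-vintage deprivation re-assignment midway
through a study period (the pipeline accepts one zones table per run).
Green tests therefore demonstrate that the *methods* behave correctly on
data with the assumed structure, not that any particular empirical finding
holds in real registries.

## Subcommunities and the pipeline

`run_pipeline()` chains the stages: simulate (optional) → quintiles → ASMR
→ life tables → decrements → diversity → trends. Subcommunities follow the
study design: per year and age range, stratified by sex (quintiles pooled)
and by quintile (sexes pooled) as two independent grids; a fully crossed
sex × quintile grid is available via `grouping = list(c("sex",
"quintile"))`. Deprivation quintiles are population-weighted: zones sorted
by income-deprivation rate, most deprived first, are cut at 20% population
blocks, a straddling zone going where its population midpoint falls (a
deterministic rule that keeps each quintile within one zone of 20%); ties
in the rate break by zone id. Weighting uses total population.

```{r pipeline}
cfg <- scenario_config(years = 2001:2005, n_zones = 40,
                       mean_population = 2000, seed = 1)
res <- suppressWarnings(run_pipeline(cfg, q = 1))
res$diversity |> filter(sex != "all") |> head(4)
res$trends |> filter(predictor == "year", sex != "all", q == 1)
```

Life tables per stratum are written as long tables
(`lifetables.csv`, `decrements.csv` keyed by year/sex/quintile) rather than
one file per stratum; the run manifest records configuration and row counts
but no timestamp, so re-running a configuration reproduces every output
byte-for-byte.

## Numerical choices and degenerate inputs

* Hill numbers drop zero-abundance causes ($0 \ln 0 := 0$); `q` within
  $10^{-12}$ of 1 uses the Shannon limit form, everything else the power
  form (numerically exact even at `q = 1 ± 1e-6`).
* A band with deaths but no population, an all-zero cause distribution, a
  constant predictor in a trend fit, and a stratum with no deaths anywhere
  all raise errors naming the offending unit; zero-exposure/zero-death ages
  record a zero rate with a warning.
* The Kannisto–Makeham background parameter $c$ is weakly identified from
  20 ages of data: its asymptotic relative standard deviation is ≈8% even
  at $10^6$ person-years of exposure per age (the slope and level
  parameters recover within ~2%). Users should not over-interpret fitted
  $c$ values from single strata of ordinary size.

## Problem sizes

The default scenario (200 zones, mean population 783, 19 years, 60 causes)
keeps a full pipeline run — 133 stratum life tables with maximum-likelihood
extrapolation fits — around half a minute on one core, which we consider a
sensible default for a fully synthetic analysis; the test suite uses
smaller grids of the same structure. All sample sizes scale freely through
`scenario_config()`.

## Limitations

Diversity values depend on the coding resolution of causes (here,
three-character-style codes) and on the number of deaths in a
subcommunity; small subcommunities give noisy, downward-biased effective
numbers, which is why the pipeline defaults to two broad age groups rather
than fine age bands. The trend fits are descriptive; no uncertainty is
propagated from the life-table construction into the diversity series.
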