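# wolfalps

Transboundary monitoring of a recolonising Alpine wolf population: a tested
R implementation of a shared interpretation standard for multi-country
wolf-presence data, plus a Bayesian state-space model for the growth of the
reproductive-unit count series.

## What it does, and for whom

Wolf populations recolonising a mountain range span several countries, and
national monitoring programmes cannot simply add their pack counts: border
territories get counted twice, and raw field data (tracks, scats, camera
images, genetic samples, howling surveys) follow different conventions.
This package is for population ecologists and wildlife-monitoring
coordinators who need a reproducible pipeline for that setting:

* **Sign validation** — every record is screened for genuineness and
  classified as hard evidence (**C1**: dead animals, live captures,
  telemetry, DNA-confirmed samples, good photo/video), confirmed
  observation (**C2**: documented tracks ≥ 100 m with typical pattern,
  expert-checked scats, kills with typical bites combined with other C2
  data, expert-checked howls with pups) or unconfirmed observation
  (**C3**: everything else), per monitoring year (1 May – 30 April).
* **Occurrence grid** — a 10 × 10 km cell is confirmed by ≥ 1 C1 or ≥ 2
  independent C2 signs; the area of occurrence is 100 km² per confirmed
  cell with centre inside the Alpine-range polygon.
* **Reproductive units** — C1/C2 signs are clustered into candidate
  territories (genetics first, 15 km spatial linkage second, 200 km²
  representation circles on MCP centroids); packs and pairs are confirmed
  on the agreed evidence rules; indistinguishable adjacent candidates are
  merged; cross-border units are resolved once, as transboundary (TR,
  genetic match across the border) or likely transboundary (LTR).
* **Growth model** — the yearly totals `y_t` follow a hierarchical
  state-space model: process `N_t = λ N_{t-1} ε_t`,
  `log ε_t ~ Normal(0, σ_p²)`; observation `y_t ~ Poisson(θ_t)` with
  `θ_t ~ Gamma(mean N_t, dispersion φ)` (a gamma-Poisson, i.e. negative
  binomial, observation layer). Missing years are imputed as latent
  states. Fitted with JAGS, uninformative priors, reproducible per-chain
  seeds.
* **Synthetic data** — a spatially explicit recolonisation simulator
  (branching territorial units, dispersal kernel with stepping stones,
  imperfect detection and genotyping, dispersers, noise signs) provides
  ground truth for end-to-end validation.

## Worked example

```r
library(wolfalps)

# classify three field records
signs <- data.frame(
  sign_id = c("a", "b", "c"), date = as.Date("2015-12-01") + 0:2,
  x = c(215, 216, 224), y = c(200, 201, 200), country = NA,
  evidence_type = "dna_sample", dna_confirmed_wolf = TRUE,
  genotype_label = c("G1", "G2", "G1"), genotype_sex = c("M", "F", "M"))
cl <- classify_signs(signs)
table(cl$category)                      # C1: 3

# the shared genotype G1 appears on both sides of the FR|CH border:
# one transboundary unit, counted once, confirmed as a pair (1 M + 1 F)
res <- resolve_units(cl, "2015-2016", alpine_layout())
res$units[, c("status", "countries", "transboundary_status")]
#>   status countries transboundary_status
#> 1   pair     CH-FR                   TR

# growth rate from the published reproductive-unit totals
# (1 in 1993-94, 5 in 1996-97, 77 in 2015-16, 243 in 2020-21)
fit <- fit_growth_model(alpine_count_series(),
                        mcmc = mcmc_preset("test", seed = 20),
                        on_nonconverged = "warn")
print(fit)
#> State-space growth fit: 28 years, 4 observed
#> lambda: mean 1.221 (sd 0.109), median 1.207, 95% CI [1.040, 1.492]
implied_geometric_rate(1, 243, 27)      # 1.2256, the deterministic check
```

The posterior mean says the number of reproductive units grew by ~22% per
year over the 28 monitoring years; the credible interval reflects that only
4 yearly totals inform the fit. (The latent abundances bridging the 18
unobserved years mix slowly, hence the warning mode; see the methods
vignette.)

The full analysis lives in `analysis/01_simulate.R` … `analysis/05_growth.R`:
simulate a reference synthetic population, classify its signs, build the
occurrence maps, resolve units per year, and fit the growth model to both
the synthetic and the published series. Each script prints what it found
and writes tables under `results/`. On the reference seed the pipeline
recovers all true unit-years with the correct pack/pair status and zero
genotype double-assignments.

## Package layout

* `R/` — geometry/layouts, sign classification, occurrence grid, unit
  resolution, the simulator, the growth model, pipeline orchestration.
* `analysis/` — the numbered analysis drivers.
* `tests/testthat/` — unit, property and acceptance tests.
* `vignettes/monitoring-methods.Rmd` — model assumptions, parameter
  defaults and their rationale, numerical choices, limitations.
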