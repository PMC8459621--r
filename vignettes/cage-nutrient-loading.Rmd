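---
title: "Nutrient mass balances and production performance of floating-cage farms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient mass balances and production performance of floating-cage farms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cageload)
```

## The accounting problem

A floating cage is an open system: pelleted feed and juvenile fish go in,
harvested and dead fish come out, and every kilogram of carbon, nitrogen or
phosphorus that enters but is not recovered remains in the waterbody. Over
a whole grow-out cycle this *loss* is what matters for eutrophication
management, and it can be computed from nothing more than the farm's
end-of-cycle bookkeeping plus a one-off proximate analysis of the feed and
the fish.

For nutrient X in {C, N, P}:

$$X_{loss} = (F \cdot x_F + J \cdot x_{fish}) - (H \cdot x_{fish} + M \cdot x_{fish})$$

with F, J, H, M the masses of feed, stocked juveniles, harvest and
mortalities (kg) and $x$ the nutrient mass fractions. Three modelling
assumptions deserve to be explicit:

* **One fish composition.** Juveniles, mortalities and harvest share a
  single measured fish composition; stage-specific compositions are rarely
  available and the juvenile and mortality terms are an order of magnitude
  smaller than the feed and harvest terms, so the approximation is cheap.
* **Mass basis.** Composition fractions are conventionally reported per
  unit *dry* weight, but cohort budgets published for this system are
  reproduced by applying the fractions to the masses *as recorded* by the
  farm (e.g. mean harvest 1226 kg × 0.1656 = 203.0 kg C, matching the
  published mean harvest carbon of 203.01 kg). `cageload` therefore
  defaults to `basis = "as_recorded"` and offers `basis = "dry_matter"` —
  each mass multiplied by (1 − moisture fraction) before the nutrient
  fraction — as the literal dry-weight reading. The two bases are exactly
  proportional per component, so the choice rescales budgets but never
  reorders cages.
* **Negative losses warn, never error.** Real bookkeeping (under-recorded
  feed, over-recorded harvest) can push a computed loss below zero. That is
  a data-quality signal the analyst must see, not an impossible state, so
  `cage_nutrient_loss()` flags it and keeps the row.

Faeces composition is carried in the composition table for reporting but
takes no part in the balance: the loss term already contains faecal,
dissolved and uneaten-feed waste in aggregate, and this package makes no
attempt to partition it.

## Performance metrics and their printed-formula quirks

The seven farm-characteristic metrics are standard, but three of them are
often printed in forms that do not survive dimensional analysis, and the
package takes a documented position on each:

* **SGR log base.** `specific_growth_rate()` uses the natural logarithm by
  default: for the study-mean cage (281.25 kg stocked, 1226 kg harvested,
  170 days) this gives 0.866 %/day, consistent with reported gourami SGRs
  of 0.87–1.04 %/day, while a base-10 reading gives 0.41 %/day — far below
  any reported value. Base 10 remains available via `log_base = 10`.
* **Gross yield.** Harvest biomass over cage volume, kg/m³. A trailing
  "×100" sometimes printed with this formula would yield ~1600 kg/m³ for a
  75 m³ cage and is dropped as a typographical artefact.
* **Feeding rate.** The default `"mean_biomass"` mode is the ration-level
  statistic farmers use: mean daily feed divided by mean standing biomass,
  (stock + harvest)/2, ×100. It lands the study-mean cage at 1.58 %/day,
  inside the reported 1.24–3.47% span. The `"literal"` mode — per-fish
  daily weight gain over mean harvest size, both in grams — is retained for
  transparency; it is a growth ratio (0.47% for the same cage), not a
  ration level, and should not be compared with feeding-level spans.
* **FCR denominator.** Feed over *total harvest weight*, the
  farm-accounting convention (2023/1226 = 1.65 for the study-mean cage).
  Note that elsewhere FCR often means feed over weight *gain*; with ~19% of
  harvest mass stocked, the two differ by ~23%.

## The synthetic cohort generator

`simulate_cages()` exists so that every downstream stage — validation,
balances, metrics, regressions, reporting — can be exercised end-to-end
with ground truth in hand. Its defaults emulate the observed conditions of
a 20-cage giant gourami cohort in 75 m³ cages: stocking density 40–107
fish/m³ with 70% of cages between 40 and 80 (a two-piece uniform mixture
split at 80), juveniles normal around 50 g (SD 2 g, truncated at 1 g),
integer cycle lengths uniform on 160–175 days, survival uniform on
86.33–95.27%, harvest size uniform on 225–290 g/fish and FCR uniform on
1.60–1.75. Uniform draws are used because the source observations are
reported as ranges, not distributions; the juvenile-weight SD is the one
place a spread had to be chosen, and 2 g (4% CV) reflects the grading
uniformity hatcheries deliver.

Derivations then follow the bookkeeping identities: `stock_count =
round(density × volume)`, `harvest_count = round(survival × stock_count)`,
`harvest_total = harvest_count × harvest_mean_weight`, and `feed = FCR ×
harvest_total`. Because feed is *derived* from the drawn FCR, the strong
feed–loss and feed–yield linearity seen across real farms emerges by
construction, and the drawn FCR and survival are recovered exactly (to
count rounding) by `compute_metrics()` — the parameter-recovery property
the tests rely on.

Dead fish are unobserved mid-cycle in end-of-cycle records; the generator
assigns each mortality half the harvest mean weight
(`dead_weight_fraction = 0.5`), reflecting deaths spread across the cycle.
This is configurable and only perturbs the small mortality term.

**What the generator does not emulate.** All draws are mutually
independent. Real cohorts have correlation structure — farms that stock
densely also tend to feed harder per unit biomass — and one reported
relationship depends on it entirely: feeding rate vs. net yield. The
feeding rate is biomass-normalised, so stocking density cancels out of it
algebraically (rate ≈ 200·FCR/(days·(1 + stock/harvest))), while net yield
is density-driven; under independence their cross-cage r² is ~0.01 where
real cohorts report ~0.96. The package computes the relationship honestly
and the cohort-level checks record the gap rather than engineering a
correlation the defaults do not imply. Passing tests therefore demonstrate
the arithmetic and the feed-driven relationships, not the behavioural
coupling of real farms. There are likewise no within-cycle dynamics: no
growth curves, no daily feed logs, no time-resolved mortality.

## Numerical and interface choices

* Records are one CSV row per cage with fixed column names; compositions
  are a small JSON object with an explicit `unit` key (`"percent"` by
  default, as proximate analyses are printed) so percent/fraction ambiguity
  cannot arise silently.
* Validation rejects violations of hard bookkeeping identities
  (`harvest_count + dead_count = stock_count`, positive volume and cycle,
  non-negative masses) naming the cage and the rule, but only *warns* when
  recorded stock weight disagrees with count × mean weight by more than 1%:
  both quantities are genuinely recorded and their disagreement is
  information.
* Least-squares lines are fitted with `stats::lm()`; r² is the squared
  Pearson correlation (identical to 1 − SSres/SStot for a line with
  intercept, which is always estimated). No p-values or intervals are
  reported at n = 20 cages; the line and r² are the summary of record.
  The independent closed-form normal-equation solution lives in the test
  suite as an oracle, and agreement is required to 1e-9.
* Aggregation uses the sample SD (n − 1); a single-cage aggregate reports
  SD 0 with `sd_defined = FALSE` rather than NA, so report tables stay
  numeric.
* `run_nutrient_report()` computes every stage before writing any file, so
  a failed stage leaves no partial bundle; `run.log` records the basis and
  mode flags so every reported number is auditable.
* Test and example problem sizes are 20-cage cohorts (the design being
  emulated), with property checks at 1000 records and coverage checks at
  1000 cages — comfortably exact for closed-form arithmetic of this kind.

## Known limitations

* The loss is a lump sum: no partition into dissolved vs. particulate or
  faecal vs. uneaten-feed fractions, and no water-quality modelling
  downstream of the load.
* Compositions are inputs; the package does not estimate them from
  laboratory measurements.
* Carrying-capacity or stocking-recommendation calculations are out of
  scope; the package reports what the cohort did, not what the lake can
  absorb.
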