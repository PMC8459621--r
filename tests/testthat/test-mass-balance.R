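test_that("dry-matter conversion applies the moisture fraction", {
  expect_equal(to_dry_mass(1226, 0.689), 381.286)
  expect_equal(to_dry_mass(123.4, 0), 123.4)
  expect_equal(to_dry_mass(0, 0.5), 0)
  expect_error(to_dry_mass(10, 1), "no dry matter")
  expect_error(to_dry_mass(-1, 0.5))
})

test_that("component nutrient mass reproduces the worked harvest-carbon value", {
  # mean harvest biomass x fish C fraction ~ published mean harvest C
  expect_equal(component_nutrient_mass(1226, 0.1656), 203.0256)
  expect_equal(component_nutrient_mass(0, 0.5), 0)
  # the feed mass implied by inverting the published mean feed-P
  m <- 14.38 / 0.0071
  expect_equal(m, 2025.352, tolerance = 1e-6)
  expect_equal(component_nutrient_mass(m, 0.0071), 14.38)
  # dry basis = as-recorded basis scaled by (1 - moisture)
  expect_equal(
    component_nutrient_mass(500, 0.2, "dry_matter", moisture_frac = 0.0875),
    component_nutrient_mass(500, 0.2) * (1 - 0.0875)
  )
})

test_that("nutrient loss reproduces the published cohort means from their components", {
  expect_equal(nutrient_loss(412.19, 44.49, 203.01, 17.40), 236.27)
  expect_equal(nutrient_loss(121.93, 8.39, 41.06, 4.73), 84.53)
  expect_equal(nutrient_loss(14.38, 1.11, 6.25, 0.53), 8.71)
  # zero outputs: loss equals total input (conservation)
  expect_equal(nutrient_loss(100, 10, 0, 0), 110)
})

test_that("per-cage balances conserve mass and match a long-hand oracle", {
  recs <- random_records(50, seed = 21)
  comp <- default_composition()
  bal <- suppressWarnings(cage_nutrient_loss(recs, comp))
  expect_equal(nrow(bal), 150)
  # conservation: inputs - outputs - loss == 0 exactly
  expect_equal(bal$input_feed + bal$input_juvenile - bal$output_harvest -
                 bal$output_dead - bal$loss, rep(0, nrow(bal)))
  # long-hand per-cage loop oracle
  for (i in sample(50, 8)) {
    r <- recs[i, ]
    for (nu in c("C", "N", "P")) {
      key <- paste0(tolower(nu), "_frac")
      expected <- (r$feed_supplied_kg * comp$feed[[key]] +
                     r$stock_total_weight_kg * comp$fish[[key]]) -
        (r$harvest_total_weight_kg * comp$fish[[key]] +
           r$dead_total_weight_kg * comp$fish[[key]])
      got <- bal$loss[bal$cage_id == r$cage_id & bal$nutrient == nu]
      expect_equal(got, expected)
    }
  }
})

test_that("doubling feed raises loss by exactly the feed-input increment", {
  recs <- random_records(10, seed = 22)
  bal1 <- cage_nutrient_loss(recs)
  recs2 <- dplyr::mutate(recs, feed_supplied_kg = feed_supplied_kg * 2)
  bal2 <- cage_nutrient_loss(recs2)
  expect_equal(bal2$input_feed, 2 * bal1$input_feed)
  expect_equal(bal2$loss - bal1$loss, bal1$input_feed)
})

test_that("dry-matter and as-recorded bases are proportional per component", {
  recs <- random_records(5, seed = 23)
  comp <- default_composition()
  wet <- cage_nutrient_loss(recs, comp, basis = "as_recorded")
  dry <- cage_nutrient_loss(recs, comp, basis = "dry_matter")
  expect_equal(dry$input_feed, wet$input_feed * (1 - comp$feed$moisture_frac))
  expect_equal(dry$output_harvest,
               wet$output_harvest * (1 - comp$fish$moisture_frac))
  expect_equal(dry$input_juvenile,
               wet$input_juvenile * (1 - comp$fish$moisture_frac))
  expect_equal(dry$feed_mass_basis,
               wet$feed_mass_basis * (1 - comp$feed$moisture_frac))
})

test_that("negative loss is flagged with a warning, not rejected", {
  recs <- random_records(1, seed = 24)
  recs$feed_supplied_kg <- 0  # nothing in, harvest out -> negative budget
  expect_warning(bal <- cage_nutrient_loss(recs), "negative nutrient loss")
  expect_true(all(bal$loss < 0))
})

test_that("per-tonne loading normalises loss by feed mass", {
  expect_equal(loading_per_tonne_feed(8.70, 2025.35), 4.2955, tolerance = 1e-4)
  expect_equal(loading_per_tonne_feed(0, 1500), 0)
  expect_equal(loading_per_tonne_feed(5, 1000), 5)
  expect_error(loading_per_tonne_feed(5, 0), "feed_mass")
})

test_that("aggregation reports mean, n-1 SD and true ranges per nutrient", {
  recs <- random_records(20, seed = 25)
  bal <- suppressWarnings(cage_nutrient_loss(recs))
  agg <- aggregate_balances(bal)
  expect_setequal(unique(agg$nutrient), c("C", "N", "P"))
  expect_setequal(unique(agg$quantity),
                  c("input_feed", "input_juvenile", "output_harvest",
                    "output_dead", "loss", "loading_per_tonne"))
  closs <- bal$loss[bal$nutrient == "C"]
  row <- agg[agg$nutrient == "C" & agg$quantity == "loss", ]
  expect_equal(row$mean, mean(closs))
  expect_equal(row$sd, sd(closs))        # sample SD, n - 1
  expect_equal(row$min, min(closs))
  expect_equal(row$max, max(closs))
  expect_equal(row$n, 20)
})

test_that("degenerate aggregations: single cage and identical cages", {
  recs1 <- random_records(1, seed = 26)
  agg1 <- aggregate_balances(cage_nutrient_loss(recs1))
  expect_true(all(agg1$sd == 0))
  expect_true(all(!agg1$sd_defined))

  one <- random_records(1, seed = 27)
  same <- dplyr::bind_rows(one, one, one)
  same$cage_id <- c("a", "b", "c")
  agg3 <- aggregate_balances(cage_nutrient_loss(same))
  expect_true(all(agg3$sd == 0))
  expect_true(all(agg3$min == agg3$max & agg3$min == agg3$mean))

  expect_error(aggregate_balances(cage_nutrient_loss(random_records(0))),
               "empty")
})
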