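test_that("specific growth rate uses the natural log by default", {
  # study-mean cage sits at the bottom of the 0.87-1.04 %/day span
  expect_equal(specific_growth_rate(281.25, 1226, 170), 0.86601, tolerance = 1e-4)
  expect_equal(specific_growth_rate(500, 500, 120), 0)
  # analytic identity: growth by a factor e over 100 days is exactly 1 %/day
  expect_equal(specific_growth_rate(100, 100 * exp(1), 100), 1)
  # base-10 option scales by 1/ln(10)
  expect_equal(specific_growth_rate(100, 1000, 100, log_base = 10), 1)
  expect_error(specific_growth_rate(0, 100, 10), "> 0")
  expect_error(specific_growth_rate(100, 100, 0), "cycle_days")
})

test_that("sgr is invariant under rescaling both weights", {
  set.seed(31)
  for (k in 1:20) {
    s <- runif(1, 100, 500); h <- runif(1, 600, 2000); d <- runif(1, 100, 200)
    scale <- runif(1, 0.1, 10)
    expect_equal(specific_growth_rate(s * scale, h * scale, d),
                 specific_growth_rate(s, h, d))
  }
})

test_that("gross and net yields are per-volume biomasses with the stocked offset", {
  expect_equal(gross_fish_yield(1226, 75), 16.3467, tolerance = 1e-4)
  expect_equal(gross_fish_yield(0, 75), 0)
  expect_equal(gross_fish_yield(75, 75), 1)
  expect_equal(net_fish_yield(1226, 281.25, 75), 12.5967, tolerance = 1e-4)
  expect_equal(net_fish_yield(300, 300, 75), 0)
  expect_error(gross_fish_yield(100, 0), "volume")
  # algebraic cross-check: net = gross - stock/volume
  set.seed(32)
  for (k in 1:20) {
    h <- runif(1, 500, 2000); s <- runif(1, 100, 400); v <- runif(1, 50, 100)
    expect_equal(net_fish_yield(h, s, v), gross_fish_yield(h, v) - s / v)
  }
})

test_that("FCR divides feed by harvest weight and FCE is its reciprocal", {
  expect_equal(feed_conversion_ratio(2023, 1226), 1.65, tolerance = 1e-3)
  expect_equal(feed_conversion_ratio(0, 500), 0)
  expect_equal(feed_conversion_ratio(850, 850), 1)
  expect_error(feed_conversion_ratio(100, 0), "harvest")
  expect_equal(feed_conversion_efficiency(1.65), 0.606, tolerance = 1e-3)
  expect_error(feed_conversion_efficiency(0), "fcr")
  # waste fraction: 1 kg feed at FCE 0.60 leaves 0.40 kg unconverted
  expect_equal(1 - feed_conversion_efficiency(1 / 0.60), 0.40)
  # reciprocal pair property: fce(fcr(f, h)) = h / f
  set.seed(33)
  for (k in 1:20) {
    f <- runif(1, 1000, 3000); h <- runif(1, 500, 2000)
    expect_equal(feed_conversion_efficiency(feed_conversion_ratio(f, h)), h / f)
  }
})

test_that("feeding rate modes: ration over mean biomass vs literal growth ratio", {
  # study-mean cage: ~1.58 % of standing biomass per day
  expect_equal(feeding_rate(2023, 170, 281.25, 1226), 1.5790, tolerance = 1e-3)
  expect_equal(feeding_rate(0, 170, 281.25, 1226), 0)
  # literal mode is a per-fish growth ratio, far below the ration level
  lit <- feeding_rate(2023, 170, 281.25, 1226, mode = "literal",
                      stock_count = 5625, harvest_count = 5000)
  expect_equal(lit, 0.468, tolerance = 1e-2)
  expect_lt(lit, 1.24)  # outside the observed 1.24-3.47 ration span
  expect_error(feeding_rate(2023, 170, 281.25, 1226, mode = "literal"),
               "literal mode needs")
  expect_error(feeding_rate(100, 0, 10, 20), "cycle_days")
})

test_that("survival is the harvested share of stocked fish", {
  expect_equal(survival_rate(5000, 5625), 88.8889, tolerance = 1e-4)
  expect_equal(survival_rate(4321, 4321), 100)
  expect_equal(survival_rate(0, 4321), 0)
  expect_error(survival_rate(10, 0), "stock_count")
  expect_error(survival_rate(11, 10), "exceed")
})

test_that("compute_metrics satisfies the metric identities on random records", {
  recs <- random_records(40, seed = 34)
  m <- compute_metrics(recs)
  expect_equal(nrow(m), 40)
  expect_equal(m$fce * m$fcr, rep(1, 40))
  expect_equal(m$gross_yield - m$net_yield,
               recs$stock_total_weight_kg / recs$volume_m3)
  expect_equal(m$survival + 100 * recs$dead_count / recs$stock_count,
               rep(100, 40))
  expect_true(all(m$survival >= 0 & m$survival <= 100))
})

test_that("a zero-growth cage has zero sgr and net yield", {
  recs <- random_records(1, seed = 35)
  recs$harvest_total_weight_kg <- recs$stock_total_weight_kg
  m <- compute_metrics(recs)
  expect_equal(m$sgr, 0)
  expect_equal(m$net_yield, 0)
})
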