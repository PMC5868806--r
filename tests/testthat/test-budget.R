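test_that("net growth efficiency is the incorporation share of processing", {
  expect_equal(net_growth_efficiency(1, 1), 0.5)
  expect_equal(net_growth_efficiency(1, 0), 1)
  expect_equal(net_growth_efficiency(1, 9), 0.10)
  expect_true(is.na(net_growth_efficiency(0, 0)))
  # invariant to common rescaling, bounded in [0, 1]
  set.seed(8)
  a <- runif(50); b <- runif(50)
  expect_equal(net_growth_efficiency(3 * a, 3 * b),
               net_growth_efficiency(a, b))
  expect_true(all(net_growth_efficiency(a, b) >= 0 &
                    net_growth_efficiency(a, b) <= 1))
})

test_that("carbon budget closes exactly and scales linearly with rates", {
  b <- carbon_budget(tissue_rate = 0.146, respiration_rate = 2.53,
                     calcification_rate = 0.0023, biomass_mmol = 10.128,
                     skeleton_mmol = 100, feeding_days = 10, added_c = 8125)
  expect_equal(b$tissue + b$respiration + b$calcification + b$unaccounted,
               b$added, tolerance = 1e-12)
  b2 <- carbon_budget(2 * 0.146, 2 * 2.53, 2 * 0.0023, 10.128, 100, 10, 8125)
  expect_equal(b2$tissue, 2 * b$tissue)
  expect_equal(b2$respiration, 2 * b$respiration)
  expect_equal(b2$calcification, 2 * b$calcification)
  expect_equal(b2$added, b$added)
  # zero rates: everything unaccounted
  b0 <- carbon_budget(0, 0, 0, 10, 100, 10, 2708)
  expect_equal(b0$unaccounted, 2708)
  expect_error(carbon_budget(0.1, 1, 0.01, 10, 0, 10, 100), "skeleton")
})

test_that("negative components are flagged, never dropped", {
  b <- budget_row(tissue = -0.5, respiration = 10, calcification = 0,
                  added = 100)
  expect_true(b$negative_component)
  expect_equal(b$unaccounted, 100 - (-0.5 + 10))
})

test_that("total processed and fraction accounted", {
  b <- budget_row(14.8, 256.1, 2.3, 8125)
  expect_equal(total_processed(b), 273.2)
  expect_equal(fraction_accounted(b), 273.2 / 8125)
  # coral x algae: 111 / 2708 (hand arithmetic)
  ba <- budget_row(9.4, 98.5, 3.1, 2708)
  expect_equal(fraction_accounted(ba), 0.041, tolerance = 1e-2)
  expect_equal(fraction_accounted(budget_row(50, 30, 20, 100)), 1)
  expect_equal(fraction_accounted(budget_row(0, 0, 0, 100)), 0)
})

test_that("stoichiometric uptake is the ratio of rate means", {
  s <- stoichiometric_uptake(0.12, 0.12)
  expect_equal(s$uptake_cn, 1)
  expect_equal(stoichiometric_uptake(0.12, 0.08)$uptake_cn, 1.5)
  expect_true(is.na(stoichiometric_uptake(0.12, 0)$uptake_cn))
})

test_that("generator with uptake C:N set to the food C:N recovers the food C:N", {
  # true C and N rates in a 6.6:1 ratio for algae and 4.5:1 for bacteria:
  # the recovered stoichiometric uptake must sit at the food value
  cfg <- truth_config(
    seed = 13,
    incorporation_c = c(coral.algae = 0.66, coral.bacteria = 0.45,
                        sponge.algae = 6.6, sponge.bacteria = 4.5),
    incorporation_n = c(coral.algae = 0.1, coral.bacteria = 0.1,
                        sponge.algae = 1.0, sponge.bacteria = 1.0))
  sim <- simulate_experiment(cfg)
  fit <- tracer_analysis(sim$measurements, sim$chambers, sim$foods,
                         anova = FALSE)
  st <- fit$stoichiometry
  expect_equal(st$uptake_cn[st$food == "algae"],
               rep(6.6, sum(st$food == "algae")), tolerance = 0.05)
  expect_equal(st$uptake_cn[st$food == "bacteria"],
               rep(4.5, sum(st$food == "bacteria")), tolerance = 0.05)
})
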