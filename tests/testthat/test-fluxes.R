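test_that("tracer uptake scales excess by pool over enrichment", {
  expect_equal(tracer_uptake(0, 100, 0.5), 0)
  expect_equal(tracer_uptake(0.001, 10000, 0.5), 20)
  # hand arithmetic: 0.0005 * 451 / 0.25 (mean sponge tissue C pool)
  expect_equal(tracer_uptake(0.0005, 451, 0.25), 0.902)
  expect_error(tracer_uptake(0.001, 100, 0), "enrichment")
  expect_error(tracer_uptake(0.001, 0, 0.5), "pool")
})

test_that("tracer uptake is linear in excess and pool; halving enrichment doubles it", {
  set.seed(4)
  e <- runif(20, 1e-5, 1e-2)
  pool <- runif(20, 10, 1e5)
  expect_equal(tracer_uptake(2 * e, pool, 0.25), 2 * tracer_uptake(e, pool, 0.25))
  expect_equal(tracer_uptake(e, 2 * pool, 0.25), 2 * tracer_uptake(e, pool, 0.25))
  expect_equal(tracer_uptake(e, pool, 0.125), 2 * tracer_uptake(e, pool, 0.25))
})

test_that("biomass-normalized rate divides by biomass and time", {
  # 14.8 umol over 10 d on the mean coral tissue pool: inside the coral range
  r <- biomass_normalized_rate(14.8, 10.128, 10)
  expect_equal(r, 0.146, tolerance = 1e-2)
  expect_gt(r, 0.08); expect_lt(r, 0.17)
  expect_equal(biomass_normalized_rate(0, 5, 10), 0)
  expect_equal(biomass_normalized_rate(10, 2 * 5, 10),
               biomass_normalized_rate(10, 5, 10) / 2)
  expect_error(biomass_normalized_rate(1, 0, 10), "biomass")
  expect_error(biomass_normalized_rate(1, 5, 0), "duration")
})

test_that("respiration rate follows the DIC-excess chain", {
  f0 <- 0.011
  expect_equal(respiration_rate(f0, f0, 2000, 10, 0.25, 2, 10), 0)
  # E = 5e-4, DIC pool 2000 umol/L x 10 L, /0.25 /2 d /10 mmol = 2.0
  expect_equal(respiration_rate(f0 + 5e-4, f0, 2000, 10, 0.25, 2, 10), 2.0)
  # linear in the excess
  expect_equal(respiration_rate(f0 + 1e-3, f0, 2000, 10, 0.25, 2, 10), 4.0)
  expect_error(respiration_rate(f0, f0, 0, 10, 0.25, 2, 10), "DIC")
})

test_that("calcification uptake is whole-sample minus organic, signed", {
  expect_equal(calcification_uptake(12, 12), 0)
  expect_equal(calcification_uptake(12.0, 9.4), 2.6)
  expect_lt(calcification_uptake(9.0, 9.4), 0)
  # rate form: 2.6 umol over 10 d on 100 mmol skeleton C, in nmol
  expect_equal(biomass_normalized_rate(2.6, 100, 10) * 1000, 2.6)
})

test_that("food_source validates its invariants", {
  f <- food_source("algae", "C", 0.25, 6.6, 2708)
  expect_equal(f$added_n, 2708 / 6.6)
  expect_error(food_source("x", "C", 0, 6.6, 100), "enrichment")
  expect_error(food_source("x", "C", 1.2, 6.6, 100), "enrichment")
  expect_error(food_source("x", "C", 0.5, -1, 100), "cn_ratio")
  expect_error(food_source("x", "C", 0.5, 6.6, -5), "added_c")
})
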