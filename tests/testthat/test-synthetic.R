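test_that("zero-noise simulation is inverted exactly for all four rate kinds", {
  sim <- simulate_experiment(truth_config(seed = 31, noise_sd_permil = 0))
  rates <- tracer_rates(sim$measurements, sim$chambers, sim$foods)
  rec <- recovery_table(rates, sim)
  expect_equal(nrow(rec), nrow(sim$truth))  # every truth row recovered
  expect_setequal(unique(rec$kind),
                  c("incorporation", "respiration", "calcification"))
  expect_lt(max(abs(rec$rel_error), na.rm = TRUE), 1e-9)
  # rates with true value 0 recovered as exactly 0 is not required, but the
  # recovered absolute values must be tiny
  zero <- rec$true_value == 0
  if (any(zero)) expect_lt(max(abs(rec$value[zero])), 1e-12)
})

test_that("the same seed reproduces the simulation exactly", {
  cfg <- truth_config(seed = 32)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$chambers, s2$chambers)
  expect_identical(s1$truth, s2$truth)
})

test_that("controls sit at natural abundance; labeled samples exceed them", {
  cfg <- truth_config(seed = 33, noise_sd_permil = 0)
  sim <- simulate_experiment(cfg)
  m <- sim$measurements
  tis_c <- m[m$pool == "tissue" & m$element == "C", ]
  tis_n <- m[m$pool == "tissue" & m$element == "N", ]
  expect_equal(unique(tis_c$delta_control), -20)
  expect_equal(unique(tis_n$delta_control), 8)
  # with positive true rates and zero noise, every sample exceeds its control
  expect_true(all(m$delta_sample > m$delta_control))
  # noisy controls cluster around the configured backgrounds
  simn <- simulate_experiment(truth_config(seed = 34, noise_sd_permil = 0.2))
  mn <- simn$measurements
  ctrl_c <- unique(mn$delta_control[mn$pool == "tissue" & mn$element == "C"])
  expect_true(all(abs(ctrl_c - (-20)) < 0.5))
})

test_that("recovered rates are unbiased at large replication", {
  # the control mean is shared across chambers, so its error only vanishes
  # when the control pool grows alongside the chamber replication
  cfg <- truth_config(seed = 35, replicates = 100, control_replicates = 100)
  sim <- simulate_experiment(cfg)
  rates <- tracer_rates(sim$measurements, sim$chambers, sim$foods)
  rec <- recovery_table(rates, sim)
  rec <- rec[rec$true_value > 0 & rec$taxon %in% c("coral", "sponge"), ]
  ratio <- rec$value / rec$true_value
  for (k in unique(rec$kind)) {
    x <- ratio[rec$kind == k]
    se <- stats::sd(x) / sqrt(length(x))
    # mean recovery within 4 SE of 1 (plus a floor for the shared control)
    expect_lt(abs(mean(x) - 1), max(4 * se, 0.05))
  }
})

test_that("label saturation and invalid configurations are rejected", {
  expect_error(truth_config(noise_sd_permil = -1), "noise")
  expect_error(truth_config(enrichment = c(algae = 0, bacteria = 0.25)),
               "enrichment")
  expect_error(truth_config(incorporation_c = c(coral.algae = -1)), "rates")
  cfg <- truth_config(seed = 36, noise_sd_permil = 0,
                      incorporation_c = c(coral.algae = 1e7,
                                          coral.bacteria = 1e7,
                                          sponge.algae = 1e7,
                                          sponge.bacteria = 1e7))
  expect_error(simulate_experiment(cfg), "label saturation")
})
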