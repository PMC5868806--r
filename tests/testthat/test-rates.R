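# The chained pipeline against a single-expression brute-force recomputation
# from raw deltas, plus structural properties of the rate table.

brute_rate <- function(d_sample, d_control, pool_umol, enr, days, element) {
  rref <- if (element == "C") 0.0111797 else 0.0036765
  f <- function(d) { r <- rref * (d / 1000 + 1); r / (r + 1) }
  ((f(d_sample) - f(d_control)) * pool_umol / enr) / (pool_umol / 1000) / days
}

test_that("chained rates equal the brute-force expression from raw deltas", {
  sim <- simulate_experiment(truth_config(seed = 11, replicates = 2))
  rates <- tracer_rates(sim$measurements, sim$chambers, sim$foods)
  m <- sim$measurements[sim$measurements$pool == "tissue", ]
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    enr <- sim$foods$enrichment[sim$foods$treatment == row$treatment &
                                  sim$foods$labeled_element == row$element]
    expected <- brute_rate(row$delta_sample, row$delta_control, row$pool_umol,
                           enr, 10, row$element)
    got <- rates$value[rates$kind == "incorporation" &
                         rates$treatment == row$treatment &
                         rates$composition == row$composition &
                         rates$replicate == row$replicate &
                         rates$taxon == row$taxon &
                         rates$element == row$element]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("zero label everywhere yields exactly zero rates", {
  sim <- simulate_experiment(truth_config(seed = 2))
  m <- sim$measurements
  m$delta_sample <- m$delta_control  # sample identical to its control
  ch <- sim$chambers
  ch$delta_dic_end <- ch$delta_dic_start
  rates <- tracer_rates(m, ch, sim$foods)
  expect_identical(max(abs(rates$value)), 0)
  expect_false(any(rates$negative))
})

test_that("negative excess is preserved and flagged, not clamped", {
  sim <- simulate_experiment(truth_config(seed = 3, noise_sd_permil = 0))
  m <- sim$measurements
  i <- which(m$pool == "tissue" & m$element == "C")[1]
  m$delta_sample[i] <- m$delta_control[i] - 0.5  # below background
  rates <- tracer_rates(m, sim$chambers, sim$foods)
  key <- rates$kind == "incorporation" & rates$element == "C" &
    rates$treatment == m$treatment[i] & rates$composition == m$composition[i] &
    rates$replicate == m$replicate[i] & rates$taxon == m$taxon[i]
  expect_lt(rates$value[key], 0)
  expect_true(rates$negative[key])
})

test_that("mixed-chamber respiration is normalized to the summed tissue C", {
  sim <- simulate_experiment(truth_config(seed = 5, noise_sd_permil = 0))
  rates <- tracer_rates(sim$measurements, sim$chambers, sim$foods)
  mix <- rates[rates$kind == "respiration" &
                 rates$composition == "coral+sponge", ]
  m <- sim$measurements
  for (i in seq_len(nrow(mix))) {
    sel <- m$treatment == mix$treatment[i] &
      m$composition == "coral+sponge" & m$replicate == mix$replicate[i] &
      m$pool == "tissue" & m$element == "C"
    expect_equal(mix$biomass_mmol[i], sum(m$pool_umol[sel]) / 1000)
  }
  # consortium rate lies between the two single-taxon rates
  single <- rates[rates$kind == "respiration" &
                    rates$composition %in% c("coral", "sponge"), ]
  expect_true(all(mix$value > min(single$value) &
                    mix$value < max(single$value)))
})

test_that("rate table structure is consistent and errors are informative", {
  sim <- simulate_experiment(truth_config(seed = 6, replicates = 1))
  rates <- tracer_rates(sim$measurements, sim$chambers, sim$foods)
  expect_setequal(unique(rates$kind),
                  c("incorporation", "calcification", "respiration"))
  # one respiration record per chamber
  expect_equal(sum(rates$kind == "respiration"), nrow(sim$chambers))
  # calcification only for corals
  expect_true(all(rates$taxon[rates$kind == "calcification"] == "coral"))
  # unknown chamber
  m <- sim$measurements
  m$replicate[1] <- 99
  expect_error(tracer_rates(m, sim$chambers, sim$foods), "no matching chamber")
  # food missing for one treatment/element
  foods <- sim$foods[-1, ]
  expect_error(tracer_rates(sim$measurements, sim$chambers, foods),
               "exactly one food source")
})
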