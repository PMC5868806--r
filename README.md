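# dualtracer

Analysis of dual stable-isotope (¹³C/¹⁵N) pulse-chase feeding experiments
with benthic suspension feeders — the kind of closed-chamber experiment used
to ask whether a cold-water coral and an encrusting sponge compete for the
same suspended food. Two diet components (algae and bacteria) are fed in a
crossed labeling design (¹³C-algae + ¹⁵N-bacteria vs. ¹⁵N-algae +
¹³C-bacteria) to corals, sponges, and coral–sponge pairs; the label is then
traced into tissue, the coral's carbonate skeleton, and the dissolved
inorganic carbon (DIC) pool of the sealed chamber.

For whom: isotope ecologists and ecophysiologists who have per-specimen
delta values and want defensible, unit-safe rates, budgets and tests without
re-deriving the tracer arithmetic each time.

## What it computes

From delta notation, δX (‰) = (R_sample/R_ref − 1) × 1000 with
R_ref = 0.0111797 (C) and 0.0036765 (N), the package chains

* atomic fraction F = R/(R + 1) and excess E = F_sample − F_control,
* tracer uptake = E × pool (µmol) / food label enrichment,
* biomass-normalized rates (µmol tracer mmol⁻¹ d⁻¹): tissue incorporation
  over the 10-d feeding period, respiration from DIC enrichment over the
  48-h closed incubation, and metabolic-derived calcification as
  whole-sample minus organic-fraction tracer on the skeleton C pool,
* per-replicate carbon budgets with exact closure
  (unaccounted = added − tissue − respiration − calcification),
  net growth efficiency NGE = I/(I + R), stoichiometric (C:N) uptake,
* the factorial fixed-effects ANOVAs on log₁₀-transformed rates
  (species × food; presence-of-other-taxon × food × element).

A synthetic-experiment generator (`simulate_experiment()`) forward-simulates
the complete measurement chain from configurable true rates, so every stage
is validated by parameter recovery: exact inversion at zero noise, unbiased
recovery at realistic IRMS noise (sd 0.2 ‰).

## Worked example

```r
library(dualtracer)
sim <- simulate_experiment(truth_config(seed = 7))   # 18-chamber design
fit <- tracer_analysis(sim$measurements, sim$chambers, sim$foods)
fit
#> Dual-tracer feeding experiment analysis
#>   chambers:         18
#>   rate records:     78 (0 negative, flagged)
#>   budget rows:      12 (single-species chambers)
#>   ANOVA models:     incorporation_c, incorporation_n, respiration, nge,
#>                     presence_coral, presence_sponge, calcification
summary(fit)
```

`summary()` prints the rate means (the seed-7 run recovers, e.g., coral C
incorporation 0.120 ± 0.0005 on algae and sponge C incorporation 3.998 ±
0.0004 µmol mmol⁻¹ d⁻¹ on bacteria — the configured truths are 0.12 and
4.0), the budget:

```
== Carbon budget (umol C over the feeding period, mean +/- sd) ==
  taxon     food       tissue    respiration calcification unaccounted added
  coral    algae 12.6 +/- 0.4  106.1 +/- 2.8   4.2 +/- 1.4  2585 +/- 2  2708
 sponge    algae 13.2 +/- 1.9 290.9 +/- 42.1   0.0 +/- 0.0 2404 +/- 44  2708
  coral bacteria 21.1 +/- 3.7 252.1 +/- 44.7   4.9 +/- 1.4 7847 +/- 49  8125
 sponge bacteria 15.5 +/- 4.9 253.5 +/- 78.6   0.0 +/- 0.0 7856 +/- 84  8125
```

(most of the added food pulse is never captured — the chambers are fed in
excess), net growth efficiencies around 4–11 %, and the ANOVA table, where
the order-of-magnitude species difference dominates
(`incorporation_c: species F(1,9)=...` at p « 0.001).

The bundled worked example reproduces a published-style budget from mean
tracer amounts:

```r
example_budget()
#>    taxon     food tissue respiration calcification added unaccounted ...
#> 1  coral bacteria   14.8       256.1           2.3  8125        7852
#> 2  coral    algae    9.4        98.5           3.1  2708        2597
#> 3 sponge bacteria   37.2       308.2           0.0  8125        7780
#> 4 sponge    algae    8.0       210.7           0.0  2708        2489
```

with `total_processed` 273, 111, 345 and 219 µmol C.

File-based analyses use the same surface:
`run_tracer_pipeline(measurements = "m.csv", chambers = "c.csv",
foods = "f.csv", out_dir = "results")` (schemas documented in
`?read_measurements`), and `inst/scripts/dualtracer-cli.R` wraps
simulate / analyze / budget-example for shell use.

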