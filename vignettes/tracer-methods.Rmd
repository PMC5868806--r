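---
title: "From delta values to carbon budgets: methods behind dualtracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From delta values to carbon budgets: methods behind dualtracer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtracer)
```

## The experimental design this package analyzes

dualtracer analyzes dual stable-isotope (^13^C/^15^N) pulse-chase feeding
experiments with benthic suspension feeders — the motivating system is a
cold-water coral and an encrusting sponge held in closed 10-L incubation
chambers. Two diet components (cultured algae and bacteria) are isotopically
labeled in a crossed way: in one treatment the algae carry the ^13^C label and
the bacteria the ^15^N label, in the complementary treatment the labels are
swapped. Each chamber holds a coral, a sponge, or both, with three replicate
chambers per cell of the design. Animals are fed daily over a 10-day period;
after the last feeding the chamber is sealed for 48 h and the ^13^C
enrichment of the dissolved inorganic carbon (DIC) pool is measured as a
proxy for respiration of labeled food. At the end, tissue, whole sample
(organic fraction plus carbonate skeleton, for the coral) and DIC are
measured by isotope-ratio mass spectrometry, each against unfed control
specimens.

Because every food's C and N labels are fed in different treatments, C uptake
of a food and N uptake of the same food are measured on different specimens —
this drives several analysis choices below.

## The conversion chain

Measurements arrive in delta notation,
$\delta X\ (\unicode{x2030}) = (R_\mathrm{sample}/R_\mathrm{ref} - 1) \times 1000$,
with fixed reference ratios $R_\mathrm{ref} = 0.0111797$ for C and
$0.0036765$ for N. The chain applied to every measurement is:

1. ratio: $R = R_\mathrm{ref}(\delta/1000 + 1)$;
2. atomic fraction: $F = R/(R+1)$;
3. excess over background: $E = F_\mathrm{sample} - F_\mathrm{control}$;
4. tracer amount: $E \times \mathrm{pool}\ (\mu mol) / \mathrm{enrichment}$,
   where the enrichment is the realized atom fraction of the label in the
   food source;
5. rate: tracer amount / biomass (mmol of the same element) / duration (d).

Respiration uses the same chain on the DIC pool
($\mathrm{DIC\ concentration} \times \mathrm{chamber\ volume}$) over the 48-h
closed incubation, normalized to the summed tissue C of every specimen in the
chamber; in mixed chambers the resulting rate belongs to the coral–sponge
consortium and is never attributed to a single taxon. Metabolic-derived
calcification is obtained by difference: tracer in the whole
(organic + skeleton) sample minus tracer in the organic fraction, normalized
to the skeleton C pool.

Duration conventions: incorporation and calcification rates divide by the
full 10-day feeding period (daily rates averaged over the experiment, the
convention such experiments report); respiration divides by the 2-day closed
incubation it was measured in. The carbon budget then extrapolates all rates
over the feeding period under an explicit constant-rate assumption.

### Numerical and policy choices

* **Signed excess.** $E$ is returned signed. An unlabeled or weakly labeled
  sample can fall below its control by measurement noise; clamping negative
  values to zero would bias means upward and distort the error structure the
  ANOVAs rely on. Negative rates are flagged (`negative` column) and carried
  through.
* **Control pairing.** Each experimental specimen is paired with the *mean*
  delta of the control specimens of the same taxon and pool. The mean is a
  single shared number per taxon × pool, which makes replicate rates within
  an experiment positively correlated — see the validation section.
* **Units.** All internal computation is in µmol (amounts), mmol (biomass)
  and µmol mmol^-1^ d^-1^ (rates). Calcification is only rescaled to
  nmol mmol^-1^ d^-1^ in written outputs, where a `unit` column makes the
  scale explicit. Report tables round to one decimal for budget components
  and to integers for the unaccounted closure term; objects keep full
  precision.
* **Degenerate inputs.** Zero or negative pools, durations, enrichments and
  out-of-range deltas ($\le -1000$ ‰) are errors, not silent NAs; an
  atomic fraction implied at or above 1 in the generator aborts with a
  "label saturation" error.

## Budget, efficiency, stoichiometry

For each single-species chamber and its ^13^C-labeled food the carbon budget
is
$\mathrm{unaccounted} = \mathrm{added} - (\mathrm{tissue} +
\mathrm{respiration} + \mathrm{calcification})$,
with every component scaled to the whole feeding period. The identity holds
exactly by construction, and the suite checks it to $10^{-9}$ µmol. Budgets
are computed per replicate and then summarized as mean ± sd, not from mean
rates — this matches how replicated budget tables are reported and gives the
sd a meaning. Net growth efficiency,
$\mathrm{NGE} = I/(I + R)$ with $I$ the tissue C incorporation rate and $R$
the respiration rate, is likewise restricted to single-species chambers;
losses that are not measured (DOC release, cell shedding) are ignored, so it
is an efficiency relative to *measured* processing only.

The fraction of added food accounted for is
$(\mathrm{tissue} + \mathrm{respiration} + \mathrm{calcification}) /
\mathrm{added}$. On the bundled worked-example budget this recomputes to
about 3–4 % for the bacterial food and 4–8 % for the algal food. Prose
summaries of such experiments sometimes quote accounted-for percentages that
are inconsistent with their own budget table; `fraction_accounted()` always
recomputes from the table rather than trusting a quoted percentage.

Stoichiometric uptake is the ratio of the *mean* C incorporation rate to the
*mean* N incorporation rate of a food (means across the replicates of the two
complementary treatments, which is the finest resolution the crossed label
design permits). Both rates are normalized per mmol of their own element, so
the ratio expresses uptake C:N relative to tissue C:N; the food and tissue
C:N ratios are attached to each record for that comparison. Only broad-scale
preferences are interpretable at this resolution.

## The factorial ANOVAs

Rates are log~10~-transformed before testing (they are positive,
right-skewed, and effects act multiplicatively — the sponge's rates are
roughly an order of magnitude above the coral's). `factorial_anova()` is a
fixed-effects least-squares ANOVA via `stats::lm`, with sequential (Type I)
sums of squares: on the balanced designs these experiments use, Type I, II
and III coincide, and on unbalanced data the behavior is predictable from the
stated term order. Non-positive responses are excluded with a warning; an
empty design cell is an error naming the missing combination.

`tracer_analysis()` fits the standard model set: species + food on
single-species incorporation (separately per element; residual df 9 at the
2 × 2 × 3 design), the same for respiration and NGE, and per species a
presence-of-the-other-taxon × food × element model with the presence:food
interaction (residual df 19), plus presence × food with interaction for
calcification. Which interactions enter is exposed as the `interactions`
argument because fuller models are defensible; the defaults reproduce the
residual degrees of freedom conventional for this design.

## The synthetic generator and what validation shows

`simulate_experiment()` forward-simulates the entire measurement chain in
reverse: a true rate becomes a tracer amount, an excess fraction on the
measured pool, and finally a sample delta on top of a natural-abundance
background, with additive Gaussian noise on the delta scale (IRMS-like;
default sd 0.2 ‰). Biomasses are truncated-at-zero Gaussian draws
(coral tissue 10,128 ± 3,459 µmol C, sponge 451 ± 146 µmol C, coral skeleton
100,000 ± 20,000 µmol C), tissue N follows from fixed tissue C:N (coral 5.5,
sponge 4.5), and DIC end-point deltas accumulate the summed true respiration
of all specimens present, so mixed chambers produce a consortium signal by
construction. Default true rates sit in the middle of the ranges reported
for cold-water corals and their associated sponges (e.g. coral C
incorporation 0.12–0.15, sponge 2.5–4.0 µmol mmol^-1^ d^-1^; calcification a
few nmol mmol^-1^ d^-1^); backgrounds default to δ^13^C = −20 ‰ and
δ^15^N = +8 ‰ for tissue, 0 ‰ for DIC and −1 ‰ for the
carbonate-dominated whole sample. The whole-sample background is a single
configured value rather than a per-specimen tissue/skeleton mixture: this
keeps the zero-noise chain exactly invertible, at the cost of not emulating
between-specimen background variation in the skeleton.

The realized label enrichment of each food is a required parameter
(placeholder default 0.25): culturing protocols state medium substitution
levels, not the enrichment the organisms actually attain, so real analyses
must measure it. All rates scale as 1/enrichment, so an enrichment error
propagates proportionally into every rate.

Validation by parameter recovery:

* at zero noise, every true rate (C and N incorporation, respiration,
  calcification, including mixed-chamber consortium respiration) is
  recovered to better than $10^{-9}$ relative error;
* at the realistic noise level, recovered means are unbiased. Because the
  control mean is shared within an experiment, its error does not shrink
  with chamber replication — the recovery check therefore pools mean
  recovery ratios across 12 independently simulated experiments (each at the
  3-replicate design) and requires, per rate kind, the grand mean within 3
  standard errors of 1. For the same reason the large-replication bias check
  grows the control pool together with the chamber count. This is a real
  feature of shared-control designs, not an artifact: with 3 control
  specimens, calcification estimates of a single experiment carry a common
  ~15 % uncertainty from the control draw alone.
* ANOVA calibration: on a null simulation of the single-species design
  (1,000 replicates), the per-term type-I error at α = 0.05 stays within
  0.05 ± 0.02, and a 10-fold species effect (1 unit on the log~10~ scale,
  residual sd 0.15 log units — the regime these experiments report, with
  species F-statistics near 100) is detected at p < 0.001 in over 99 % of
  replicates.

What passing these checks does *not* show about real data: the generator
draws independent Gaussian noise on the delta scale only. Instrument drift,
pool-size measurement error, within-chamber heterogeneity, label recycling
through DOC or cell shedding, and feeding-period kinetics (daily pulses and
flushing) are not simulated; rates are treated as constant over the feeding
period exactly as the budget assumes. Recovery under the generator therefore
validates the arithmetic and plumbing, not the biology of those assumptions.

Problem sizes used throughout the suite — a 2 × 3 × 3 design (36 chambers)
per simulated experiment, 12 experiments for the noisy-recovery check, and
1,000 replicates per ANOVA simulation — were chosen to estimate each checked
quantity to well under its test tolerance.

## Known limitations

* Respiration in mixed chambers is reported only at the consortium level;
  no source-partitioning or mixing-model inference is attempted.
* No isotope-fractionation corrections are applied anywhere in the chain;
  at tracer-level enrichments these are negligible relative to the signal.
* Sponge calcification is fixed at zero in budgets (the field is kept for
  schema uniformity).
* The unaccounted budget term conflates food never captured with true losses
  (DOC, shed cells); the package deliberately does not model its fate.
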