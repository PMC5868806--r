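# Net growth efficiency, the closed-chamber carbon budget, and stoichiometric
# (C:N) uptake.

#' Net growth efficiency
#'
#' `NGE = tissue incorporation / (tissue incorporation + respiration)`, both
#' rates biomass-normalized to the same tissue C pool, so only single-species
#' chambers qualify (respiration of a mixed chamber cannot be attributed to
#' one taxon). Losses other than respiration (mucus/DOC release, cell
#' shedding) are not measured and therefore ignored, so NGE is an upper-bound
#' style efficiency.
#'
#' @param tissue_rate C incorporation rate, umol C mmol^-1 d^-1.
#' @param respiration_rate Respiration rate, same units.
#' @return NGE in [0, 1] for non-negative inputs; `NA` where both rates are
#'   zero (undefined). Invariant to a common rescaling of both rates.
#' @examples
#' net_growth_efficiency(1, 9)  # 0.10
#' @export
net_growth_efficiency <- function(tissue_rate, respiration_rate) {
  total <- tissue_rate + respiration_rate
  ifelse(total == 0, NA_real_, tissue_rate / total)
}

#' Assemble one carbon-budget row from tracer amounts
#'
#' The closure term is defined exactly: `unaccounted = added - (tissue +
#' respiration + calcification)`. Negative components (possible from
#' measurement noise) are flagged via the `negative_component` column, never
#' dropped or clamped.
#'
#' @param tissue,respiration,calcification Tracer C over the experiment, umol.
#' @param added Food C added per chamber over the experiment, umol.
#' @param taxon,food Optional labels.
#' @return A one-row `data.frame` with the components, `unaccounted`, and a
#'   `negative_component` flag.
#' @export
budget_row <- function(tissue, respiration, calcification, added,
                       taxon = NA_character_, food = NA_character_) {
  stopifnot(is.finite(tissue), is.finite(respiration),
            is.finite(calcification), is.finite(added), added >= 0)
  data.frame(taxon = taxon, food = food, tissue = tissue,
             respiration = respiration, calcification = calcification,
             added = added,
             unaccounted = added - (tissue + respiration + calcification),
             negative_component = tissue < 0 | respiration < 0 |
               calcification < 0,
             stringsAsFactors = FALSE)
}

#' Carbon budget of one specimen over the feeding period
#'
#' Scales biomass-normalized rates back to whole-experiment tracer amounts
#' under the assumption that the rates were constant over the feeding period:
#' `tissue = tissue_rate x biomass x days`, respiration analogously on the
#' tissue pool, calcification on the skeleton pool; then closes the budget
#' against the added food via [budget_row()].
#'
#' @param tissue_rate,respiration_rate C incorporation and respiration rates,
#'   umol C mmol^-1 d^-1 (single-species chambers).
#' @param calcification_rate Calcification rate, umol C mmol^-1 skeleton C
#'   d^-1; 0 for non-calcifiers.
#' @param biomass_mmol Tissue C pool, mmol.
#' @param skeleton_mmol Skeleton C pool, mmol (0 allowed when
#'   `calcification_rate` is 0).
#' @param feeding_days Feeding-period duration, days (default 10).
#' @param added_c Food C added per chamber, umol.
#' @param taxon,food Optional labels.
#' @return A one-row budget `data.frame`; see [budget_row()].
#' @examples
#' carbon_budget(0.146, 2.53, 0.0023, biomass_mmol = 10.128,
#'               skeleton_mmol = 100, added_c = 8125)
#' @export
carbon_budget <- function(tissue_rate, respiration_rate, calcification_rate,
                          biomass_mmol, skeleton_mmol, feeding_days = 10,
                          added_c, taxon = NA_character_,
                          food = NA_character_) {
  stopifnot(is.finite(biomass_mmol), biomass_mmol > 0,
            is.finite(feeding_days), feeding_days > 0,
            is.finite(skeleton_mmol), skeleton_mmol >= 0)
  if (calcification_rate != 0 && skeleton_mmol <= 0)
    stop("a nonzero calcification rate needs a positive skeleton pool",
         call. = FALSE)
  budget_row(tissue = tissue_rate * biomass_mmol * feeding_days,
             respiration = respiration_rate * biomass_mmol * feeding_days,
             calcification = calcification_rate * skeleton_mmol * feeding_days,
             added = added_c, taxon = taxon, food = food)
}

#' Total carbon processed
#'
#' Sum of tissue incorporation, respiration and calcification of a budget row
#' (or table): the food carbon that can be traced back in the organism or the
#' DIC pool.
#'
#' @param budget A budget `data.frame` from [budget_row()] / [carbon_budget()].
#' @return Numeric vector, umol C, one value per row.
#' @export
total_processed <- function(budget) {
  stopifnot(all(c("tissue", "respiration", "calcification") %in%
                  names(budget)))
  budget$tissue + budget$respiration + budget$calcification
}

#' Fraction of the added food carbon accounted for
#'
#' @param budget A budget `data.frame` with positive `added`.
#' @return `total_processed(budget) / added`, one value per row.
#' @export
fraction_accounted <- function(budget) {
  stopifnot(all(budget$added > 0))
  total_processed(budget) / budget$added
}

#' Stoichiometric (C:N) uptake of a food source
#'
#' Because the C and the N label of one food are fed in complementary
#' treatments (and thus measured on different specimens), the uptake
#' stoichiometry can only be formed from rate means: `uptake_cn = mean C
#' incorporation rate / mean N incorporation rate`. Both rates being
#' normalized to the tissue pool of their own element, this ratio expresses
#' uptake C:N relative to the tissue's C:N; the food and tissue C:N are
#' attached for the comparison. Only broad-scale differences are
#' interpretable at this resolution.
#'
#' @param c_rate_mean Mean C incorporation rate, umol C mmol C^-1 d^-1.
#' @param n_rate_mean Mean N incorporation rate, umol N mmol N^-1 d^-1.
#' @param food_cn,tissue_cn Molar C:N of the food source and of the
#'   consumer's tissue, attached for reference.
#' @param taxon,food,composition Optional labels.
#' @return A one-row `data.frame` with `uptake_cn` (`NA` when the N rate is
#'   not positive), `food_cn` and `tissue_cn`.
#' @export
stoichiometric_uptake <- function(c_rate_mean, n_rate_mean, food_cn = NA_real_,
                                  tissue_cn = NA_real_, taxon = NA_character_,
                                  food = NA_character_,
                                  composition = NA_character_) {
  uptake_cn <- if (!is.finite(n_rate_mean) || n_rate_mean <= 0) NA_real_
  else c_rate_mean / n_rate_mean
  data.frame(taxon = taxon, food = food, composition = composition,
             c_rate_mean = c_rate_mean, n_rate_mean = n_rate_mean,
             uptake_cn = uptake_cn, food_cn = food_cn, tissue_cn = tissue_cn,
             stringsAsFactors = FALSE)
}
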