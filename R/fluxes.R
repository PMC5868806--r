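# Tracer amounts and biomass-normalized fluxes.
#
# Unit conventions (kept throughout internal computation):
#   pools/amounts  umol of the element
#   biomass        mmol of the element
#   rates          umol tracer mmol^-1 d^-1
# Calcification is rescaled to nmol mmol^-1 d^-1 only at the reporting layer.

#' Describe a labeled food source
#'
#' A food source is a diet component enriched in one heavy isotope: its
#' labeled element, the realized atom-fraction enrichment of that element in
#' the food, its molar C:N ratio, and the total amounts added per chamber over
#' the experiment. The enrichment is the divisor that converts excess tracer
#' into food-derived element.
#'
#' @param name Food name, e.g. `"algae"` or `"bacteria"`.
#' @param labeled_element `"C"` or `"N"`.
#' @param enrichment Atom fraction (0, 1] of the heavy isotope of the labeled
#'   element in the food. Must be supplied from culture measurements; there is
#'   no universal default beyond the placeholder 0.25.
#' @param cn_ratio Molar C:N ratio of the food, > 0.
#' @param added_c Total umol C added per chamber over the experiment, >= 0.
#' @param added_n Total umol N added per chamber; defaults to
#'   `added_c / cn_ratio`.
#' @param treatment Optional treatment label this food belongs to.
#' @return A one-row `data.frame` with the food-source fields.
#' @examples
#' food_source("algae", "C", enrichment = 0.25, cn_ratio = 6.6, added_c = 2708)
#' @export
food_source <- function(name, labeled_element = c("C", "N"), enrichment,
                        cn_ratio, added_c, added_n = added_c / cn_ratio,
                        treatment = NA_character_) {
  labeled_element <- match.arg(labeled_element)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(enrichment) || enrichment <= 0 || enrichment > 1)
    stop("food enrichment must lie in (0, 1], got ", enrichment, call. = FALSE)
  if (!is.finite(cn_ratio) || cn_ratio <= 0)
    stop("food cn_ratio must be > 0", call. = FALSE)
  if (!is.finite(added_c) || added_c < 0)
    stop("added_c must be >= 0", call. = FALSE)
  data.frame(name = name, treatment = treatment,
             labeled_element = labeled_element, enrichment = enrichment,
             cn_ratio = cn_ratio, added_c = added_c, added_n = added_n,
             stringsAsFactors = FALSE)
}

#' Food-derived tracer amount in a pool
#'
#' Converts an excess atomic fraction measured on an element pool into the
#' amount of food-derived element, by scaling with the pool size and dividing
#' by the food's label enrichment: `excess * pool_umol / enrichment`.
#'
#' @param excess Excess atomic fraction (signed; see [excess_fraction()]).
#' @param pool_umol Size of the measured element pool, umol, > 0.
#' @param enrichment Atom-fraction enrichment of the labeled element in the
#'   food source, in (0, 1].
#' @return Food-derived element, umol. Linear in both `excess` and
#'   `pool_umol`; halving the enrichment doubles the inferred uptake.
#' @examples
#' tracer_uptake(0.001, pool_umol = 10000, enrichment = 0.5)  # 20 umol
#' @export
tracer_uptake <- function(excess, pool_umol, enrichment) {
  if (any(!is.finite(pool_umol)) || any(pool_umol <= 0))
    stop("pool size must be > 0 umol", call. = FALSE)
  if (any(!is.finite(enrichment)) || any(enrichment <= 0) || any(enrichment > 1))
    stop("cannot divide by food enrichment outside (0, 1]: the realized ",
         "atom-fraction enrichment of the food must be positive", call. = FALSE)
  excess * pool_umol / enrichment
}

#' Biomass-normalized daily tracer flux
#'
#' `uptake / biomass / duration`, giving umol tracer per mmol biomass of the
#' same element per day.
#'
#' @param uptake_umol Tracer amount, umol.
#' @param biomass_mmol Organic biomass pool of the normalizing element, mmol,
#'   > 0.
#' @param duration_d Duration over which the uptake accumulated, days, > 0.
#' @return Rate in umol tracer mmol^-1 d^-1.
#' @examples
#' biomass_normalized_rate(14.8, biomass_mmol = 10.128, duration_d = 10)
#' @export
biomass_normalized_rate <- function(uptake_umol, biomass_mmol, duration_d) {
  if (any(!is.finite(biomass_mmol)) || any(biomass_mmol <= 0))
    stop("biomass must be > 0 mmol", call. = FALSE)
  if (any(!is.finite(duration_d)) || any(duration_d <= 0))
    stop("duration must be > 0 days", call. = FALSE)
  uptake_umol / biomass_mmol / duration_d
}

#' Respiration rate from DIC isotope enrichment
#'
#' Respiration of labeled food is inferred from the 13C enrichment of the
#' dissolved inorganic carbon (DIC) pool over a closed incubation:
#' `((f_end - f_start) * dic_umol_per_l * volume_l / enrichment / duration_d)
#' / chamber_biomass_mmol`. The normalizing biomass is the total organic C of
#' all specimens in the chamber (coral + sponge tissue when both are present).
#'
#' @param f_end,f_start Atomic fraction of 13C in DIC after/before the closed
#'   incubation.
#' @param dic_umol_per_l DIC concentration, umol L^-1, > 0.
#' @param volume_l Chamber volume, L, > 0.
#' @param enrichment Atom-fraction enrichment of the 13C-labeled food.
#' @param duration_d Closed-incubation duration, days (48 h = 2 d), > 0.
#' @param chamber_biomass_mmol Summed organic C of all specimens present,
#'   mmol, > 0.
#' @return Respiration rate, umol C tracer mmol^-1 d^-1.
#' @examples
#' respiration_rate(f_end = 0.0116, f_start = 0.0111, dic_umol_per_l = 2000,
#'                  volume_l = 10, enrichment = 0.25, duration_d = 2,
#'                  chamber_biomass_mmol = 10)
#' @export
respiration_rate <- function(f_end, f_start, dic_umol_per_l, volume_l,
                             enrichment, duration_d, chamber_biomass_mmol) {
  if (any(!is.finite(dic_umol_per_l)) || any(dic_umol_per_l <= 0))
    stop("DIC concentration must be > 0 umol L^-1", call. = FALSE)
  if (any(!is.finite(volume_l)) || any(volume_l <= 0))
    stop("chamber volume must be > 0 L", call. = FALSE)
  excess <- f_end - f_start
  amount <- tracer_uptake(excess, pool_umol = dic_umol_per_l * volume_l,
                          enrichment = enrichment)
  biomass_normalized_rate(amount, chamber_biomass_mmol, duration_d)
}

#' Skeleton (calcification) tracer amount by subtraction
#'
#' Metabolic-derived carbonate incorporation is the 13C tracer in the whole
#' sample (organic fraction plus inorganic skeleton) minus the tracer in the
#' organic fraction alone. Measurement noise can make the difference slightly
#' negative; the value is returned signed and flagged downstream rather than
#' clamped.
#'
#' @param total_umol Tracer C in the whole (organic + skeleton) sample, umol.
#' @param organic_umol Tracer C in the organic fraction, umol.
#' @return Tracer C incorporated into the skeleton, umol (signed).
#' @examples
#' calcification_uptake(12.0, 9.4)
#' @export
calcification_uptake <- function(total_umol, organic_umol) {
  if (any(!is.finite(total_umol)) || any(!is.finite(organic_umol)))
    stop("tracer amounts must be finite", call. = FALSE)
  total_umol - organic_umol
}
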