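# From measurement tables to biomass-normalized tracer rates.

.chamber_key <- function(df) paste(df$treatment, df$composition, df$replicate,
                                   sep = "||")

# the food of `treatment` labeled in `element`
.food_for <- function(foods, treatment, element) {
  hit <- foods$treatment == treatment & foods$labeled_element == element
  if (sum(hit) != 1L)
    stop("expected exactly one food source labeled in ", element,
         " for treatment '", treatment, "', found ", sum(hit), call. = FALSE)
  foods[hit, , drop = FALSE]
}

#' Compute all biomass-normalized tracer rates of an experiment
#'
#' Runs the full conversion chain for every measurement: delta to isotope
#' ratio to atomic fraction, excess above the paired control, food-derived
#' tracer amount (division by the food's label enrichment), and
#' normalization to the organic biomass of the same element and to time.
#'
#' Three rate kinds are produced:
#' \describe{
#'   \item{incorporation}{per `"tissue"` measurement row; the food source is
#'     the one of that treatment labeled in the row's element; duration is the
#'     chamber's `feeding_days`.}
#'   \item{calcification}{per `"total"` (organic + skeleton) C row, paired
#'     with the same specimen's tissue C row: the skeleton tracer is the whole
#'     sample tracer minus the organic tracer, normalized to the skeleton C
#'     pool (the difference of the two pool sizes). Internal units stay
#'     umol mmol^-1 d^-1; see [write_results()] for the nmol reporting scale.}
#'   \item{respiration}{per chamber, from the DIC delta-13C before/after the
#'     closed incubation, normalized to the summed tissue C of all specimens
#'     present and to `respiration_days`. In mixed chambers the rate belongs
#'     to the consortium, not to either taxon.}
#' }
#'
#' Negative rates (sample below control, within noise) are preserved signed
#' and marked in the `negative` column, never clamped.
#'
#' @param measurements,chambers,foods Data frames in the package's CSV
#'   schemas (see [read_measurements()], [read_chambers()], [read_foods()]).
#' @return A `data.frame` with columns `treatment`, `composition`,
#'   `replicate`, `taxon`, `food`, `element`, `kind`, `value`
#'   (umol tracer mmol^-1 d^-1), `uptake_umol` (tracer amount over the
#'   measured duration), `biomass_mmol`, and `negative`.
#' @export
tracer_rates <- function(measurements, chambers, foods) {
  measurements <- .validate_table(measurements, "measurements")
  chambers <- .validate_table(chambers, "chambers")
  foods <- .validate_table(foods, "foods")

  m <- measurements
  ch <- chambers
  m$.chamber <- .chamber_key(m)
  ch$.chamber <- .chamber_key(ch)
  if (anyDuplicated(ch$.chamber))
    stop("duplicated chamber rows (same treatment, composition, replicate)",
         call. = FALSE)
  orphan <- !m$.chamber %in% ch$.chamber
  if (any(orphan))
    stop("measurements row ", which(orphan)[1L],
         ": no matching chamber (treatment='", m$treatment[orphan][1L],
         "', composition='", m$composition[orphan][1L], "', replicate='",
         m$replicate[orphan][1L], "')", call. = FALSE)
  feed_days <- ch$feeding_days[match(m$.chamber, ch$.chamber)]

  rec <- function(row, taxon, food, element, kind, value, uptake, biomass)
    data.frame(treatment = row$treatment, composition = row$composition,
               replicate = row$replicate, taxon = taxon, food = food,
               element = element, kind = kind, value = value,
               uptake_umol = uptake, biomass_mmol = biomass,
               negative = value < 0, stringsAsFactors = FALSE)
  out <- list()

  ## tissue incorporation
  tis <- which(m$pool == "tissue")
  for (i in tis) {
    row <- m[i, ]
    food <- .food_for(foods, row$treatment, row$element)
    e <- excess_fraction(delta_to_fraction(row$delta_sample, row$element),
                         delta_to_fraction(row$delta_control, row$element))
    uptake <- tracer_uptake(e, row$pool_umol, food$enrichment)
    biomass <- row$pool_umol / 1000
    days <- feed_days[i]
    out[[length(out) + 1L]] <-
      rec(row, row$taxon, food$name, row$element, "incorporation",
          biomass_normalized_rate(uptake, biomass, days), uptake, biomass)
  }

  ## calcification: whole-sample minus organic tracer, on the skeleton pool
  tot <- which(m$pool == "total")
  for (i in tot) {
    row <- m[i, ]
    if (row$element != "C")
      stop("measurements row ", i,
           ": 'total' pool measurements must be element C", call. = FALSE)
    j <- which(m$pool == "tissue" & m$element == "C" &
                 m$.chamber == row$.chamber & m$taxon == row$taxon)
    if (length(j) != 1L)
      stop("measurements row ", i, ": need exactly one matching tissue C row ",
           "for taxon '", row$taxon, "' in the same chamber to compute ",
           "calcification, found ", length(j), call. = FALSE)
    org <- m[j, ]
    skeleton_umol <- row$pool_umol - org$pool_umol
    if (skeleton_umol <= 0)
      stop("measurements row ", i, ": whole-sample C pool must exceed the ",
           "tissue C pool (skeleton pool must be positive)", call. = FALSE)
    food <- .food_for(foods, row$treatment, "C")
    e_tot <- excess_fraction(delta_to_fraction(row$delta_sample, "C"),
                             delta_to_fraction(row$delta_control, "C"))
    e_org <- excess_fraction(delta_to_fraction(org$delta_sample, "C"),
                             delta_to_fraction(org$delta_control, "C"))
    uptake <- calcification_uptake(
      tracer_uptake(e_tot, row$pool_umol, food$enrichment),
      tracer_uptake(e_org, org$pool_umol, food$enrichment))
    biomass <- skeleton_umol / 1000
    out[[length(out) + 1L]] <-
      rec(row, row$taxon, food$name, "C", "calcification",
          biomass_normalized_rate(uptake, biomass, feed_days[i]),
          uptake, biomass)
  }

  ## respiration: DIC enrichment per chamber
  for (i in seq_len(nrow(ch))) {
    row <- ch[i, ]
    food <- .food_for(foods, row$treatment, "C")
    in_ch <- m$.chamber == row$.chamber & m$pool == "tissue" & m$element == "C"
    if (!any(in_ch))
      stop("chamber '", row$.chamber, "': no tissue C measurements; cannot ",
           "normalize respiration", call. = FALSE)
    biomass <- sum(m$pool_umol[in_ch]) / 1000
    value <- respiration_rate(
      f_end = delta_to_fraction(row$delta_dic_end, "C"),
      f_start = delta_to_fraction(row$delta_dic_start, "C"),
      dic_umol_per_l = row$dic_umol_per_l, volume_l = row$volume_l,
      enrichment = food$enrichment, duration_d = row$respiration_days,
      chamber_biomass_mmol = biomass)
    uptake <- value * biomass * row$respiration_days
    out[[length(out) + 1L]] <-
      rec(row, row$composition, food$name, "C", "respiration",
          value, uptake, biomass)
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
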