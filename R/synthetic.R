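# Forward simulation of a dual-tracer feeding experiment with known truth.
#
# The generator runs the analysis chain in reverse: true rate -> tracer
# amount -> excess atomic fraction -> sample delta (= background + excess,
# plus Gaussian measurement noise on the delta scale). At zero noise the
# analysis pipeline inverts it exactly.

.TREATMENTS <- c("13C-Alg+15N-Bac", "15N-Alg+13C-Bac")
.COMPOSITIONS <- c("coral", "sponge", "coral+sponge")

#' Ground-truth configuration for a synthetic feeding experiment
#'
#' Defines the true per-taxon, per-food rates and the experimental conditions
#' the generator emulates: a 2-treatment (each food labeled in C in one
#' treatment and in N in the other) x 3-composition (coral only, sponge only,
#' coral + sponge) design with 3 replicate 10-L chambers per cell, a 10-day
#' feeding period, and a 48-h (2-day) closed incubation for respiration.
#'
#' Defaults emulate a cold-water coral / encrusting sponge experiment:
#' coral tissue 10,128 +/- 3,459 umol C, sponge tissue 451 +/- 146 umol C
#' (truncated-at-zero Gaussian draws), food pulses of 2,708 umol algal C and
#' 8,125 umol bacterial C per chamber, and true rates in the middle of the
#' range such organisms show (corals: C incorporation ~0.1, respiration ~1-2
#' umol mmol^-1 d^-1, calcification a few nmol mmol^-1 d^-1; sponges roughly
#' an order of magnitude higher). Natural-abundance backgrounds default to
#' delta13C = -20 permil and delta15N = +8 permil for tissue (typical marine
#' invertebrate values), 0 permil for DIC and -1 permil for the
#' carbonate-dominated whole sample; measurement noise is additive Gaussian
#' on the delta scale with sd 0.2 permil (IRMS-like). All are configurable.
#'
#' Rate vectors are named `taxon.food` (e.g. `coral.algae`) in
#' umol tracer mmol^-1 d^-1 (calcification included: 0.004 = 4 nmol).
#'
#' @param replicates Chambers per design cell.
#' @param feeding_days,respiration_days,volume_l,dic_umol_per_l Experimental
#'   constants: feeding period (d), closed-incubation duration (d), chamber
#'   volume (L), DIC concentration (umol L^-1).
#' @param enrichment Named atom-fraction label enrichments of the foods.
#' @param food_cn,added_c Named molar C:N ratios and added C (umol chamber^-1)
#'   of the foods.
#' @param coral_tissue_c,sponge_tissue_c,coral_skeleton_c Named `c(mean=, sd=)`
#'   biomass distributions, umol C.
#' @param coral_tissue_cn,sponge_tissue_cn Molar tissue C:N ratios (set the
#'   tissue N pool from the drawn tissue C pool).
#' @param incorporation_c,incorporation_n,respiration,calcification True
#'   rates, named `taxon.food`; all must be >= 0.
#' @param background_delta Named natural-abundance deltas (permil):
#'   `tissue_c`, `tissue_n`, `whole_c` (organic + skeleton sample),
#'   `dic_c`.
#' @param noise_sd_permil Gaussian measurement noise sd on the delta scale.
#' @param control_replicates Unfed control specimens per taxon whose mean
#'   delta is the paired control value.
#' @param seed Optional integer; makes [simulate_experiment()] fully
#'   reproducible.
#' @return A `truth_config` list.
#' @export
truth_config <- function(replicates = 3,
                         feeding_days = 10,
                         respiration_days = 2,
                         volume_l = 10,
                         dic_umol_per_l = 2000,
                         enrichment = c(algae = 0.25, bacteria = 0.25),
                         food_cn = c(algae = 6.6, bacteria = 4.5),
                         added_c = c(algae = 2708, bacteria = 8125),
                         coral_tissue_c = c(mean = 10128, sd = 3459),
                         sponge_tissue_c = c(mean = 451, sd = 146),
                         coral_tissue_cn = 5.5,
                         sponge_tissue_cn = 4.5,
                         coral_skeleton_c = c(mean = 1e5, sd = 2e4),
                         incorporation_c = c(coral.algae = 0.12,
                                             coral.bacteria = 0.15,
                                             sponge.algae = 2.5,
                                             sponge.bacteria = 4.0),
                         incorporation_n = c(coral.algae = 0.08,
                                             coral.bacteria = 0.10,
                                             sponge.algae = 1.0,
                                             sponge.bacteria = 2.5),
                         respiration = c(coral.algae = 1.0,
                                         coral.bacteria = 1.8,
                                         sponge.algae = 55,
                                         sponge.bacteria = 65),
                         calcification = c(coral.algae = 0.004,
                                           coral.bacteria = 0.006),
                         background_delta = c(tissue_c = -20, tissue_n = 8,
                                              whole_c = -1, dic_c = 0),
                         noise_sd_permil = 0.2,
                         control_replicates = 3,
                         seed = NULL) {
  cfg <- list(replicates = replicates, feeding_days = feeding_days,
              respiration_days = respiration_days, volume_l = volume_l,
              dic_umol_per_l = dic_umol_per_l, enrichment = enrichment,
              food_cn = food_cn, added_c = added_c,
              coral_tissue_c = coral_tissue_c,
              sponge_tissue_c = sponge_tissue_c,
              coral_tissue_cn = coral_tissue_cn,
              sponge_tissue_cn = sponge_tissue_cn,
              coral_skeleton_c = coral_skeleton_c,
              incorporation_c = incorporation_c,
              incorporation_n = incorporation_n,
              respiration = respiration, calcification = calcification,
              background_delta = background_delta,
              noise_sd_permil = noise_sd_permil,
              control_replicates = control_replicates, seed = seed)
  rates <- c(incorporation_c, incorporation_n, respiration, calcification)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all true rates must be finite and >= 0", call. = FALSE)
  if (any(enrichment <= 0) || any(enrichment > 1))
    stop("food enrichments must lie in (0, 1]", call. = FALSE)
  if (!is.finite(noise_sd_permil) || noise_sd_permil < 0)
    stop("noise_sd_permil must be >= 0", call. = FALSE)
  stopifnot(replicates >= 1, control_replicates >= 1)
  class(cfg) <- "truth_config"
  cfg
}

# positive truncated-normal draw
.rtruncpos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    k <- x <= 0
    x[k] <- stats::rnorm(sum(k), mean, sd)
  }
  x
}

.rate_of <- function(rates, taxon, food) {
  key <- paste(taxon, food, sep = ".")
  if (key %in% names(rates)) unname(rates[key]) else 0
}

# measured delta = fraction_to_delta(background F + excess) + noise;
# errors out when the label saturates the pool (F >= 1)
.label_delta <- function(bg_delta, excess, element, noise_sd) {
  f <- delta_to_fraction(bg_delta, element) + excess
  if (any(f >= 1))
    stop("label saturation: configured rates imply an atomic fraction >= 1",
         call. = FALSE)
  fraction_to_delta(f, element) + stats::rnorm(length(f), 0, noise_sd)
}

#' Simulate a complete dual-tracer feeding experiment
#'
#' Forward-simulates every measurement of the design described in
#' [truth_config()]: specimen biomasses are drawn, true rates are converted
#' to tracer amounts over the feeding period, to excess atomic fractions on
#' the measured pools, and to sample deltas on top of natural-abundance
#' backgrounds, with Gaussian noise on the delta scale. Paired control deltas
#' are the means of simulated unfed control specimens. DIC end-point deltas
#' accumulate the summed true respiration of all specimens in the chamber, so
#' mixed-chamber respiration is a consortium signal by construction.
#'
#' @param cfg A [truth_config()].
#' @return A `tracer_simulation` list with elements `measurements`,
#'   `chambers`, `foods` (the schemas [tracer_rates()] consumes) and `truth`,
#'   one row per recoverable true rate (`treatment`, `composition`,
#'   `replicate`, `taxon`, `kind`, `element`, `food`, `true_value` in
#'   umol mmol^-1 d^-1), plus the `config`.
#' @examples
#' sim <- simulate_experiment(truth_config(seed = 1, noise_sd_permil = 0))
#' rates <- tracer_rates(sim$measurements, sim$chambers, sim$foods)
#' @export
simulate_experiment <- function(cfg = truth_config()) {
  stopifnot(inherits(cfg, "truth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  bg <- cfg$background_delta
  noise <- cfg$noise_sd_permil

  ## foods: each diet component is C-labeled in one treatment, N in the other
  foods <- rbind(
    food_source("algae", "C", cfg$enrichment[["algae"]],
                cfg$food_cn[["algae"]], cfg$added_c[["algae"]],
                treatment = .TREATMENTS[1]),
    food_source("bacteria", "N", cfg$enrichment[["bacteria"]],
                cfg$food_cn[["bacteria"]], cfg$added_c[["bacteria"]],
                treatment = .TREATMENTS[1]),
    food_source("algae", "N", cfg$enrichment[["algae"]],
                cfg$food_cn[["algae"]], cfg$added_c[["algae"]],
                treatment = .TREATMENTS[2]),
    food_source("bacteria", "C", cfg$enrichment[["bacteria"]],
                cfg$food_cn[["bacteria"]], cfg$added_c[["bacteria"]],
                treatment = .TREATMENTS[2]))

  ## paired controls: mean delta of simulated unfed specimens, per taxon x pool
  ctrl <- function(bg_delta)
    mean(bg_delta + stats::rnorm(cfg$control_replicates, 0, noise))
  controls <- list()
  for (tx in c("coral", "sponge"))
    controls[[tx]] <- list(tissue_c = ctrl(bg[["tissue_c"]]),
                           tissue_n = ctrl(bg[["tissue_n"]]),
                           whole_c = ctrl(bg[["whole_c"]]))

  meas <- list()
  chams <- list()
  truth <- list()
  add_meas <- function(trt, comp, rep, taxon, pool, element, ds, dc, pool_umol)
    meas[[length(meas) + 1L]] <<-
      data.frame(treatment = trt, composition = comp, replicate = rep,
                 taxon = taxon, pool = pool, element = element,
                 delta_sample = ds, delta_control = dc, pool_umol = pool_umol,
                 stringsAsFactors = FALSE)
  add_truth <- function(trt, comp, rep, taxon, kind, element, food, value)
    truth[[length(truth) + 1L]] <<-
      data.frame(treatment = trt, composition = comp, replicate = rep,
                 taxon = taxon, kind = kind, element = element, food = food,
                 true_value = value, stringsAsFactors = FALSE)

  for (comp in .COMPOSITIONS) {
    taxa <- strsplit(comp, "+", fixed = TRUE)[[1]]
    for (trt in .TREATMENTS) {
      food_c <- foods$name[foods$treatment == trt & foods$labeled_element == "C"]
      food_n <- foods$name[foods$treatment == trt & foods$labeled_element == "N"]
      enr_c <- cfg$enrichment[[food_c]]
      enr_n <- cfg$enrichment[[food_n]]
      for (rep in seq_len(cfg$replicates)) {
        resp_total_umol <- 0
        chamber_tissue_mmol <- 0
        for (tx in taxa) {
          tc_par <- if (tx == "coral") cfg$coral_tissue_c else cfg$sponge_tissue_c
          tissue_c <- .rtruncpos(1, tc_par[["mean"]], tc_par[["sd"]])
          cn <- if (tx == "coral") cfg$coral_tissue_cn else cfg$sponge_tissue_cn
          tissue_n <- tissue_c / cn
          tissue_c_mmol <- tissue_c / 1000

          ## tissue C incorporation (traces the C-labeled food)
          r_c <- .rate_of(cfg$incorporation_c, tx, food_c)
          upt_c <- r_c * tissue_c_mmol * cfg$feeding_days
          e_c <- upt_c * enr_c / tissue_c
          add_meas(trt, comp, rep, tx, "tissue", "C",
                   .label_delta(bg[["tissue_c"]], e_c, "C", noise),
                   controls[[tx]]$tissue_c, tissue_c)
          add_truth(trt, comp, rep, tx, "incorporation", "C", food_c, r_c)

          ## tissue N incorporation (traces the N-labeled food)
          r_n <- .rate_of(cfg$incorporation_n, tx, food_n)
          upt_n <- r_n * (tissue_n / 1000) * cfg$feeding_days
          e_n <- upt_n * enr_n / tissue_n
          add_meas(trt, comp, rep, tx, "tissue", "N",
                   .label_delta(bg[["tissue_n"]], e_n, "N", noise),
                   controls[[tx]]$tissue_n, tissue_n)
          add_truth(trt, comp, rep, tx, "incorporation", "N", food_n, r_n)

          ## whole sample (organic + skeleton): coral calcification
          if (tx == "coral") {
            skel_c <- .rtruncpos(1, cfg$coral_skeleton_c[["mean"]],
                                 cfg$coral_skeleton_c[["sd"]])
            r_cal <- .rate_of(cfg$calcification, tx, food_c)
            upt_skel <- r_cal * (skel_c / 1000) * cfg$feeding_days
            total_pool <- tissue_c + skel_c
            e_tot <- (upt_c + upt_skel) * enr_c / total_pool
            add_meas(trt, comp, rep, tx, "total", "C",
                     .label_delta(bg[["whole_c"]], e_tot, "C", noise),
                     controls[[tx]]$whole_c, total_pool)
            add_truth(trt, comp, rep, tx, "calcification", "C", food_c, r_cal)
          }

          r_resp <- .rate_of(cfg$respiration, tx, food_c)
          resp_total_umol <- resp_total_umol +
            r_resp * tissue_c_mmol * cfg$respiration_days
          chamber_tissue_mmol <- chamber_tissue_mmol + tissue_c_mmol
          if (comp == tx)  # single-species chamber: taxon-attributable
            add_truth(trt, comp, rep, tx, "respiration", "C", food_c, r_resp)
        }
        ## DIC enrichment from the summed respiration of the chamber
        e_dic <- resp_total_umol * enr_c /
          (cfg$dic_umol_per_l * cfg$volume_l)
        d_start <- bg[["dic_c"]] + stats::rnorm(1, 0, noise)
        d_end <- .label_delta(bg[["dic_c"]], e_dic, "C", noise)
        chams[[length(chams) + 1L]] <-
          data.frame(treatment = trt, composition = comp, replicate = rep,
                     volume_l = cfg$volume_l,
                     dic_umol_per_l = cfg$dic_umol_per_l,
                     feeding_days = cfg$feeding_days,
                     respiration_days = cfg$respiration_days,
                     delta_dic_start = d_start, delta_dic_end = d_end,
                     stringsAsFactors = FALSE)
        if (comp == "coral+sponge")  # consortium rate is what is recoverable
          add_truth(trt, comp, rep, comp, "respiration", "C", food_c,
                    resp_total_umol / chamber_tissue_mmol /
                      cfg$respiration_days)
      }
    }
  }

  out <- list(measurements = do.call(rbind, meas),
              chambers = do.call(rbind, chams),
              foods = foods,
              truth = do.call(rbind, truth),
              config = cfg)
  rownames(out$measurements) <- rownames(out$truth) <- NULL
  class(out) <- "tracer_simulation"
  out
}

#' @export
print.tracer_simulation <- function(x, ...) {
  cat("Synthetic dual-tracer feeding experiment\n")
  cat("  chambers:     ", nrow(x$chambers), " (",
      length(unique(x$chambers$composition)), " compositions x ",
      length(unique(x$chambers$treatment)), " treatments x ",
      x$config$replicates, " replicates)\n", sep = "")
  cat("  measurements: ", nrow(x$measurements), "\n", sep = "")
  cat("  noise sd:     ", x$config$noise_sd_permil, " permil\n", sep = "")
  invisible(x)
}

#' Join recovered rates to the generator's truth table
#'
#' Convenience for parameter-recovery checks: merges the output of
#' [tracer_rates()] with the `truth` table of a [simulate_experiment()]
#' result on (treatment, composition, replicate, taxon, kind, element) and
#' returns one row per recoverable rate with its true and recovered value.
#'
#' @param rates A [tracer_rates()] result computed from the simulation.
#' @param sim The `tracer_simulation` the rates came from.
#' @return A `data.frame` with `true_value`, `value` and their relative error
#'   `rel_error` (`NA` where the true value is 0).
#' @export
recovery_table <- function(rates, sim) {
  stopifnot(inherits(sim, "tracer_simulation"))
  keys <- c("treatment", "composition", "replicate", "taxon", "kind",
            "element")
  merged <- merge(sim$truth, rates[, c(keys, "value")], by = keys)
  merged$rel_error <- ifelse(merged$true_value == 0, NA_real_,
                             (merged$value - merged$true_value) /
                               merged$true_value)
  merged
}
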