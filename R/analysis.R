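# The main entry point: assemble rates, budget, NGE, stoichiometry and the
# factorial ANOVAs into one classed result.

.agg <- function(x, by, fun) stats::aggregate(x, by = by, FUN = fun)

#' Analyze a dual-tracer feeding experiment
#'
#' Runs the full analysis of a 13C/15N pulse-chase feeding experiment from
#' the three measurement tables: biomass-normalized tracer rates
#' ([tracer_rates()]), per-replicate carbon budgets with exact mass-balance
#' closure and their mean/sd summary, net growth efficiencies, stoichiometric
#' (C:N) uptake ratios, and the standard factorial ANOVAs on
#' log10-transformed rates.
#'
#' Budgets and NGE use single-species chambers only: respiration is measured
#' on the whole chamber and cannot be attributed to one taxon in mixed
#' chambers. Each budget cell (taxon x food) uses the replicates of the
#' treatment in which that food carries the 13C label, extrapolating the
#' measured rates over the whole feeding period.
#'
#' The fitted ANOVA models (when the design supports them):
#' \describe{
#'   \item{incorporation_c, incorporation_n}{single-species chambers,
#'     species + food (residual df 9 in the full 2 x 2 x 3 design).}
#'   \item{respiration, nge}{single-species chambers, species + food.}
#'   \item{presence_coral, presence_sponge}{per species: incorporation rates
#'     vs presence of the other taxon, food, element, plus the
#'     presence:food interaction (residual df 19 at 3 replicates).}
#'   \item{calcification}{coral chambers: presence of the sponge, food, and
#'     their interaction.}
#' }
#' Models whose factors lack two observed levels in the data are skipped.
#'
#' @param measurements,chambers,foods Data frames or CSV paths in the
#'   package's schemas (see [read_measurements()] and friends).
#' @param anova Logical; fit the factorial ANOVAs (default `TRUE`).
#' @return A `tracer_analysis` object: list with `rates`, `budget`,
#'   `budget_summary`, `nge`, `stoichiometry`, `anova`, and the validated
#'   input tables. Has `print`, `summary`, `coef` and `plot` methods.
#' @examples
#' sim <- simulate_experiment(truth_config(seed = 7))
#' fit <- tracer_analysis(sim$measurements, sim$chambers, sim$foods)
#' summary(fit)
#' @export
tracer_analysis <- function(measurements, chambers, foods, anova = TRUE) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(chambers)) chambers <- read_chambers(chambers)
  if (is.character(foods)) foods <- read_foods(foods)
  measurements <- .validate_table(measurements, "measurements")
  chambers <- .validate_table(chambers, "chambers")
  foods <- .validate_table(foods, "foods")

  rates <- tracer_rates(measurements, chambers, foods)
  single <- rates$composition %in% c("coral", "sponge") &
    rates$taxon == rates$composition

  ## --- per-replicate carbon budgets (single-species chambers) -------------
  budget <- list()
  nge <- list()
  ch_key <- .chamber_key(chambers)
  for (i in seq_len(nrow(chambers))) {
    comp <- chambers$composition[i]
    if (!comp %in% c("coral", "sponge")) next
    trt <- chambers$treatment[i]
    rep <- chambers$replicate[i]
    food <- .food_for(foods, trt, "C")
    sel <- rates$treatment == trt & rates$composition == comp &
      rates$replicate == rep
    r_inc <- rates[sel & rates$kind == "incorporation" & rates$element == "C", ]
    r_resp <- rates[sel & rates$kind == "respiration", ]
    r_cal <- rates[sel & rates$kind == "calcification", ]
    if (nrow(r_inc) != 1L || nrow(r_resp) != 1L) next
    budget[[length(budget) + 1L]] <- cbind(
      carbon_budget(tissue_rate = r_inc$value,
                    respiration_rate = r_resp$value,
                    calcification_rate = if (nrow(r_cal)) r_cal$value else 0,
                    biomass_mmol = r_inc$biomass_mmol,
                    skeleton_mmol = if (nrow(r_cal)) r_cal$biomass_mmol else 0,
                    feeding_days = chambers$feeding_days[i],
                    added_c = food$added_c, taxon = comp, food = food$name),
      treatment = trt, replicate = rep)
    nge[[length(nge) + 1L]] <-
      data.frame(taxon = comp, food = food$name, treatment = trt,
                 replicate = rep,
                 value = net_growth_efficiency(r_inc$value, r_resp$value),
                 stringsAsFactors = FALSE)
  }
  budget <- if (length(budget)) do.call(rbind, budget) else
    budget_row(0, 0, 0, 0)[0, ]
  nge <- if (length(nge)) do.call(rbind, nge) else
    data.frame(taxon = character(0), food = character(0),
               treatment = character(0), replicate = character(0),
               value = numeric(0))
  rownames(budget) <- rownames(nge) <- NULL

  budget_summary <- if (nrow(budget)) {
    by <- list(taxon = budget$taxon, food = budget$food)
    comp_cols <- c("tissue", "respiration", "calcification", "unaccounted",
                   "added")
    means <- .agg(budget[comp_cols], by, mean)
    sds <- .agg(budget[comp_cols], by, stats::sd)
    out <- means[c("taxon", "food")]
    for (col in comp_cols[comp_cols != "added"]) {
      out[[paste0(col, "_mean")]] <- means[[col]]
      out[[paste0(col, "_sd")]] <- sds[[col]]
    }
    out$added <- means$added
    out$n <- .agg(budget$tissue, by, length)$x
    out
  } else NULL

  ## --- stoichiometric uptake per taxon x food x composition ---------------
  inc <- rates[rates$kind == "incorporation", ]
  stoich <- list()
  if (nrow(inc)) {
    cells <- unique(inc[c("taxon", "food", "composition")])
    tiss <- measurements[measurements$pool == "tissue", ]
    for (k in seq_len(nrow(cells))) {
      cc <- cells[k, ]
      pick <- function(el) inc$value[inc$taxon == cc$taxon &
                                       inc$food == cc$food &
                                       inc$composition == cc$composition &
                                       inc$element == el]
      c_rates <- pick("C"); n_rates <- pick("N")
      if (!length(c_rates) || !length(n_rates)) next
      tsel <- tiss$taxon == cc$taxon & tiss$composition == cc$composition
      tissue_cn <- mean(tiss$pool_umol[tsel & tiss$element == "C"]) /
        mean(tiss$pool_umol[tsel & tiss$element == "N"])
      stoich[[length(stoich) + 1L]] <- stoichiometric_uptake(
        mean(c_rates), mean(n_rates),
        food_cn = foods$cn_ratio[match(cc$food, foods$name)],
        tissue_cn = tissue_cn, taxon = cc$taxon, food = cc$food,
        composition = cc$composition)
    }
  }
  stoich <- if (length(stoich)) do.call(rbind, stoich) else
    stoichiometric_uptake(NA_real_, NA_real_)[0, ]
  rownames(stoich) <- NULL

  ## --- factorial ANOVAs ---------------------------------------------------
  anovas <- NULL
  if (isTRUE(anova)) {
    anovas <- list()
    try_fit <- function(...) tryCatch(suppressWarnings(factorial_anova(...)),
                                      error = function(e) NULL)
    ss_inc <- inc[inc$taxon == inc$composition &
                    inc$composition %in% c("coral", "sponge"), ]
    ss_inc$species <- ss_inc$taxon
    anovas$incorporation_c <- try_fit(ss_inc[ss_inc$element == "C", ],
                                      "value", c("species", "food"))
    anovas$incorporation_n <- try_fit(ss_inc[ss_inc$element == "N", ],
                                      "value", c("species", "food"))
    resp <- rates[rates$kind == "respiration" &
                    rates$composition %in% c("coral", "sponge"), ]
    resp$species <- resp$taxon
    anovas$respiration <- try_fit(resp, "value", c("species", "food"))
    if (nrow(nge)) {
      nge2 <- nge; nge2$species <- nge2$taxon
      anovas$nge <- try_fit(nge2, "value", c("species", "food"))
    }
    for (sp in c("coral", "sponge")) {
      d <- inc[inc$taxon == sp &
                 inc$composition %in% c(sp, "coral+sponge"), ]
      d$presence <- ifelse(d$composition == sp, "alone", "with_other")
      anovas[[paste0("presence_", sp)]] <-
        try_fit(d, "value", c("presence", "food", "element"),
                interactions = "presence:food")
    }
    cal <- rates[rates$kind == "calcification", ]
    if (nrow(cal)) {
      cal$presence <- ifelse(cal$composition == cal$taxon, "alone",
                             "with_other")
      anovas$calcification <- try_fit(cal, "value", c("presence", "food"),
                                      interactions = "presence:food")
    }
    anovas <- Filter(Negate(is.null), anovas)
  }

  structure(list(rates = rates, budget = budget,
                 budget_summary = budget_summary, nge = nge,
                 stoichiometry = stoich, anova = anovas,
                 measurements = measurements, chambers = chambers,
                 foods = foods),
            class = "tracer_analysis")
}

#' @export
print.tracer_analysis <- function(x, ...) {
  cat("Dual-tracer feeding experiment analysis\n")
  cat("  chambers:         ", nrow(x$chambers), "\n", sep = "")
  cat("  rate records:     ", nrow(x$rates),
      " (", sum(x$rates$negative), " negative, flagged)\n", sep = "")
  cat("  budget rows:      ", nrow(x$budget), " (single-species chambers)\n",
      sep = "")
  if (!is.null(x$anova))
    cat("  ANOVA models:     ", paste(names(x$anova), collapse = ", "), "\n",
        sep = "")
  cat("Use summary() for rate means, budgets, NGE and test results.\n")
  invisible(x)
}

#' @export
summary.tracer_analysis <- function(object, digits = 3, ...) {
  x <- object
  cat("== Mean tracer rates (umol mmol^-1 d^-1; calcification nmol) ==\n")
  print(coef(x), digits = digits)
  if (!is.null(x$budget_summary)) {
    cat("\n== Carbon budget (umol C over the feeding period, mean +/- sd) ==\n")
    bs <- x$budget_summary
    disp <- data.frame(taxon = bs$taxon, food = bs$food,
      tissue = sprintf("%.1f +/- %.1f", bs$tissue_mean, bs$tissue_sd),
      respiration = sprintf("%.1f +/- %.1f", bs$respiration_mean,
                            bs$respiration_sd),
      calcification = sprintf("%.1f +/- %.1f", bs$calcification_mean,
                              bs$calcification_sd),
      unaccounted = sprintf("%.0f +/- %.0f", bs$unaccounted_mean,
                            bs$unaccounted_sd),
      added = bs$added)
    print(disp, row.names = FALSE)
  }
  if (nrow(x$nge)) {
    cat("\n== Net growth efficiency ==\n")
    m <- .agg(x$nge$value, list(taxon = x$nge$taxon, food = x$nge$food), mean)
    names(m)[3] <- "nge_mean"
    print(m, row.names = FALSE, digits = digits)
  }
  if (nrow(x$stoichiometry)) {
    cat("\n== Stoichiometric uptake (C:N of rate means) ==\n")
    print(x$stoichiometry, row.names = FALSE, digits = digits)
  }
  if (!is.null(x$anova)) {
    cat("\n== Factorial ANOVAs (log10 rates) ==\n")
    for (nm in names(x$anova)) {
      a <- x$anova[[nm]]
      terms <- a$term != "Residuals"
      cat(sprintf("  %s: %s\n", nm,
                  paste(sprintf("%s F(%d,%d)=%.3g p=%.3g", a$term[terms],
                                a$df[terms], a$df_den[terms],
                                a$statistic[terms], a$p.value[terms]),
                        collapse = "; ")))
    }
  }
  invisible(x)
}

#' Mean tracer rates per taxon, food, kind and element
#'
#' @param object A `tracer_analysis` object.
#' @param ... Unused.
#' @return A `data.frame` of rate means and sds across replicates, with
#'   calcification on the reporting scale (nmol mmol^-1 d^-1).
#' @export
coef.tracer_analysis <- function(object, ...) {
  r <- .report_rates(object$rates)
  by <- list(taxon = r$taxon, composition = r$composition, food = r$food,
             kind = r$kind, element = r$element, unit = r$unit)
  out <- .agg(r$value, by, mean)
  names(out)[names(out) == "x"] <- "mean"
  out$sd <- .agg(r$value, by, stats::sd)$x
  out$n <- .agg(r$value, by, length)$x
  out[order(out$kind, out$taxon, out$composition, out$food, out$element), ,
      drop = FALSE]
}

#' Plot mean tracer rates of an analyzed experiment
#'
#' Barplot of mean biomass-normalized rates (+/- sd whiskers) per taxon and
#' food source, one panel per rate kind, on a log axis friendly linear scale.
#'
#' @param x A `tracer_analysis` object.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the rate-mean table plotted.
#' @export
plot.tracer_analysis <- function(x, ...) {
  cf <- coef.tracer_analysis(x)
  cf <- cf[cf$taxon == cf$composition | cf$kind == "respiration", ]
  kinds <- unique(cf$kind)
  old <- graphics::par(mfrow = c(1, length(kinds)), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(old))
  for (k in kinds) {
    d <- cf[cf$kind == k, ]
    d$sd[!is.finite(d$sd)] <- 0
    lab <- paste(d$taxon, d$food, d$element, sep = "\n")
    ylab <- if (k == "calcification") "nmol mmol^-1 d^-1" else
      "umol mmol^-1 d^-1"
    top <- max(c(d$mean + d$sd, 0), na.rm = TRUE)
    bp <- graphics::barplot(d$mean, names.arg = lab, las = 2, main = k,
                            ylab = ylab,
                            ylim = c(0, if (top > 0) top * 1.1 else 1), ...)
    has_sd <- d$sd > max(top, .Machine$double.eps) * 1e-6
    if (any(has_sd)) {
      x <- bp[has_sd]
      lo <- d$mean[has_sd] - d$sd[has_sd]
      hi <- d$mean[has_sd] + d$sd[has_sd]
      graphics::segments(x, lo, x, hi)
      w <- 0.15
      graphics::segments(x - w, lo, x + w, lo)
      graphics::segments(x - w, hi, x + w, hi)
    }
  }
  invisible(cf)
}
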