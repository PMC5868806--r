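# CSV schemas and validated readers/writers.
#
# Dialect: UTF-8, comma-separated, mandatory header row, decimal point.
# Missing values are empty cells, never sentinel numbers.

.SCHEMAS <- list(
  measurements = list(
    cols = c("treatment", "composition", "replicate", "taxon", "pool",
             "element", "delta_sample", "delta_control", "pool_umol"),
    numeric = c("delta_sample", "delta_control", "pool_umol")),
  chambers = list(
    cols = c("treatment", "composition", "replicate", "volume_l",
             "dic_umol_per_l", "feeding_days", "respiration_days",
             "delta_dic_start", "delta_dic_end"),
    numeric = c("volume_l", "dic_umol_per_l", "feeding_days",
                "respiration_days", "delta_dic_start", "delta_dic_end")),
  foods = list(
    cols = c("name", "treatment", "labeled_element", "enrichment", "cn_ratio",
             "added_c", "added_n"),
    numeric = c("enrichment", "cn_ratio", "added_c", "added_n"))
)

.validate_table <- function(df, what, file = NULL) {
  schema <- .SCHEMAS[[what]]
  src <- if (is.null(file)) paste0(what, " table") else
    paste0(what, " file '", file, "'")
  if (!is.data.frame(df)) stop(src, ": not a data frame", call. = FALSE)
  missing <- setdiff(schema$cols, names(df))
  if (length(missing))
    stop(src, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in schema$numeric)
    if (!is.numeric(df[[col]]))
      stop(src, ": column '", col, "' must be numeric", call. = FALSE)
  bad_row <- function(cond, msg) {
    if (any(cond, na.rm = TRUE))
      stop(src, ", row ", which(cond)[1L], ": ", msg, call. = FALSE)
  }
  if (what == "measurements") {
    bad_row(!df$pool %in% c("tissue", "total"),
            "column 'pool' must be 'tissue' or 'total'")
    bad_row(!df$element %in% c("C", "N"), "column 'element' must be C or N")
    bad_row(!is.finite(df$pool_umol) | df$pool_umol <= 0,
            "column 'pool_umol' must be > 0")
    bad_row(df$delta_sample <= -1000 | df$delta_control <= -1000,
            "delta values must be > -1000 permil")
  } else if (what == "chambers") {
    bad_row(df$volume_l <= 0, "column 'volume_l' must be > 0")
    bad_row(df$dic_umol_per_l <= 0, "column 'dic_umol_per_l' must be > 0")
    bad_row(df$feeding_days <= 0 | df$respiration_days <= 0,
            "durations must be > 0 days")
  } else if (what == "foods") {
    bad_row(!df$labeled_element %in% c("C", "N"),
            "column 'labeled_element' must be C or N")
    bad_row(df$enrichment <= 0 | df$enrichment > 1,
            "column 'enrichment' must lie in (0, 1]")
    bad_row(df$cn_ratio <= 0, "column 'cn_ratio' must be > 0")
    bad_row(df$added_c < 0, "column 'added_c' must be >= 0")
  }
  df
}

.read_table <- function(path, what) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(what, " file not found: ", path, call. = FALSE)
  .validate_table(utils::read.csv(path, stringsAsFactors = FALSE), what, path)
}

#' Read the per-specimen isotope measurement table
#'
#' One row per (treatment, composition, replicate, taxon, pool, element):
#' `delta_sample` and `delta_control` in permil against the fixed reference
#' ratios, and `pool_umol`, the size of the measured element pool. `pool` is
#' `"tissue"` (decalcified organic fraction) or `"total"` (organic plus
#' inorganic skeleton, corals only, element C).
#'
#' @param path Path to a CSV file.
#' @return A validated `data.frame`.
#' @export
read_measurements <- function(path) .read_table(path, "measurements")

#' Read the per-chamber incubation table
#'
#' One row per incubation chamber (treatment, composition, replicate):
#' chamber volume (L), DIC concentration (umol L^-1), the feeding-period and
#' closed respiration-incubation durations (days), and the DIC delta-13C
#' before and after the closed incubation (permil).
#'
#' @param path Path to a CSV file.
#' @return A validated `data.frame`.
#' @export
read_chambers <- function(path) .read_table(path, "chambers")

#' Read the food-source table
#'
#' One row per (treatment, food): labeled element, realized atom-fraction
#' enrichment, molar C:N, and total amounts added per chamber.
#'
#' @param path Path to a CSV file.
#' @return A validated `data.frame`.
#' @export
read_foods <- function(path) .read_table(path, "foods")

# Reporting-layer unit policy: calcification rates leave the package in
# nmol mmol^-1 d^-1; everything else in umol mmol^-1 d^-1.
.report_rates <- function(rates) {
  out <- rates
  is_cal <- out$kind == "calcification"
  out$value[is_cal] <- out$value[is_cal] * 1000
  out$unit <- ifelse(is_cal, "nmol_per_mmol_d", "umol_per_mmol_d")
  out
}

#' Write all result tables of a tracer analysis to CSV
#'
#' Writes `rates.csv` (calcification rescaled to nmol mmol^-1 d^-1 with an
#' explicit `unit` column), `budget.csv` (per-replicate budgets),
#' `budget_summary.csv` (mean and sd per taxon x food, rounded to reporting
#' precision: one decimal for tracer amounts, integers for the unaccounted
#' closure term), `nge.csv`, `stoichiometry.csv`, `anova.csv`, and a
#' `run_log.txt` recording the configuration.
#'
#' @param x A [tracer_analysis()] result.
#' @param dir Output directory; created if absent.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "tracer_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, file) {
    p <- file.path(dir, file)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  wr(.report_rates(x$rates), "rates.csv")
  wr(x$budget, "budget.csv")
  bs <- x$budget_summary
  for (col in c("tissue_mean", "tissue_sd", "respiration_mean",
                "respiration_sd", "calcification_mean", "calcification_sd"))
    bs[[col]] <- round(bs[[col]], 1)
  for (col in c("unaccounted_mean", "unaccounted_sd"))
    bs[[col]] <- round(bs[[col]])
  wr(bs, "budget_summary.csv")
  wr(x$nge, "nge.csv")
  wr(x$stoichiometry, "stoichiometry.csv")
  if (!is.null(x$anova)) {
    tabs <- lapply(names(x$anova), function(nm)
      cbind(model = nm, as.data.frame(x$anova[[nm]])))
    wr(do.call(rbind, tabs), "anova.csv")
  }
  log_path <- file.path(dir, "run_log.txt")
  writeLines(c(
    paste0("dualtracer ", as.character(utils::packageVersion("dualtracer"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("measurement rows: ", nrow(x$measurements)),
    paste0("chambers: ", nrow(x$chambers)),
    paste0("foods: ", paste(unique(x$foods$name), collapse = ", ")),
    paste0("negative-rate flags: ", sum(x$rates$negative))
  ), log_path)
  invisible(c(paths, log_path))
}

#' Write a simulated experiment to CSV files
#'
#' Writes `measurements.csv`, `chambers.csv`, `foods.csv` (the schemas the
#' readers expect) and `truth.csv` (the generator's true rates, for parameter
#' recovery) into `dir`.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory; created if absent.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tracer_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(c("measurements", "chambers", "foods", "truth"),
                  function(nm) {
                    p <- file.path(dir, paste0(nm, ".csv"))
                    utils::write.csv(sim[[nm]], p, row.names = FALSE, na = "")
                    p
                  }, character(1))
  invisible(paths)
}
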