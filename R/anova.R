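# Fixed-effects factorial ANOVA on log10-transformed rates.

#' Factorial ANOVA on (log-transformed) tracer rates
#'
#' Fits a fixed-effects least-squares ANOVA of a rate column on categorical
#' design factors, by default after a log10 transform (tracer rates are
#' right-skewed and multiplicative). Sums of squares are sequential (Type I),
#' which coincides with Type II/III on the balanced designs these experiments
#' use; on unbalanced data the term order therefore matters and is the order
#' of `factors`.
#'
#' Non-positive or non-finite responses cannot be log-transformed and are
#' removed with a warning. Every factor must have at least two observed
#' levels, and every cell of the full factorial must be observed; an empty
#' cell is an error naming the missing combination.
#'
#' @param data A `data.frame` of rate records.
#' @param response Name of the (strictly positive) response column.
#' @param factors Character vector of factor column names (main effects, in
#'   the order sums of squares are assigned).
#' @param interactions Optional character vector of interaction terms in
#'   formula notation, e.g. `"treatment:food"`.
#' @param transform `"log10"` (default) or `"none"`.
#' @return A `factorial_anova` object: a `data.frame` with one row per model
#'   term (`term`, `df`, `sumsq`, `meansq`, `statistic`, `df_den`,
#'   `p.value`), the residual row last. The fitted `lm` is attached as
#'   attribute `"fit"`.
#' @examples
#' d <- expand.grid(species = c("coral", "sponge"),
#'                  food = c("algae", "bacteria"), rep = 1:3)
#' d$rate <- ifelse(d$species == "sponge", 3, 0.1) * exp(rnorm(nrow(d), 0, .2))
#' factorial_anova(d, "rate", c("species", "food"))
#' @export
factorial_anova <- function(data, response, factors, interactions = NULL,
                            transform = c("log10", "none")) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(data), length(factors) >= 1L)
  missing_cols <- setdiff(c(response, factors), names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- data[[response]]
  if (transform == "log10") {
    bad <- !is.finite(y) | y <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive or non-finite response value(s) ",
              "removed before the log10 transform", call. = FALSE)
      data <- data[!bad, , drop = FALSE]
    }
    data$.y <- log10(data[[response]])
  } else {
    data$.y <- y
  }
  if (nrow(data) < length(factors) + 2L)
    stop("too few usable observations for the requested design",
         call. = FALSE)
  for (f in factors) {
    data[[f]] <- factor(as.character(data[[f]]))
    if (nlevels(data[[f]]) < 2L)
      stop("factor '", f, "' has fewer than 2 observed levels", call. = FALSE)
  }
  cells <- table(data[factors])
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)
    idx <- if (is.matrix(idx)) idx[1L, ] else idx[1L]
    lev <- vapply(seq_along(factors),
                  function(k) dimnames(cells)[[k]][idx[k]], character(1))
    stop("empty design cell: ",
         paste(factors, lev, sep = " = ", collapse = ", "), call. = FALSE)
  }
  rhs <- paste(c(factors, interactions), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = data)
  at <- stats::anova(fit)
  terms <- rownames(at)
  df_den <- at["Residuals", "Df"]
  out <- data.frame(term = terms, df = at$Df, sumsq = at$`Sum Sq`,
                    meansq = at$`Mean Sq`, statistic = at$`F value`,
                    df_den = ifelse(terms == "Residuals", NA_real_, df_den),
                    p.value = at$`Pr(>F)`, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  attr(out, "transform") <- transform
  attr(out, "response") <- response
  class(out) <- c("factorial_anova", "data.frame")
  out
}

#' @export
print.factorial_anova <- function(x, digits = 4, ...) {
  cat("Factorial ANOVA on ",
      if (attr(x, "transform") == "log10") "log10(" else "",
      attr(x, "response"),
      if (attr(x, "transform") == "log10") ")" else "", "\n\n", sep = "")
  df <- as.data.frame(x)
  df$sumsq <- signif(df$sumsq, digits)
  df$meansq <- signif(df$meansq, digits)
  df$statistic <- signif(df$statistic, digits)
  df$p.value <- signif(df$p.value, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
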