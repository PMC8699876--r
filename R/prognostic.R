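#' Analytical-error scenario for biohumoral variables
#'
#' Laboratory analytical error in clinical biochemistry reaches at most 13%.
#' Two propagation scenarios are modelled: `maximum` multiplies every
#' error-injectable value by `1 + max_fraction`; `random` multiplies each
#' value by an independent uniform draw from
#' `[1 - max_fraction, 1 + max_fraction]` (i.e. 0.87-1.13 at the default).
#'
#' @param kind `"none"`, `"maximum"` or `"random"`.
#' @param max_fraction maximum analytical error fraction (default 0.13).
#' @param direction for `maximum`: `"increase"` (default) or `"decrease"`.
#' @param per_column logical; draw one multiplier per column instead of per
#'   cell in the random scenario.
#' @param seed integer seed for the random scenario.
#' @return A list of class `error_scenario`.
#' @export
error_scenario <- function(kind = c("none", "maximum", "random"),
                           max_fraction = 0.13,
                           direction = c("increase", "decrease"),
                           per_column = FALSE, seed = 1L) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  stopifnot(max_fraction > 0, max_fraction < 1)
  structure(list(kind = kind, max_fraction = max_fraction, direction = direction,
                 per_column = per_column, seed = as.integer(seed)),
            class = "error_scenario")
}

injectable_columns <- function(table) {
  cols <- attr(table, "biohumoral")
  if (is.null(cols)) cols <- intersect(biohumoral_roster(), names(table))
  if (!length(cols)) stop("no error-injectable biohumoral columns found", call. = FALSE)
  cols
}

#' Inject analytical measurement error into a cohort table
#'
#' Only the biohumoral columns (the `"biohumoral"` attribute, or the standard
#' roster) are modified; outcome and non-biohumoral predictors are untouched.
#' The random scenario is fully reproducible given its seed.
#'
#' @param table cohort tibble (see [generate_cohort()]).
#' @param scenario an [error_scenario()].
#' @return The table with perturbed biohumoral columns.
#' @export
inject_error <- function(table, scenario) {
  stopifnot(inherits(scenario, "error_scenario"))
  cols <- injectable_columns(table)
  if (scenario$kind == "none") return(table)
  if (scenario$kind == "maximum") {
    f <- if (scenario$direction == "increase") 1 + scenario$max_fraction else
      1 - scenario$max_fraction
    for (cc in cols) table[[cc]] <- table[[cc]] * f
    return(table)
  }
  lo <- 1 - scenario$max_fraction
  hi <- 1 + scenario$max_fraction
  with_seed(scenario$seed, {
    for (cc in cols) {
      mult <- if (scenario$per_column) runif(1, lo, hi) else runif(nrow(table), lo, hi)
      table[[cc]] <- table[[cc]] * mult
    }
  })
  table
}

fit_one <- function(table, formula, model, term, alpha) {
  fit <- if (model == "linear") lm(formula, data = table) else
    glm(formula, data = table, family = binomial())
  cf <- coef(summary(fit))
  if (!term %in% rownames(cf)) return(NULL)
  est <- cf[term, 1]
  se <- cf[term, 2]
  crit <- if (model == "linear") qt(0.975, df = fit$df.residual) else 1.96
  p <- cf[term, 4]
  tibble::tibble(term = term, estimate = est,
                 ci_low = est - crit * se, ci_high = est + crit * se,
                 p_value = p, significant = p < alpha)
}

#' Univariate screen for association with plaque progression
#'
#' Fits one single-predictor regression of the outcome per variable and
#' reports the coefficient, Wald 95% CI and p-value. Ordinary least squares
#' by default (the reported multivariate models are linear); a logistic
#' option covers a binary progression outcome. No multiple-testing
#' correction is applied by default, matching the reported analysis; set
#' `p_adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param table cohort tibble.
#' @param vars variables to screen (default: the biohumoral columns).
#' @param outcome outcome column name.
#' @param model `"linear"` or `"logistic"`.
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Tibble of class `regression_report` with one row per screened
#'   variable: `term, estimate, ci_low, ci_high, p_value, significant`.
#'   Constant predictors are skipped with a warning.
#' @export
univariate_screen <- function(table, vars = injectable_columns(table),
                              outcome = "plaque_progression",
                              model = c("linear", "logistic"), alpha = 0.05,
                              p_adjust = c("none", "BH")) {
  model <- match.arg(model)
  p_adjust <- match.arg(p_adjust)
  if (!outcome %in% names(table)) stop("outcome column not found", call. = FALSE)
  if (anyNA(table[[outcome]])) stop("missing outcome values", call. = FALSE)
  rows <- lapply(vars, function(v) {
    if (sd(table[[v]]) == 0) {
      warning(sprintf("skipping constant predictor '%s'", v), call. = FALSE)
      return(NULL)
    }
    fit_one(table, stats::reformulate(v, outcome), model, v, alpha)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, "BH")
    out$significant <- out$p_value < alpha
  }
  class(out) <- c("regression_report", class(out))
  out
}

#' Multivariate regression over a fixed predictor list
#'
#' Joint linear (or logistic) fit of the outcome on the supplied predictors,
#' with per-coefficient Wald 95% CI and p-value. Rank-deficient designs are
#' rejected with an error naming the collinear columns.
#'
#' @inheritParams univariate_screen
#' @param predictors character vector of predictor column names.
#' @return Tibble of class `regression_report`, one row per predictor.
#' @export
multivariate_fit <- function(table, predictors, outcome = "plaque_progression",
                             model = c("linear", "logistic"), alpha = 0.05) {
  model <- match.arg(model)
  if (nrow(table) <= length(predictors) + 1) {
    stop("need more observations than parameters", call. = FALSE)
  }
  mm <- stats::model.matrix(stats::reformulate(predictors), data = table)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop(sprintf("rank-deficient design: collinear columns %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  formula <- stats::reformulate(predictors, outcome)
  fit <- if (model == "linear") lm(formula, data = table) else
    glm(formula, data = table, family = binomial())
  cf <- coef(summary(fit))
  terms <- setdiff(rownames(cf), "(Intercept)")
  crit <- if (model == "linear") qt(0.975, df = fit$df.residual) else 1.96
  out <- tibble::tibble(term = terms, estimate = cf[terms, 1],
                        ci_low = cf[terms, 1] - crit * cf[terms, 2],
                        ci_high = cf[terms, 1] + crit * cf[terms, 2],
                        p_value = cf[terms, 4],
                        significant = cf[terms, 4] < alpha)
  class(out) <- c("regression_report", class(out))
  out
}

#' Compare predictor significance across error scenarios
#'
#' Tabulates, per variable, which scenarios flag it significant, and the
#' Jaccard overlap of each scenario's significant set with the first
#' (reference) scenario's.
#'
#' @param reports named list of `regression_report`s over the same variables
#'   (first entry is the reference).
#' @return List with `pattern` (tibble: term x scenario significance flags)
#'   and `jaccard` (named numeric, overlap of each scenario with the first).
#' @export
compare_scenarios <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 2)
  terms <- reports[[1]]$term
  for (r in reports) {
    if (!identical(sort(r$term), sort(terms))) {
      stop("mismatched variable rosters across reports", call. = FALSE)
    }
  }
  flags <- lapply(reports, function(r) r$significant[match(terms, r$term)])
  pattern <- tibble::as_tibble(c(list(term = terms), flags))
  ref_set <- terms[flags[[1]]]
  jac <- vapply(flags, function(f) {
    s <- terms[f]
    if (!length(ref_set) && !length(s)) return(1)
    length(intersect(ref_set, s)) / length(union(ref_set, s))
  }, numeric(1))
  list(pattern = pattern, jaccard = jac)
}
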