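#' Standard biohumoral variable roster
#'
#' The sixteen serum/biomarker variables screened for association with plaque
#' progression; these are the columns treated as error-injectable by the
#' analytical-error scenarios.
#'
#' @return Character vector of column names.
#' @export
biohumoral_roster <- function() {
  c("alanine", "alkaline", "aspartate", "gamma_GT", "creatinine", "uric_acid",
    "glucose", "triglycerides", "cholesterol", "LDL", "HDL",
    "reactive_protein", "interleukin_6", "leptin", "ICAM1", "VCAM1")
}

# log-normal marginals with plausible clinical central values (units are the
# usual lab units; exact marginals are config-irrelevant to the contracts)
biohumoral_marginals <- function() {
  means <- c(alanine = 25, alkaline = 70, aspartate = 25, gamma_GT = 30,
             creatinine = 0.9, uric_acid = 5.5, glucose = 100,
             triglycerides = 130, cholesterol = 190, LDL = 115, HDL = 50,
             reactive_protein = 2, interleukin_6 = 2, leptin = 10,
             ICAM1 = 250, VCAM1 = 550)
  list(meanlog = log(means), sdlog = setNames(rep(0.35, length(means)), names(means)))
}

#' Recipe for a synthetic patient cohort
#'
#' The cohort table carries the biohumoral roster, age, four lipidomic
#' species, baseline plaque burden, minimum ESS, maximum wall LDL
#' concentration and SmartFFR, plus a plaque-progression outcome. Only the
#' predictors named in `coefficients` have planted (true) effects on the
#' outcome; every other variable is null.
#'
#' @param n_patients number of rows (default 20, the study cohort size; >= 10).
#' @param coefficients named numeric vector of true linear effects on the
#'   continuous progression outcome. Defaults plant age (+0.010 per year) and
#'   baseline plaque burden (-0.011 per % burden).
#' @param noise_sd residual standard deviation of the continuous outcome.
#' @param outcome `"continuous"` (progression score) or `"binary"`
#'   (progression yes/no via a logistic link).
#' @param seed integer seed.
#' @return A list of class `cohort_recipe`.
#' @export
cohort_recipe <- function(n_patients = 20,
                          coefficients = c(age = 0.010, baseline_plaque_burden = -0.011),
                          noise_sd = 0.3,
                          outcome = c("continuous", "binary"),
                          seed = 1L) {
  outcome <- match.arg(outcome)
  if (n_patients < 10) stop("n_patients must be at least 10", call. = FALSE)
  stopifnot(noise_sd >= 0)
  structure(list(n_patients = as.integer(n_patients), coefficients = coefficients,
                 noise_sd = noise_sd, outcome = outcome, seed = as.integer(seed)),
            class = "cohort_recipe")
}

#' Generate a synthetic patient cohort table
#'
#' @param recipe a [cohort_recipe()].
#' @return A tibble with one row per patient, the outcome in column
#'   `plaque_progression`, and the error-injectable columns recorded in the
#'   `"biohumoral"` attribute. Deterministic given the recipe seed.
#' @export
generate_cohort <- function(recipe) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  n <- recipe$n_patients
  with_seed(recipe$seed, {
    marg <- biohumoral_marginals()
    bio <- lapply(biohumoral_roster(), function(v) {
      rlnorm(n, meanlog = marg$meanlog[[v]], sdlog = marg$sdlog[[v]])
    })
    names(bio) <- biohumoral_roster()
    tab <- tibble::as_tibble(bio)
    tab$age <- round(rnorm(n, 65, 8))
    tab$CE_18_3 <- rlnorm(n, log(2), 0.4)
    tab$CE_20_3 <- rlnorm(n, log(1), 0.4)
    tab$CE_20_4 <- rlnorm(n, log(4), 0.4)
    tab$PS_38_6 <- rlnorm(n, log(0.5), 0.4)
    tab$baseline_plaque_burden <- runif(n, 20, 60)       # percent
    tab$min_ESS <- rlnorm(n, log(0.6), 0.4)              # Pa
    tab$max_LDL_concentration <- rlnorm(n, log(6e-4), 0.3)
    tab$SmartFFR <- pmin(1, 0.80 + 0.20 * stats::rbeta(n, 4, 1.2))
    eta <- rep(0, n)
    for (v in names(recipe$coefficients)) {
      if (!v %in% names(tab)) {
        stop(sprintf("unknown predictor '%s' in recipe coefficients", v), call. = FALSE)
      }
      eta <- eta + recipe$coefficients[[v]] * tab[[v]]
    }
    if (recipe$outcome == "continuous") {
      tab$plaque_progression <- eta + rnorm(n, 0, recipe$noise_sd)
    } else {
      tab$plaque_progression <- rbinom(n, 1, plogis(eta - mean(eta)))
    }
    attr(tab, "biohumoral") <- biohumoral_roster()
    tab
  })
}
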