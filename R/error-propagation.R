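#' Paired original-vs-perturbed comparison
#'
#' Holds matched values from the original and a perturbed model run. The
#' default difference convention is `original - perturbed`, which is the
#' convention under which the published per-case SmartFFR differences
#' reproduce (-0.004 for overestimation, +0.009 for underestimation).
#'
#' @param original,perturbed numeric vectors of equal length (n >= 2).
#' @param sign_convention `"original_minus_perturbed"` or
#'   `"perturbed_minus_original"`.
#' @return A list of class `paired_comparison` with `differences` and `n`.
#' @export
paired_comparison <- function(original, perturbed,
                              sign_convention = c("original_minus_perturbed",
                                                  "perturbed_minus_original")) {
  sign_convention <- match.arg(sign_convention)
  if (length(original) != length(perturbed)) {
    stop("original and perturbed must have equal length", call. = FALSE)
  }
  if (length(original) < 2) stop("need at least 2 paired values", call. = FALSE)
  d <- if (sign_convention == "original_minus_perturbed") {
    original - perturbed
  } else {
    perturbed - original
  }
  structure(list(original = original, perturbed = perturbed, differences = d,
                 n = length(d), sign_convention = sign_convention),
            class = "paired_comparison")
}

pop_or_sample_sd <- function(x, convention) {
  s <- sd(x)
  if (convention == "population") s * sqrt((length(x) - 1) / length(x)) else s
}

#' Mean and standard deviation of paired differences
#'
#' @param comp a [paired_comparison()].
#' @param sd_convention `"population"` (divide by n; the default, matching
#'   the published SmartFFR difference spreads) or `"sample"`.
#' @return List with `mean_diff` and `sd_diff`.
#' @export
paired_stats <- function(comp, sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  stopifnot(inherits(comp, "paired_comparison"))
  list(mean_diff = mean(comp$differences),
       sd_diff = pop_or_sample_sd(comp$differences, sd_convention))
}

#' Bland-Altman limits of agreement
#'
#' Limits are `mean +/- 1.96 sd` of the paired differences; the 95% CI of
#' each limit uses the standard Bland-Altman variance `3 sd^2 / n`.
#'
#' `bland_altman_moments()` computes the same quantities directly from a
#' stated mean, sd and n (e.g. from published summary values).
#'
#' @inheritParams paired_stats
#' @return List of class `bland_altman` with `mean_diff, sd_diff, loa_low,
#'   loa_high, ci_low, ci_high` (each CI a length-2 vector), `n`.
#' @export
bland_altman <- function(comp, sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  stopifnot(inherits(comp, "paired_comparison"))
  st <- paired_stats(comp, sd_convention)
  bland_altman_moments(st$mean_diff, st$sd_diff, comp$n)
}

#' @param mean_diff,sd_diff,n stated moments of the paired differences.
#' @rdname bland_altman
#' @export
bland_altman_moments <- function(mean_diff, sd_diff, n) {
  stopifnot(n >= 2, sd_diff >= 0)
  half <- 1.96 * sd_diff
  se_limit <- sqrt(3 * sd_diff^2 / n)
  loa_low <- mean_diff - half
  loa_high <- mean_diff + half
  structure(list(mean_diff = mean_diff, sd_diff = sd_diff,
                 loa_low = loa_low, loa_high = loa_high,
                 ci_low = c(loa_low - 1.96 * se_limit, loa_low + 1.96 * se_limit),
                 ci_high = c(loa_high - 1.96 * se_limit, loa_high + 1.96 * se_limit),
                 n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean %.4f +/- %.4f; LoA [%.4f, %.4f] (n = %d)\n",
              x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors (n >= 3) with nonzero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need at least 3 paired values", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  cor(x, y, method = "pearson")
}

#' Relative-error summary between two models' summary statistics
#'
#' Percentage difference of a perturbed model's summary statistic from the
#' original's, computed elementwise on the (min, max, mean) triple:
#' `100 * (perturbed - original) / original`.
#'
#' @param orig,pert numeric length-3 vectors `(min, max, mean)` of the
#'   original and perturbed model; original entries must be nonzero.
#' @return List of class `relative_error_summary` with `re_min, re_max,
#'   re_mean` (percent).
#' @export
relative_error_summary <- function(orig, pert) {
  stopifnot(length(orig) == 3, length(pert) == 3)
  if (any(orig == 0)) stop("undefined relative error: zero original statistic", call. = FALSE)
  re <- 100 * (pert - orig) / orig
  structure(list(re_min = re[[1]], re_max = re[[2]], re_mean = re[[3]]),
            class = "relative_error_summary")
}

#' Quadrature propagation of uncertainty across simulation levels
#'
#' Combined uncertainty of a level given its own spread and the uncertainty
#' carried over from the previous level:
#' `u = sqrt(sd^2 + u_prev^2)` (the addition/subtraction propagation
#' formula). The reconstruction level's uncertainty is 0.09.
#'
#' @param sd standard deviation observed at the current level (>= 0).
#' @param u_prev combined uncertainty of the previous level (>= 0;
#'   default 0.09, the reconstruction uncertainty).
#' @return Combined uncertainty `u >= max(sd, u_prev)`.
#' @export
propagate_uncertainty <- function(sd, u_prev = 0.09) {
  if (any(sd < 0) || any(u_prev < 0)) {
    stop("sd and u_prev must be non-negative", call. = FALSE)
  }
  sqrt(sd^2 + u_prev^2)
}

#' Original/perturbed propagation report for a station-level quantity
#'
#' Builds one perturbed-model row of the descriptive-statistics report:
#' min/max/mean/sd of the perturbed values, the relative errors of the
#' (min, max, mean) triple against the original, and the quadrature
#' uncertainty of the level.
#'
#' @param original,perturbed numeric vectors of the quantity per station.
#' @param u_prev previous-level uncertainty entering the quadrature.
#' @param sd_convention passed to the spread computation.
#' @return One-row tibble with columns `min, max, mean, sd, re_min, re_max,
#'   re_mean, uncertainty`.
#' @export
propagation_report <- function(original, perturbed, u_prev = 0.09,
                               sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  o <- c(min(original), max(original), mean(original))
  p <- c(min(perturbed), max(perturbed), mean(perturbed))
  re <- relative_error_summary(o, p)
  s <- pop_or_sample_sd(perturbed, sd_convention)
  tibble::tibble(min = p[1], max = p[2], mean = p[3], sd = s,
                 re_min = re$re_min, re_max = re$re_max, re_mean = re$re_mean,
                 uncertainty = propagate_uncertainty(s, u_prev))
}
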