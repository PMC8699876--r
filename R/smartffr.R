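#' Pd/Pa curve over the flow ramp
#'
#' Computes the distal-to-proximal pressure ratio at each flow of the ramp
#' (0, 1, 2, 3, 4 mL/s by default, the five simulated flow states) and
#' resamples it with a shape-preserving monotone cubic spline to exactly 100
#' points spanning the flow range inclusive. At zero flow Pd/Pa is 1 by
#' construction.
#'
#' @param vessel a [new_vessel_model()], or an [axial_profile()].
#' @param flows flow ramp in mL/s.
#' @param cond base [flow_conditions()]; its `flow` field is overridden by
#'   each ramp value.
#' @param n_spline number of resampled points (default 100).
#' @param ... passed to [pressure_profile()].
#' @return List of class `pdpa_curve`: `flows`, `pd_pa` (knot values),
#'   `spline_flows`, `spline_pd_pa`.
#' @export
pdpa_curve <- function(vessel, flows = c(0, 1, 2, 3, 4), cond = flow_conditions(),
                       n_spline = 100, ...) {
  prof <- if (inherits(vessel, "axial_profile")) vessel else axial_profile(vessel)
  stopifnot(length(flows) >= 2, all(flows >= 0), !is.unsorted(flows))
  pd_pa <- vapply(flows, function(q) {
    cq <- cond
    cq$flow <- q
    pressure_profile(prof, cq, ...)$pd_over_pa
  }, numeric(1))
  fun <- splinefun(flows, pd_pa, method = "hyman")
  sf <- seq(min(flows), max(flows), length.out = n_spline)
  structure(list(flows = flows, pd_pa = pd_pa, spline_flows = sf,
                 spline_pd_pa = fun(sf)),
            class = "pdpa_curve")
}

trapezoid_auc <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Pd/Pa curve of the vessel's healthy reference segment
#'
#' The healthy reference shares the vessel's centerline length and station
#' grid but has a constant radius; by default the 95th percentile of the
#' station effective radii, emulating the unobstructed calibre of the
#' segment.
#'
#' @inheritParams pdpa_curve
#' @param reference_radius explicit radius in mm, overriding `method`.
#' @param method `"quantile"` (default) or `"proximal_mean"` (mean radius of
#'   the first five stations).
#' @param q quantile used when `method = "quantile"`.
#' @return A `pdpa_curve` for the constant-radius reference.
#' @export
healthy_reference <- function(vessel, flows = c(0, 1, 2, 3, 4),
                              cond = flow_conditions(), reference_radius = NULL,
                              method = c("quantile", "proximal_mean"), q = 0.95,
                              ...) {
  method <- match.arg(method)
  prof <- if (inherits(vessel, "axial_profile")) vessel else axial_profile(vessel)
  r <- if (!is.null(reference_radius)) {
    reference_radius
  } else if (method == "quantile") {
    unname(quantile(prof$radius_mm, q, type = 7))
  } else {
    mean(utils::head(prof$radius_mm, 5))
  }
  ref <- as_axial_profile(prof$z_mm, rep(pi * r^2, length(prof$z_mm)))
  pdpa_curve(ref, flows = flows, cond = cond, ...)
}

#' SmartFFR: normalized area under the Pd/Pa flow-ramp curve
#'
#' SmartFFR is the trapezoidal area under the vessel's 100-point Pd/Pa curve
#' divided by the area under the curve of its healthy reference segment,
#' clipped to at most 1. Values near the clinical grey zone around 0.80 are
#' flagged: below `cutoff - grey_halfwidth` is `ischemic`, within the band is
#' `grey-zone`, above is `healthy`.
#'
#' @inheritParams pdpa_curve
#' @param cutoff classification cutoff (default 0.80).
#' @param grey_halfwidth half-width of the grey-zone band (default 0.03).
#' @param reference passed through to [healthy_reference()] as
#'   `reference_radius`.
#' @return List of class `smartffr_result`: `auc_case`, `auc_healthy`,
#'   `smartffr`, `classification`.
#' @export
compute_smartffr <- function(vessel, flows = c(0, 1, 2, 3, 4),
                             cond = flow_conditions(), cutoff = 0.80,
                             grey_halfwidth = 0.03, reference = NULL, ...) {
  curve_case <- pdpa_curve(vessel, flows = flows, cond = cond, ...)
  curve_ref <- healthy_reference(vessel, flows = flows, cond = cond,
                                 reference_radius = reference, ...)
  auc_case <- trapezoid_auc(curve_case$spline_flows, curve_case$spline_pd_pa)
  auc_healthy <- trapezoid_auc(curve_ref$spline_flows, curve_ref$spline_pd_pa)
  s <- min(1, auc_case / auc_healthy)
  cls <- if (s < cutoff - grey_halfwidth) {
    "ischemic"
  } else if (s <= cutoff + grey_halfwidth) {
    "grey-zone"
  } else {
    "healthy"
  }
  structure(list(auc_case = auc_case, auc_healthy = auc_healthy,
                 smartffr = s, classification = cls,
                 curve_case = curve_case, curve_healthy = curve_ref),
            class = "smartffr_result")
}

#' @export
print.smartffr_result <- function(x, ...) {
  cat(sprintf("SmartFFR = %.4f (%s); AUC case %.4f / healthy %.4f\n",
              x$smartffr, x$classification, x$auc_case, x$auc_healthy))
  invisible(x)
}

#' SmartFFR report for a set of vessels
#'
#' @param vessels list of `vessel_model`s (any mix of tags).
#' @param ... passed to [compute_smartffr()].
#' @return Tibble with columns `case_id, tag, smartffr, classification,
#'   auc_case, auc_healthy`.
#' @export
smartffr_report <- function(vessels, ...) {
  rows <- lapply(vessels, function(v) {
    r <- compute_smartffr(v, ...)
    tibble::tibble(case_id = v$case_id, tag = v$tag, smartffr = r$smartffr,
                   classification = r$classification, auc_case = r$auc_case,
                   auc_healthy = r$auc_healthy)
  })
  do.call(rbind, rows)
}
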