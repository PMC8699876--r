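#' Blood flow boundary conditions
#'
#' @param viscosity dynamic viscosity of blood in Pa s (default 0.0035,
#'   Newtonian).
#' @param density blood density in kg/m^3 (default 1060).
#' @param inlet_pressure mean inlet (aortic) pressure in mmHg (default 100).
#' @param flow volumetric flow rate in mL/s; 1 mL/s is the average resting
#'   coronary flow.
#' @return A list of class `flow_conditions`.
#' @export
flow_conditions <- function(viscosity = 0.0035, density = 1060,
                            inlet_pressure = 100, flow = 1) {
  stopifnot(viscosity > 0, density > 0, inlet_pressure > 0, flow >= 0)
  structure(list(viscosity = viscosity, density = density,
                 inlet_pressure = inlet_pressure, flow = flow),
            class = "flow_conditions")
}

#' Per-station lumen area and effective radius
#'
#' @param vessel a [new_vessel_model()].
#' @return A tibble of class `axial_profile` with columns `z_mm`,
#'   `area_mm2` (shoelace lumen area) and `radius_mm = sqrt(area / pi)`.
#' @export
axial_profile <- function(vessel) {
  stopifnot(is_vessel_model(vessel))
  areas <- stack_areas(vessel$lumen)
  prof <- tibble::tibble(
    z_mm = (seq_along(areas) - 1) * vessel$lumen$spacing,
    area_mm2 = areas,
    radius_mm = sqrt(areas / pi)
  )
  class(prof) <- c("axial_profile", class(prof))
  prof
}

#' Build an axial profile directly from station areas
#'
#' Useful for idealized geometries (e.g. an exact circular tube) where the
#' polygonal contour discretisation is not wanted.
#'
#' @param z_mm station positions, mm.
#' @param area_mm2 lumen areas, mm^2.
#' @return An `axial_profile` tibble.
#' @export
as_axial_profile <- function(z_mm, area_mm2) {
  prof <- tibble::tibble(z_mm = z_mm, area_mm2 = area_mm2,
                         radius_mm = sqrt(area_mm2 / pi))
  class(prof) <- c("axial_profile", class(prof))
  prof
}

#' Endothelial shear stress along the vessel
#'
#' Reduced-order wall shear stress for fully developed laminar flow:
#' `tau(z) = 4 mu Q / (pi r(z)^3)` in SI units, reported in Pa. This closed
#' form substitutes a 3-D laminar incompressible Navier-Stokes solve; it
#' preserves the monotone area-to-shear structure that the error-propagation
#' analysis exercises.
#'
#' @param profile an [axial_profile()].
#' @param cond [flow_conditions()]; the default rest flow is 1 mL/s.
#' @return Tibble of class `ess_field` with columns `z_mm`, `tau_Pa`.
#' @export
compute_ess <- function(profile, cond = flow_conditions()) {
  stopifnot(inherits(profile, "axial_profile"), inherits(cond, "flow_conditions"))
  if (any(profile$radius_mm <= 0)) stop("profile error: non-positive radius", call. = FALSE)
  r_m <- profile$radius_mm * 1e-3
  q_m3s <- cond$flow * 1e-6
  out <- tibble::tibble(z_mm = profile$z_mm,
                        tau_Pa = 4 * cond$viscosity * q_m3s / (pi * r_m^3))
  attr(out, "flow_conditions") <- cond
  class(out) <- c("ess_field", class(out))
  out
}

# Contiguous runs of stations with area below `threshold` * reference area,
# each treated as one stenosis with its own throat.
detect_stenoses <- function(area, a_ref, threshold = 0.95) {
  below <- area < threshold * a_ref
  if (!any(below)) return(list())
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(k) {
    span <- starts[k]:ends[k]
    list(stations = span, throat_station = span[which.min(area[span])],
         a_throat = min(area[span]))
  })
}

#' Pressure profile and distal-to-proximal pressure ratio
#'
#' Axial pressure from a reduced-order model: a Poiseuille viscous gradient
#' `8 mu Q / (pi r^4)` integrated by the trapezoid rule over the stations,
#' plus a Young-type flow-separation loss
#' `K_t (rho/2) (Q/A_ref)^2 (A_ref/A_throat - 1)^2` applied at the throat of
#' each detected stenosis. Pd/Pa is `(P_in - dP) / P_in`, floored at
#' `pd_pa_floor`.
#'
#' @inheritParams compute_ess
#' @param kt separation-loss coefficient (default 1.52).
#' @param separation logical; disable for a purely viscous model.
#' @param ref_quantile quantile of the station areas used as the reference
#'   (healthy) area for stenosis detection and the separation term.
#' @param pd_pa_floor lower clamp for Pd/Pa (default 0); a clamped value is
#'   reported with a warning.
#' @return List of class `pressure_profile`: `pressure_mmHg` per station,
#'   `delta_p_mmHg`, `pd_over_pa`, and the conditions used.
#' @export
pressure_profile <- function(profile, cond = flow_conditions(), kt = 1.52,
                             separation = TRUE, ref_quantile = 0.95,
                             pd_pa_floor = 0) {
  stopifnot(inherits(profile, "axial_profile"), inherits(cond, "flow_conditions"))
  r_m <- profile$radius_mm * 1e-3
  z_m <- profile$z_mm * 1e-3
  q <- cond$flow * 1e-6
  grad <- 8 * cond$viscosity * q / (pi * r_m^4)          # Pa per m
  n <- length(z_m)
  visc_drop <- c(0, cumsum((grad[-n] + grad[-1]) / 2 * diff(z_m)))
  sep_drop <- rep(0, n)
  if (separation && q > 0 && kt > 0) {
    a_m2 <- profile$area_mm2 * 1e-6
    a_ref <- unname(quantile(a_m2, ref_quantile, type = 7))
    for (s in detect_stenoses(a_m2, a_ref)) {
      loss <- kt * (cond$density / 2) * (q / a_ref)^2 * (a_ref / s$a_throat - 1)^2
      sep_drop[seq_len(n) >= s$throat_station] <- sep_drop[seq_len(n) >= s$throat_station] + loss
    }
  }
  p_pa <- cond$inlet_pressure * MMHG_PA - visc_drop - sep_drop
  p_mmhg <- p_pa / MMHG_PA
  dp <- cond$inlet_pressure - p_mmhg[n]
  pd_pa <- (cond$inlet_pressure - dp) / cond$inlet_pressure
  if (pd_pa < pd_pa_floor) {
    warning(sprintf("distal pressure below floor (Pd/Pa = %.4f); clamped", pd_pa))
    pd_pa <- pd_pa_floor
  }
  structure(list(z_mm = profile$z_mm, pressure_mmHg = p_mmhg,
                 delta_p_mmHg = dp, pd_over_pa = pd_pa, conditions = cond,
                 kt = kt, separation = separation),
            class = "pressure_profile")
}

#' Hemodynamics results table for a vessel
#'
#' Convenience wrapper combining area, radius, shear stress and pressure per
#' station at a single flow.
#'
#' @inheritParams axial_profile
#' @inheritParams compute_ess
#' @param ... passed to [pressure_profile()].
#' @return Tibble with columns `case_id, tag, z_mm, area_mm2, radius_mm,
#'   tau_Pa, P_mmHg`.
#' @export
hemodynamics_table <- function(vessel, cond = flow_conditions(), ...) {
  prof <- axial_profile(vessel)
  ess <- compute_ess(prof, cond)
  pp <- pressure_profile(prof, cond, ...)
  tibble::tibble(case_id = vessel$case_id, tag = vessel$tag,
                 z_mm = prof$z_mm, area_mm2 = prof$area_mm2,
                 radius_mm = prof$radius_mm, tau_Pa = ess$tau_Pa,
                 P_mmHg = pp$pressure_mmHg)
}
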