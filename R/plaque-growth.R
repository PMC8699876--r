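#' Kedem-Katchalsky endothelial transport parameters
#'
#' Membrane-transport relations coupling the transmural volume flux and the
#' solute flux across the endothelium. The solute permeability is
#' shear-dependent, `P(tau) = P0 * (1 + a / (1 + b * tau))`, strictly
#' decreasing in the local shear stress: low-shear regions are more permeable
#' to LDL, the mechanistic link through which a lumen-area error propagates
#' into plaque growth.
#'
#' @param Lp hydraulic conductivity, m/(s Pa).
#' @param sigma_d osmotic reflection coefficient, in [0, 1].
#' @param sigma_f solvent-drag reflection coefficient, in [0, 1].
#' @param P0 baseline solute permeability, m/s.
#' @param a,b shear-modulation coefficients (dimensionless; 1/Pa). Defaults
#'   give a mild modulation over the physiological 0.5-25 Pa shear range.
#' @param delta_p transmural pressure difference, Pa (default 70 mmHg).
#' @param delta_pi transmural osmotic pressure difference, Pa.
#' @return A list of class `kk_params`.
#' @export
kk_params <- function(Lp = 3e-12, sigma_d = 0.997, sigma_f = 0.997,
                      P0 = 2e-11, a = 0.5, b = 1,
                      delta_p = 70 * MMHG_PA, delta_pi = 2660) {
  stopifnot(Lp >= 0, P0 >= 0, sigma_d >= 0, sigma_d <= 1,
            sigma_f >= 0, sigma_f <= 1, a >= 0, b >= 0)
  structure(list(Lp = Lp, sigma_d = sigma_d, sigma_f = sigma_f, P0 = P0,
                 a = a, b = b, delta_p = delta_p, delta_pi = delta_pi),
            class = "kk_params")
}

#' Endothelial volume and solute flux
#'
#' `Jv = Lp (dp - sigma_d dpi)` and
#' `Js = P(tau) (C_lumen - C_wall) + (1 - sigma_f) Jv (C_lumen + C_wall) / 2`.
#'
#' @param tau local wall shear stress, Pa (scalar or vector).
#' @param c_lumen,c_wall species concentration on the lumen and wall side
#'   (arbitrary units, non-negative).
#' @param kk a [kk_params()].
#' @return List with `Jv` (m/s) and `Js` (m/s times concentration units).
#' @export
endothelial_flux <- function(tau, c_lumen, c_wall, kk = kk_params()) {
  stopifnot(all(tau >= 0))
  if (any(c_lumen < 0) || any(c_wall < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  p_tau <- kk$P0 * (1 + kk$a / (1 + kk$b * tau))
  jv <- kk$Lp * (kk$delta_p - kk$sigma_d * kk$delta_pi)
  js <- p_tau * (c_lumen - c_wall) + (1 - kk$sigma_f) * jv * (c_lumen + c_wall) / 2
  list(Jv = rep(jv, length.out = length(js)), Js = js)
}

WALL_SPECIES <- c("LDL_w", "HDL_w", "oxLDL", "monocytes", "macrophages",
                  "foam_cells", "cytokines", "SMC_contractile", "SMC_synthetic",
                  "collagen")

#' Plaque-growth model parameters
#'
#' Rate constants of the wall species cascade (time unit: days): LDL
#' oxidation damped by HDL, oxLDL-amplified monocyte recruitment, monocyte
#' differentiation into macrophages, oxLDL uptake producing foam cells,
#' cytokine production, contractile-to-synthetic smooth-muscle-cell (SMC)
#' conversion, and collagen synthesis. Plaque volume is the weighted sum of
#' foam cells, synthetic SMCs and collagen.
#'
#' @param k_ox LDL oxidation rate (1/day); effective rate is
#'   `k_ox / (1 + k_h * HDL_w)`.
#' @param k_h HDL damping of oxidation (1/a.u.).
#' @param k_m monocyte recruitment gain on oxLDL (1/a.u.).
#' @param k_dif monocyte-to-macrophage differentiation rate (1/day).
#' @param k_up oxLDL uptake rate by macrophages (1/(a.u. day)).
#' @param k_c cytokine production rate by macrophages (1/day).
#' @param k_s SMC phenotype conversion rate by cytokines (1/(a.u. day)).
#' @param k_g collagen production rate by synthetic SMCs (1/day).
#' @param d_L,d_H,d_ox,d_M,d_c,d_G first-order degradation rates (1/day).
#' @param w_F,w_S,w_G plaque-volume weights of foam cells, synthetic SMCs and
#'   collagen.
#' @param smc_c0 physiologic initial contractile SMC concentration (a.u.).
#' @param diseased_multiplier factor applied to `smc_c0` for a diseased wall
#'   (default 2).
#' @param remodeling_gain lumen-area loss (mm^2) per unit of per-station
#'   plaque volume when geometry feedback shrinks the lumen.
#' @param coupling_interval days between shear/flux/geometry updates.
#' @param dt integrator step, days.
#' @param t_end simulated horizon, days.
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(k_ox = 0.2, k_h = 1, k_m = 50, k_dif = 0.5, k_up = 1,
                          k_c = 0.1, k_s = 0.5, k_g = 0.1,
                          d_L = 0.02, d_H = 0.02, d_ox = 0.02, d_M = 0.01,
                          d_c = 0.2, d_G = 0.01,
                          w_F = 1, w_S = 1, w_G = 1,
                          smc_c0 = 0.02, diseased_multiplier = 2,
                          remodeling_gain = 1,
                          coupling_interval = 5, dt = 0.05, t_end = 30) {
  rates <- c(k_ox, k_h, k_m, k_dif, k_up, k_c, k_s, k_g,
             d_L, d_H, d_ox, d_M, d_c, d_G, w_F, w_S, w_G, smc_c0,
             diseased_multiplier, remodeling_gain)
  stopifnot(all(rates >= 0), dt > 0, t_end > 0, coupling_interval > 0)
  structure(mget(names(formals())), class = "growth_params")
}

# Right-hand side of the wall ODE system. `state` is a stations x 10 matrix
# with columns WALL_SPECIES; `influx` a stations x 3 matrix (LDL, HDL,
# monocytes) of endothelial solute flux already scaled by the station
# surface-to-volume ratio (a.u./day).
wall_derivs <- function(state, influx, p) {
  LDL <- state[, "LDL_w"]; HDL <- state[, "HDL_w"]; ox <- state[, "oxLDL"]
  mw <- state[, "monocytes"]; M <- state[, "macrophages"]
  cyt <- state[, "cytokines"]; Sc <- state[, "SMC_contractile"]
  Ss <- state[, "SMC_synthetic"]; G <- state[, "collagen"]
  ox_rate <- p$k_ox * LDL / (1 + p$k_h * HDL)
  cbind(
    LDL_w = influx[, 1] - ox_rate - p$d_L * LDL,
    HDL_w = influx[, 2] - p$d_H * HDL,
    oxLDL = ox_rate - p$k_up * ox * M - p$d_ox * ox,
    monocytes = influx[, 3] * (1 + p$k_m * ox) - p$k_dif * mw,
    macrophages = p$k_dif * mw - p$d_M * M,
    foam_cells = p$k_up * ox * M,
    cytokines = p$k_c * M - p$d_c * cyt,
    SMC_contractile = -p$k_s * cyt * Sc,
    SMC_synthetic = p$k_s * cyt * Sc,
    collagen = p$k_g * Ss - p$d_G * G
  )
}

#' Advance the wall species system by one time step
#'
#' One explicit step (classic fourth-order Runge-Kutta by default, forward
#' Euler optionally) of the wall ODE cascade, with all states clipped at
#' zero. A step that drives any state materially negative before clipping
#' raises a stability warning.
#'
#' @param state stations x 10 matrix with columns as in `WALL_SPECIES`, or a
#'   named length-10 vector for a single compartment.
#' @param influx stations x 3 matrix (columns LDL, HDL, monocytes) of
#'   surface-to-volume-scaled endothelial influx, a.u./day; held constant
#'   over the step.
#' @param params a [growth_params()].
#' @param dt step length in days (defaults to `params$dt`).
#' @param method `"rk4"` or `"euler"`.
#' @return Updated state in the same shape as the input.
#' @export
step_wall_odes <- function(state, influx, params, dt = params$dt,
                           method = c("rk4", "euler")) {
  method <- match.arg(method)
  vec_in <- is.null(dim(state))
  if (vec_in) state <- matrix(state, nrow = 1, dimnames = list(NULL, WALL_SPECIES))
  if (is.null(dim(influx))) influx <- matrix(influx, nrow = nrow(state), ncol = 3, byrow = TRUE)
  if (method == "euler") {
    out <- state + dt * wall_derivs(state, influx, params)
  } else {
    k1 <- wall_derivs(state, influx, params)
    k2 <- wall_derivs(pmax(state + dt / 2 * k1, 0), influx, params)
    k3 <- wall_derivs(pmax(state + dt / 2 * k2, 0), influx, params)
    k4 <- wall_derivs(pmax(state + dt * k3, 0), influx, params)
    out <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  if (any(out < -1e-8 * max(1, max(abs(state))))) {
    warning("integration step produced negative concentrations; dt may be too large",
            call. = FALSE)
  }
  out <- pmax(out, 0)
  if (vec_in) out[1, ] else out
}

#' Run the shear-coupled plaque-growth simulation
#'
#' Implements the causal chain under study: per-station shear stress (at
#' rest flow) sets the endothelial permeability, the Kedem-Katchalsky solute
#' flux feeds the wall species cascade, the accumulated foam-cell/SMC/
#' collagen plaque volume thickens the wall and narrows the lumen, and the
#' narrowed geometry feeds back into the shear field at every coupling
#' interval.
#'
#' @param vessel a [new_vessel_model()].
#' @param lumen_conc named vector of lumen-side concentrations (a.u.) for
#'   `LDL`, `HDL` and `monocytes`.
#' @param kk a [kk_params()].
#' @param params a [growth_params()].
#' @param cond [flow_conditions()] used for the shear field (rest flow).
#' @return A list of class `growth_result`: `times` (days), `trajectory`
#'   (list of per-station state matrices at coupling times), `final_state`,
#'   `plaque_volume` per station (`w_F F + w_S S_s + w_G G`),
#'   `plaque_volume_total`, `thickened_wall_area` per station (mm^2),
#'   `vessel_out` (regenerated geometry) and `status`
#'   (`"completed"` or `"lumen_closure"`).
#' @export
run_growth <- function(vessel, lumen_conc = c(LDL = 1, HDL = 1, monocytes = 1),
                       kk = kk_params(), params = growth_params(),
                       cond = flow_conditions()) {
  stopifnot(is_vessel_model(vessel), inherits(params, "growth_params"))
  v <- vessel
  n <- n_stations(v$lumen)
  state <- matrix(0, n, length(WALL_SPECIES), dimnames = list(NULL, WALL_SPECIES))
  state[, "SMC_contractile"] <- params$smc_c0 * params$diseased_multiplier
  t_grid <- seq(0, params$t_end, by = params$coupling_interval)
  if (t_grid[length(t_grid)] < params$t_end) t_grid <- c(t_grid, params$t_end)
  trajectory <- vector("list", length(t_grid))
  trajectory[[1]] <- state
  status <- "completed"
  comp_prev <- rep(0, n)
  for (k in seq_len(length(t_grid) - 1)) {
    prof <- axial_profile(v)
    tau <- compute_ess(prof, cond)$tau_Pa
    r_m <- prof$radius_mm * 1e-3
    R_m <- sqrt(stack_areas(v$outer_wall) / pi) * 1e-3
    sv <- 2 * r_m / (R_m^2 - r_m^2)                       # 1/m
    influx <- cbind(
      endothelial_flux(tau, lumen_conc[["LDL"]], state[, "LDL_w"], kk)$Js,
      endothelial_flux(tau, lumen_conc[["HDL"]], state[, "HDL_w"], kk)$Js,
      endothelial_flux(tau, lumen_conc[["monocytes"]], state[, "monocytes"], kk)$Js
    ) * sv * 86400                                        # a.u./day
    span <- t_grid[k + 1] - t_grid[k]
    n_steps <- max(1L, ceiling(span / params$dt))
    dt <- span / n_steps
    for (s in seq_len(n_steps)) {
      state <- step_wall_odes(state, influx, params, dt)
    }
    comp <- params$w_F * state[, "foam_cells"] +
      params$w_S * state[, "SMC_synthetic"] + params$w_G * state[, "collagen"]
    d_area <- params$remodeling_gain * (comp - comp_prev)  # mm^2 lumen loss
    comp_prev <- comp
    areas <- stack_areas(v$lumen)
    new_areas <- areas - d_area
    if (any(new_areas <= pi * 0.1^2)) {
      status <- "lumen_closure"
      trajectory[[k + 1]] <- state
      t_grid <- t_grid[seq_len(k + 1)]
      trajectory <- trajectory[seq_len(k + 1)]
      break
    }
    v$lumen <- new_contour_stack(
      mapply(function(ct, f) scale_contour(ct, f), v$lumen$contours,
             new_areas / areas, SIMPLIFY = FALSE),
      spacing = v$lumen$spacing)
    trajectory[[k + 1]] <- state
  }
  comp <- params$w_F * state[, "foam_cells"] +
    params$w_S * state[, "SMC_synthetic"] + params$w_G * state[, "collagen"]
  thick <- stack_areas(v$outer_wall) - stack_areas(v$lumen)
  structure(list(times = t_grid, trajectory = trajectory, final_state = state,
                 plaque_volume = comp, plaque_volume_total = sum(comp),
                 thickened_wall_area = thick, vessel_out = v, status = status,
                 params = params),
            class = "growth_result")
}

#' Summary statistics of the plaque-growth output variables
#'
#' Minimum, maximum, mean and standard deviation across stations of the
#' twelve reported variables: the ten wall species plus plaque volume and
#' thickened-wall area.
#'
#' @param result a [run_growth()] output.
#' @param sd_convention `"sample"` (divide by n-1) or `"population"`
#'   (divide by n).
#' @return Tibble with columns `variable, min, max, mean, sd` (12 rows).
#' @export
plaque_summary <- function(result, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  stopifnot(inherits(result, "growth_result"))
  vals <- cbind(result$final_state,
                plaque_volume = result$plaque_volume,
                thickened_wall_area = result$thickened_wall_area)
  sd_fun <- function(x) {
    s <- sd(x)
    if (sd_convention == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  tibble::tibble(
    variable = colnames(vals),
    min = apply(vals, 2, min),
    max = apply(vals, 2, max),
    mean = apply(vals, 2, mean),
    sd = apply(vals, 2, sd_fun)
  )
}
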