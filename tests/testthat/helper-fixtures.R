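# Shared fixtures, built in code.

regular_polygon <- function(n = 72, r = 1, center = c(0, 0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  new_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th),
                    center[3]))
}

unit_square <- function() {
  new_contour(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
}

straight_tube <- function(length = 10, radius = 1.5) {
  generate_vessel(vessel_recipe(length = length, base_radius = radius),
                  case_id = "tube")
}

stenosed_vessel <- function(severity = 0.6, length = 20) {
  generate_vessel(vessel_recipe(length = length, base_radius = 1.5,
                                stenoses = list(stenosis_spec(length / 2, 6, severity))),
                  case_id = "stenosed")
}

# exact-circle profile, bypassing polygonal discretisation
circle_profile <- function(radius = 1.5, length = 10, spacing = 0.5) {
  z <- seq(0, length, by = spacing)
  as_axial_profile(z, rep(pi * radius^2, length(z)))
}

stack_areas_of <- function(stack) vapply(stack$contours, contour_area, numeric(1))
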