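#' Recipe for a synthetic stenosed coronary segment
#'
#' Defines a straight or gently curved tube whose lumen area profile carries
#' Gaussian-shaped stenoses. Severity is defined on cross-sectional area
#' (clinical "% area stenosis"): a bump of severity 0.5 reduces the lumen
#' area at the throat to half the base area.
#'
#' @param length segment length in mm (default 20).
#' @param base_radius healthy lumen radius in mm (default 1.5, a typical
#'   proximal coronary lumen).
#' @param wall_thickness radial lumen-to-outer-wall offset in mm (default 0.5).
#' @param stenoses list of [stenosis_spec()] entries.
#' @param curvature centerline curvature in 1/mm (0 = straight tube).
#' @param points_per_contour vertices per ring (default 72).
#' @param spacing axial contour spacing in mm (default 0.5).
#' @param seed integer seed (reserved for randomized recipes; generation is
#'   deterministic given the recipe).
#' @return A list of class `vessel_recipe`.
#' @export
vessel_recipe <- function(length = 20, base_radius = 1.5, wall_thickness = 0.5,
                          stenoses = list(), curvature = 0,
                          points_per_contour = 72, spacing = 0.5, seed = 1L) {
  stopifnot(length > 0, base_radius > 0, wall_thickness > 0, spacing > 0,
            points_per_contour >= 3, curvature >= 0)
  if (!is.list(stenoses) || (length(stenoses) && is.numeric(stenoses[[1]]) &&
                             !is.list(stenoses[[1]]))) {
    if (!all(vapply(stenoses, is.list, TRUE))) {
      stop("stenoses must be a list of stenosis_spec() entries", call. = FALSE)
    }
  }
  structure(list(length = length, base_radius = base_radius,
                 wall_thickness = wall_thickness, stenoses = stenoses,
                 curvature = curvature, points_per_contour = points_per_contour,
                 spacing = spacing, seed = as.integer(seed)),
            class = "vessel_recipe")
}

#' @param center_position stenosis centre along the centerline, mm.
#' @param length_mm axial extent of the lesion, mm.
#' @param severity fraction of cross-sectional area lost at the throat, in [0, 1).
#' @rdname vessel_recipe
#' @export
stenosis_spec <- function(center_position, length_mm, severity) {
  stopifnot(severity >= 0, severity < 1, length_mm > 0)
  list(center_position = center_position, length_mm = length_mm, severity = severity)
}

# Lumen area multiplier 1 - sum of severity-shaped Gaussian bumps.
area_multiplier <- function(z, stenoses) {
  mult <- rep(1, length(z))
  for (s in stenoses) {
    sigma <- s$length_mm / 4  # lesion "length" spans about +/- 2 sigma
    mult <- mult - s$severity * exp(-(z - s$center_position)^2 / (2 * sigma^2))
  }
  mult
}

#' Generate a synthetic vessel model from a recipe
#'
#' The lumen radius profile is `base_radius * sqrt(area multiplier)` so each
#' stenosis reduces the throat *area* by its severity; the outer wall follows
#' the lumen at a constant radial offset. Contours are regular polygons.
#'
#' @param recipe a [vessel_recipe()].
#' @param case_id identifier for the resulting model.
#' @return An original-tagged [new_vessel_model()].
#' @export
generate_vessel <- function(recipe, case_id = "synthetic") {
  stopifnot(inherits(recipe, "vessel_recipe"))
  z <- seq(0, recipe$length, by = recipe$spacing)
  mult <- area_multiplier(z, recipe$stenoses)
  if (any(mult <= 0)) {
    stop("recipe error: overlapping stenoses drive the lumen area to zero", call. = FALSE)
  }
  r_lumen <- recipe$base_radius * sqrt(mult)
  r_wall <- r_lumen + recipe$wall_thickness
  m <- recipe$points_per_contour
  theta <- 2 * pi * (seq_len(m) - 1) / m
  ring <- function(radius, origin, e1, e2) {
    new_contour(sweep(outer(radius * cos(theta), e1) + outer(radius * sin(theta), e2),
                      2, origin, "+"))
  }
  frames <- centerline_frames(z, recipe$curvature)
  lumen <- vector("list", length(z))
  wall <- vector("list", length(z))
  for (i in seq_along(z)) {
    lumen[[i]] <- ring(r_lumen[i], frames$origin[i, ], frames$e1[i, ], frames$e2[i, ])
    wall[[i]] <- ring(r_wall[i], frames$origin[i, ], frames$e1[i, ], frames$e2[i, ])
  }
  new_vessel_model(case_id,
                   new_contour_stack(lumen, spacing = recipe$spacing),
                   new_contour_stack(wall, spacing = recipe$spacing),
                   tag = "original")
}

# Contour-plane frames along a straight (z axis) or circular-arc centerline.
# Arc-length parameterisation keeps consecutive origins `spacing` apart.
centerline_frames <- function(z, curvature) {
  n <- length(z)
  if (curvature == 0) {
    origin <- cbind(0, 0, z)
    e1 <- matrix(rep(c(1, 0, 0), each = n), n)
    e2 <- matrix(rep(c(0, 1, 0), each = n), n)
  } else {
    R <- 1 / curvature
    phi <- z / R
    origin <- cbind(R * (1 - cos(phi)), 0, R * sin(phi))
    e1 <- cbind(cos(phi), 0, -sin(phi))  # in-plane radial direction
    e2 <- matrix(rep(c(0, 1, 0), each = n), n)
  }
  list(origin = origin, e1 = e1, e2 = e2)
}

#' Generate a small synthetic study set of stenosed vessels
#'
#' Convenience wrapper drawing per-vessel stenosis severity, position and
#' length from the seed, emulating a mixed healthy/stenosed segment set.
#'
#' @param n number of vessels.
#' @param seed integer seed; vessels are deterministic given it.
#' @param length,base_radius passed to [vessel_recipe()].
#' @return List of original-tagged `vessel_model`s named `case_1 ...`.
#' @export
generate_vessel_set <- function(n, seed = 1L, length = 20, base_radius = 1.5) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sev <- runif(1, 0.2, 0.7)
      pos <- runif(1, 0.35, 0.65) * length
      len <- runif(1, 4, 8)
      generate_vessel(vessel_recipe(length = length, base_radius = base_radius,
                                    stenoses = list(stenosis_spec(pos, len, sev)),
                                    seed = child_seed(seed, i)),
                      case_id = sprintf("case_%d", i))
    })
  })
}
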