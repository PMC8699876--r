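#' Construct a closed planar contour
#'
#' A contour is an ordered closed ring of 3-D points (conventionally 72 per
#' contour) lying on, or close to, a plane. Contours are the primitive of the
#' point-cloud vessel representation: a vessel surface is a stack of such
#' rings spaced 0.5 mm apart along the centerline.
#'
#' @param points numeric matrix with one row per vertex and columns x, y, z
#'   (mm). The ring is implicitly closed: the last vertex connects back to the
#'   first; do not repeat the first vertex.
#' @return An object of class `contour`.
#' @examples
#' sq <- new_contour(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
#' contour_area(sq)
#' @export
new_contour <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3) {
    stop("contour points must be a numeric matrix with columns x, y, z", call. = FALSE)
  }
  if (nrow(points) < 3) {
    stop("invalid contour: fewer than 3 points", call. = FALSE)
  }
  if (!all(is.finite(points))) {
    stop("invalid contour: non-finite coordinates", call. = FALSE)
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points), class = "contour")
}

is_contour <- function(x) inherits(x, "contour")

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour: %d points, area %.4f mm^2>\n", nrow(x$points), contour_area(x)))
  invisible(x)
}

#' Vertex centroid of a contour
#'
#' The centroid is the arithmetic mean of the vertex positions (a point-cloud
#' centroid, exact for regular rings), not the enclosed-area centroid.
#'
#' @param contour a [new_contour()] object.
#' @return Numeric length-3 vector (x, y, z) in mm.
#' @export
contour_centroid <- function(contour) {
  stopifnot(is_contour(contour))
  colMeans(contour$points)
}

# Orthonormal in-plane basis (e1, e2) and unit normal of the best-fit plane
# through the ring, by SVD of the centred vertices.
plane_basis <- function(contour) {
  ctr <- contour_centroid(contour)
  centred <- sweep(contour$points, 2, ctr)
  sv <- svd(centred, nu = 0, nv = 3)
  list(origin = ctr, e1 = sv$v[, 1], e2 = sv$v[, 2], normal = sv$v[, 3],
       singular_values = sv$d)
}

# 2-D coordinates of the vertices in the best-fit plane (out-of-plane
# component discarded).
project_to_plane <- function(contour, basis = plane_basis(contour)) {
  centred <- sweep(contour$points, 2, basis$origin)
  cbind(u = centred %*% basis$e1, v = centred %*% basis$e2)
}

#' Enclosed area of a contour
#'
#' Shoelace area of the ring after projection onto its best-fit plane.
#'
#' @inheritParams contour_centroid
#' @return Area in mm^2 (strictly positive).
#' @export
contour_area <- function(contour) {
  stopifnot(is_contour(contour))
  uv <- project_to_plane(contour)
  n <- nrow(uv)
  nxt <- c(2:n, 1L)
  a <- abs(sum(uv[, 1] * uv[nxt, 2] - uv[nxt, 1] * uv[, 2])) / 2
  if (a <= 1e-12) {
    stop("invalid contour: degenerate (near-collinear) ring encloses no area", call. = FALSE)
  }
  a
}

#' Scale a contour to a target enclosed-area factor
#'
#' Implements the per-contour area-perturbation step: each vertex is moved
#' toward or away from the vertex centroid by the linear factor
#' `sqrt(area_factor)` (isotropic in-plane scaling is the unique similarity
#' achieving a prescribed area change), and the scaled ring is re-translated
#' so its centroid coincides with the original centroid. Out-of-plane jitter
#' is projected onto the best-fit plane before scaling.
#'
#' @inheritParams contour_centroid
#' @param area_factor positive scalar; the ratio of new to old enclosed area
#'   (e.g. 0.95 for a 5% area underestimation).
#' @return A new `contour` with `contour_area` equal to
#'   `area_factor * contour_area(contour)` and an unchanged centroid.
#' @export
scale_contour <- function(contour, area_factor) {
  stopifnot(is_contour(contour))
  if (!is.numeric(area_factor) || length(area_factor) != 1 || !is.finite(area_factor) ||
      area_factor <= 0) {
    stop("area_factor must be a positive finite scalar", call. = FALSE)
  }
  basis <- plane_basis(contour)
  uv <- project_to_plane(contour, basis)
  uv <- uv * sqrt(area_factor)
  pts <- sweep(uv[, 1, drop = FALSE] %*% t(basis$e1) +
               uv[, 2, drop = FALSE] %*% t(basis$e2), 2, basis$origin, "+")
  out <- new_contour(pts)
  # explicit re-centring (steps 3-6 of the procedure); numerically a no-op
  # for in-plane scaling about the centroid
  shift <- basis$origin - contour_centroid(out)
  out$points <- sweep(out$points, 2, shift, "+")
  out
}

#' Construct an axially ordered stack of contours
#'
#' @param contours list of [new_contour()] objects ordered proximal to distal.
#' @param spacing axial distance between consecutive contour planes in mm
#'   (default 0.5).
#' @return An object of class `contour_stack`.
#' @export
new_contour_stack <- function(contours, spacing = 0.5) {
  if (!is.list(contours) || length(contours) < 2 || !all(vapply(contours, is_contour, TRUE))) {
    stop("a contour stack needs a list of at least 2 contours", call. = FALSE)
  }
  if (!is.numeric(spacing) || spacing <= 0) {
    stop("spacing must be positive (mm)", call. = FALSE)
  }
  structure(list(contours = contours, spacing = spacing), class = "contour_stack")
}

is_contour_stack <- function(x) inherits(x, "contour_stack")

n_stations <- function(stack) length(stack$contours)

stack_areas <- function(stack) vapply(stack$contours, contour_area, numeric(1))

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack: %d contours, spacing %.3g mm, %d points each>\n",
              n_stations(x), x$spacing, nrow(x$contours[[1]]$points)))
  invisible(x)
}

#' Construct a two-surface vessel model
#'
#' A vessel model pairs a lumen contour stack with an outer-wall stack sharing
#' the same stations, tagged as the original reconstruction or as one of its
#' area-perturbed variants.
#'
#' @param case_id character identifier.
#' @param lumen,outer_wall [new_contour_stack()] objects with equal contour
#'   counts; the outer wall must enclose at least the lumen area at every
#'   station.
#' @param tag one of `"original"`, `"overestimated"`, `"underestimated"`.
#' @return An object of class `vessel_model`.
#' @export
new_vessel_model <- function(case_id, lumen, outer_wall,
                             tag = c("original", "overestimated", "underestimated")) {
  tag <- match.arg(tag)
  stopifnot(is_contour_stack(lumen), is_contour_stack(outer_wall))
  if (n_stations(lumen) != n_stations(outer_wall)) {
    stop("lumen and outer wall must have equal contour counts", call. = FALSE)
  }
  al <- stack_areas(lumen)
  aw <- stack_areas(outer_wall)
  if (any(aw < al - 1e-9)) {
    stop("outer-wall area is smaller than lumen area at some station", call. = FALSE)
  }
  structure(list(case_id = as.character(case_id), lumen = lumen,
                 outer_wall = outer_wall, tag = tag),
            class = "vessel_model")
}

is_vessel_model <- function(x) inherits(x, "vessel_model")

#' @export
print.vessel_model <- function(x, ...) {
  cat(sprintf("<vessel_model '%s' [%s]: %d stations, lumen area %.3f-%.3f mm^2>\n",
              x$case_id, x$tag, n_stations(x$lumen),
              min(stack_areas(x$lumen)), max(stack_areas(x$lumen))))
  invisible(x)
}

scale_stack <- function(stack, area_factor) {
  new_contour_stack(lapply(stack$contours, scale_contour, area_factor = area_factor),
                    spacing = stack$spacing)
}

#' Apply the area-perturbation procedure to a vessel
#'
#' Scales every lumen and outer-wall contour by the area factor `1 + error`
#' (overestimation) or `1 - error` (underestimation), preserving centroids,
#' contour count and axial spacing. Applying the study's 5% error in both
#' directions to each original vessel yields the original/over/under model
#' triplet (60 segments for a 20-vessel set).
#'
#' @param vessel an original-tagged [new_vessel_model()].
#' @param error area error fraction in (0, 1); default 0.05.
#' @param direction `"over"` or `"under"`.
#' @return A `vessel_model` tagged `"overestimated"` or `"underestimated"`.
#' @export
perturb_vessel <- function(vessel, error = 0.05, direction = c("over", "under")) {
  direction <- match.arg(direction)
  stopifnot(is_vessel_model(vessel))
  if (vessel$tag != "original") {
    stop("perturb_vessel expects an original-tagged vessel", call. = FALSE)
  }
  if (!is.numeric(error) || length(error) != 1 || error <= 0 || error >= 1) {
    stop("error must be a fraction in (0, 1)", call. = FALSE)
  }
  f <- if (direction == "over") 1 + error else 1 - error
  new_vessel_model(vessel$case_id,
                   scale_stack(vessel$lumen, f),
                   scale_stack(vessel$outer_wall, f),
                   tag = if (direction == "over") "overestimated" else "underestimated")
}

#' Original/overestimated/underestimated model triplet
#'
#' @inheritParams perturb_vessel
#' @return Named list `original`, `overestimated`, `underestimated`.
#' @export
vessel_triplet <- function(vessel, error = 0.05) {
  list(original = vessel,
       overestimated = perturb_vessel(vessel, error, "over"),
       underestimated = perturb_vessel(vessel, error, "under"))
}

#' Loft a triangle surface between consecutive contours
#'
#' Builds an open-ended tube: each quad between corresponding vertices of
#' consecutive contours is split into two triangles, so a stack of `n`
#' contours with `m` points each gives `n * m` vertices and
#' `2 * m * (n - 1)` triangles.
#'
#' @param stack a [new_contour_stack()] whose contours all share one point count.
#' @return A list of class `surface_mesh` with `vertices` (matrix, mm) and
#'   `triangles` (integer matrix of 1-based vertex index triples).
#' @export
loft_surface <- function(stack) {
  stopifnot(is_contour_stack(stack))
  m <- vapply(stack$contours, function(ct) nrow(ct$points), integer(1))
  if (length(unique(m)) != 1) {
    stop("lofting error: contours have mismatched point counts", call. = FALSE)
  }
  m <- m[1]
  n <- n_stations(stack)
  vertices <- do.call(rbind, lapply(stack$contours, function(ct) ct$points))
  tri <- matrix(0L, nrow = 2L * m * (n - 1L), ncol = 3)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    base0 <- (i - 1L) * m
    base1 <- i * m
    j <- seq_len(m)
    jn <- c(2:m, 1L)
    tri[k + j, ] <- cbind(base0 + j, base0 + jn, base1 + j)
    tri[k + m + j, ] <- cbind(base0 + jn, base1 + jn, base1 + j)
    k <- k + 2L * m
  }
  structure(list(vertices = vertices, triangles = tri), class = "surface_mesh")
}

mesh_area <- function(mesh) {
  v <- mesh$vertices
  t1 <- v[mesh$triangles[, 1], , drop = FALSE]
  t2 <- v[mesh$triangles[, 2], , drop = FALSE]
  t3 <- v[mesh$triangles[, 3], , drop = FALSE]
  a <- t2 - t1
  b <- t3 - t1
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}
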