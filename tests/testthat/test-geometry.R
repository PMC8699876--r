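test_that("contour centroid is the vertex mean and respects symmetry and translation", {
  expect_equal(contour_centroid(unit_square()), c(x = 0.5, y = 0.5, z = 0))
  expect_equal(contour_centroid(regular_polygon(72, 2, c(1, 1, 0))),
               c(x = 1, y = 1, z = 0), tolerance = 1e-12)
  ct <- regular_polygon(12, 1.3)
  v <- c(3.2, -1.1, 7.5)
  shifted <- new_contour(sweep(ct$points, 2, v, "+"))
  expect_equal(contour_centroid(shifted), contour_centroid(ct) + v)
  expect_error(new_contour(rbind(c(0, 0, 0), c(1, 0, 0))), "fewer than 3")
})

test_that("contour area matches closed forms and similarity scaling", {
  expect_equal(contour_area(unit_square()), 1)
  # closed form for a regular n-gon: (n/2) r^2 sin(2 pi / n)
  expect_equal(contour_area(regular_polygon(72, 1)), 36 * sin(2 * pi / 72),
               tolerance = 1e-12)
  ct <- regular_polygon(72, 2)
  scaled <- new_contour(sweep(sweep(ct$points, 2, contour_centroid(ct)) * 1.7,
                              2, contour_centroid(ct), "+"))
  expect_equal(contour_area(scaled) / contour_area(ct), 1.7^2, tolerance = 1e-12)
  expect_error(contour_area(new_contour(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))),
               "degenerate")
})

test_that("scale_contour hits the requested area factor and preserves the centroid", {
  cases <- list(unit_square(), regular_polygon(72, 1.4), regular_polygon(7, 0.8))
  for (ct in cases) {
    for (s in c(0.9, 0.95, 1, 1.05, 1.1)) {
      sc <- scale_contour(ct, s)
      expect_equal(contour_area(sc) / contour_area(ct), s, tolerance = 1e-9)
      expect_lt(sqrt(sum((contour_centroid(sc) - contour_centroid(ct))^2)), 1e-9)
      expect_identical(nrow(sc$points), nrow(ct$points))
    }
  }
  # vertex radii scale by sqrt(area factor)
  circ <- regular_polygon(72, 1)
  up <- scale_contour(circ, 1.05)
  expect_equal(sqrt(rowSums(up$points[, 1:2]^2)), rep(sqrt(1.05), 72),
               tolerance = 1e-12)
  expect_equal(scale_contour(circ, 1)$points, circ$points, tolerance = 1e-12)
  expect_error(scale_contour(circ, -0.1), "positive")
})

test_that("perturb_vessel scales both surfaces, preserves structure, and is asymmetric", {
  v <- stenosed_vessel()
  under <- perturb_vessel(v, 0.05, "under")
  over <- perturb_vessel(v, 0.05, "over")
  expect_identical(under$tag, "underestimated")
  expect_identical(over$tag, "overestimated")
  for (surf in c("lumen", "outer_wall")) {
    expect_equal(stack_areas_of(under[[surf]]), 0.95 * stack_areas_of(v[[surf]]),
                 tolerance = 1e-9)
    expect_equal(stack_areas_of(over[[surf]]), 1.05 * stack_areas_of(v[[surf]]),
                 tolerance = 1e-9)
  }
  expect_identical(under$lumen$spacing, v$lumen$spacing)
  # under-then-over at equal error is not the identity: 0.95 * 1.05 = 0.9975
  under$tag <- "original"  # re-tag to allow a second perturbation
  round_trip <- perturb_vessel(under, 0.05, "over")
  expect_equal(stack_areas_of(round_trip$lumen) / stack_areas_of(v$lumen),
               rep(0.9975, length(v$lumen$contours)), tolerance = 1e-9)
  expect_error(perturb_vessel(v, 1.2), "fraction")
  expect_error(perturb_vessel(over), "original")
})

test_that("a 20-vessel set yields 60 segments in triplets", {
  vessels <- generate_vessel_set(20, seed = 7, length = 10)
  models <- unlist(lapply(vessels, vessel_triplet), recursive = FALSE)
  expect_length(models, 60)
  expect_equal(sum(vapply(models, function(m) m$tag == "original", TRUE)), 20)
})

test_that("loft_surface builds the expected triangulation and approximates a cylinder", {
  v <- straight_tube(length = 0.5, radius = 1)  # 2 contours
  mesh <- loft_surface(v$lumen)
  expect_identical(nrow(mesh$vertices), 144L)
  expect_identical(nrow(mesh$triangles), 144L)
  expect_true(all(mesh$triangles >= 1 & mesh$triangles <= 144))
  tube <- straight_tube(length = 10, radius = 1.5)
  area <- coroprop:::mesh_area(loft_surface(tube$lumen))
  expect_lt(abs(area - 2 * pi * 1.5 * 10) / (2 * pi * 1.5 * 10), 0.01)
  # lofting a perturbed stack preserves topology
  pert <- perturb_vessel(tube, 0.05, "under")
  expect_identical(loft_surface(pert$lumen)$triangles, loft_surface(tube$lumen)$triangles)
  bad <- new_contour_stack(list(regular_polygon(72), regular_polygon(36, 1, c(0, 0, 0.5))))
  expect_error(loft_surface(bad), "mismatched")
})

test_that("vessel model invariants are enforced", {
  lum <- new_contour_stack(list(regular_polygon(72, 1.5),
                                regular_polygon(72, 1.5, c(0, 0, 0.5))))
  small_wall <- new_contour_stack(list(regular_polygon(72, 1.0),
                                       regular_polygon(72, 1.0, c(0, 0, 0.5))))
  expect_error(new_vessel_model("x", lum, small_wall), "outer-wall")
})
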