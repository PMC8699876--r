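#' Write a vessel model to the contour-stack CSV format
#'
#' One row per point with columns `case_id, surface, contour_index,
#' point_index, x_mm, y_mm, z_mm, tag, spacing_mm`. Coordinates are written
#' with 9 decimals, making the write/read round trip lossless to 1e-9 mm.
#'
#' @param vessel a [new_vessel_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vessel_csv <- function(vessel, path) {
  stopifnot(is_vessel_model(vessel))
  rows <- lapply(c(lumen = "lumen", wall = "wall"), function(surf) {
    stack <- if (surf == "lumen") vessel$lumen else vessel$outer_wall
    do.call(rbind, lapply(seq_along(stack$contours), function(i) {
      p <- stack$contours[[i]]$points
      data.frame(case_id = vessel$case_id, surface = surf,
                 contour_index = i, point_index = seq_len(nrow(p)),
                 x_mm = sprintf("%.9f", p[, 1]), y_mm = sprintf("%.9f", p[, 2]),
                 z_mm = sprintf("%.9f", p[, 3]), tag = vessel$tag,
                 spacing_mm = stack$spacing)
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_error <- function(path, line, msg) {
  stop(sprintf("parse error in '%s' at line %d: %s", path, line, msg), call. = FALSE)
}

#' Read a vessel model from the contour-stack CSV format
#'
#' Malformed rows raise an error naming the offending line.
#'
#' @param path file written by [write_vessel_csv()] (or conforming to its schema).
#' @return A [new_vessel_model()].
#' @export
read_vessel_csv <- function(path) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("parse error in '%s': %s", path,
                                                  conditionMessage(e)), call. = FALSE))
  needed <- c("case_id", "surface", "contour_index", "point_index",
              "x_mm", "y_mm", "z_mm")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    parse_error(path, 1L, paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  for (cc in c("x_mm", "y_mm", "z_mm")) {
    vals <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(vals))
    if (length(bad)) parse_error(path, bad[1] + 1L, sprintf("non-numeric %s", cc))
    df[[cc]] <- vals
  }
  bad_surface <- which(!df$surface %in% c("lumen", "wall"))
  if (length(bad_surface)) {
    parse_error(path, bad_surface[1] + 1L, sprintf("unknown surface '%s'", df$surface[bad_surface[1]]))
  }
  spacing <- if ("spacing_mm" %in% names(df)) as.numeric(df$spacing_mm[1]) else 0.5
  tag <- if ("tag" %in% names(df)) as.character(df$tag[1]) else "original"
  build <- function(surf) {
    sub <- df[df$surface == surf, ]
    if (!nrow(sub)) parse_error(path, 1L, sprintf("no '%s' rows", surf))
    new_contour_stack(lapply(split(sub, sub$contour_index), function(s) {
      s <- s[order(s$point_index), ]
      new_contour(as.matrix(s[, c("x_mm", "y_mm", "z_mm")]))
    }), spacing = spacing)
  }
  new_vessel_model(df$case_id[1], build("lumen"), build("wall"), tag = tag)
}

#' Write / read a vessel model as JSON
#'
#' Structured equivalent of the CSV schema, with full double precision.
#'
#' @inheritParams write_vessel_csv
#' @return `path` invisibly (write); a `vessel_model` (read).
#' @export
write_vessel_json <- function(vessel, path) {
  stopifnot(is_vessel_model(vessel))
  ser_stack <- function(stack) {
    list(spacing_mm = stack$spacing,
         contours = lapply(stack$contours, function(ct) unname(ct$points)))
  }
  obj <- list(case_id = vessel$case_id, tag = vessel$tag,
              lumen = ser_stack(vessel$lumen), outer_wall = ser_stack(vessel$outer_wall))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vessel_json
#' @export
read_vessel_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_stack <- function(s) {
    cts <- s$contours
    contours <- if (is.array(cts) && length(dim(cts)) == 3) {
      lapply(seq_len(dim(cts)[1]), function(i) new_contour(cts[i, , ]))
    } else {
      lapply(cts, function(m) new_contour(as.matrix(m)))
    }
    new_contour_stack(contours, spacing = s$spacing_mm)
  }
  new_vessel_model(obj$case_id, de_stack(obj$lumen), de_stack(obj$outer_wall),
                   tag = obj$tag)
}

#' Export a lofted surface mesh
#'
#' `write_mesh_obj()` writes Wavefront OBJ; `write_mesh_stl()` writes ASCII STL.
#'
#' @param mesh a `surface_mesh` from [loft_surface()].
#' @param path output file path.
#' @param name solid name for the STL header.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9f %.9f %.9f", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
write_mesh_stl <- function(mesh, path, name = "vessel") {
  v <- mesh$vertices
  tr <- mesh$triangles
  t1 <- v[tr[, 1], , drop = FALSE]
  t2 <- v[tr[, 2], , drop = FALSE]
  t3 <- v[tr[, 3], , drop = FALSE]
  a <- t2 - t1
  b <- t3 - t1
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  body <- sprintf(paste0("facet normal %.6e %.6e %.6e\n outer loop\n",
                         "  vertex %.6e %.6e %.6e\n  vertex %.6e %.6e %.6e\n",
                         "  vertex %.6e %.6e %.6e\n endloop\nendfacet"),
                  nrm[, 1], nrm[, 2], nrm[, 3],
                  t1[, 1], t1[, 2], t1[, 3], t2[, 1], t2[, 2], t2[, 3],
                  t3[, 1], t3[, 2], t3[, 3])
  writeLines(body, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Write / read a patient cohort table as CSV
#'
#' The set of error-injectable biohumoral columns travels with the table as
#' an attribute and is re-attached on read by intersecting with the standard
#' roster.
#'
#' @param table a cohort tibble (see [generate_cohort()]).
#' @param path file path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  attr(df, "biohumoral") <- intersect(biohumoral_roster(), names(df))
  df
}
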