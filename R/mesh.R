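#' Idealized cylindrical vessel mesh
#'
#' Builds a triangulated open cylinder (the lateral wall only) aligned with
#' the z axis, the idealized substrate on which analytic wall-shear fields
#' are generated. Two ports are attached: `in1` at z = 0 and `out` at
#' z = `length`. All coordinates are in millimetres.
#'
#' @param radius Inner radius (mm), > 0.
#' @param length Axial length (mm), > 0.
#' @param n_axial Number of axial rings (>= 2).
#' @param n_circ Number of circumferential points per ring (>= 3).
#'
#' @return An object of class `tube_mesh`: a list with `points` (n x 3 matrix,
#'   mm), `triangles` (m x 3 integer matrix, 1-based), `wall_normals`
#'   (n x 3, outward unit vectors), `axial_coordinate` (per-point z, mm),
#'   `radius`, `length`, and `ports` (list of port definitions with `name`,
#'   `point_ids`, `area` in mm^2 and outward unit `normal`).
#' @export
#' @examples
#' m <- make_tube_mesh(1.5, 20, 10, 16)
#' nrow(m$points)  # 160
make_tube_mesh <- function(radius, length, n_axial, n_circ) {
  if (!is.finite(radius) || radius <= 0) abort("`radius` must be > 0")
  if (!is.finite(length) || length <= 0) abort("`length` must be > 0")
  if (n_axial < 2) abort("`n_axial` must be >= 2")
  if (n_circ < 3) abort("`n_circ` must be >= 3")
  n_axial <- as.integer(n_axial); n_circ <- as.integer(n_circ)

  z <- seq(0, length, length.out = n_axial)
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  # point index = (ring - 1) * n_circ + j
  ct <- cos(theta); st <- sin(theta)
  points <- cbind(
    x = radius * rep(ct, times = n_axial),
    y = radius * rep(st, times = n_axial),
    z = rep(z, each = n_circ)
  )
  normals <- cbind(rep(ct, times = n_axial), rep(st, times = n_axial), 0)
  colnames(normals) <- c("x", "y", "z")

  # two triangles per quad between consecutive rings
  tri <- matrix(0L, nrow = 2L * (n_axial - 1L) * n_circ, ncol = 3L)
  k <- 1L
  for (i in seq_len(n_axial - 1L)) {
    base <- (i - 1L) * n_circ
    for (j in seq_len(n_circ)) {
      jn <- if (j == n_circ) 1L else j + 1L
      a <- base + j; b <- base + jn
      c2 <- base + n_circ + j; d <- base + n_circ + jn
      tri[k, ] <- c(a, b, d); k <- k + 1L
      tri[k, ] <- c(a, d, c2); k <- k + 1L
    }
  }

  area <- pi * radius^2
  ports <- list(
    in1 = list(name = "in1", point_ids = seq_len(n_circ), area = area,
               normal = c(0, 0, -1)),
    out = list(name = "out",
               point_ids = (n_axial - 1L) * n_circ + seq_len(n_circ),
               area = area, normal = c(0, 0, 1))
  )

  structure(
    list(points = points, triangles = tri, wall_normals = normals,
         axial_coordinate = points[, 3], radius = radius, length = length,
         ports = ports),
    class = "tube_mesh"
  )
}

#' @export
print.tube_mesh <- function(x, ...) {
  cat("<tube_mesh> ", nrow(x$points), " points, ", nrow(x$triangles),
      " triangles, R = ", x$radius, " mm, L = ", x$length, " mm, ports: ",
      paste(names(x$ports), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Total triangulated surface area of a mesh (mm^2)
#' @param mesh A `tube_mesh`.
#' @return Scalar area in mm^2.
#' @export
surface_area <- function(mesh) {
  p <- mesh$points; tr <- mesh$triangles
  a <- p[tr[, 2], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  b <- p[tr[, 3], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Standardize a geometry to a reference inner diameter
#'
#' Uniformly (isotropically) rescales a vessel geometry so that the inlet
#' inner diameter equals `target_diameter`. Feature extraction standardizes
#' all samples to the same 3 mm inner diameter so that geometric size does
#' not confound the hemodynamic comparison.
#'
#' @param mesh A `tube_mesh`.
#' @param target_diameter Target inner diameter in mm (default 3.0).
#' @return The rescaled `tube_mesh`, with attribute `"scale_factor"` holding
#'   the applied isotropic factor.
#' @export
#' @examples
#' m <- make_tube_mesh(2.5, 20, 5, 16)   # 5 mm diameter
#' m3 <- scale_to_reference_diameter(m)
#' 2 * m3$radius        # 3
#' attr(m3, "scale_factor")  # 0.6
scale_to_reference_diameter <- function(mesh, target_diameter = 3.0) {
  stopifnot(inherits(mesh, "tube_mesh"))
  d <- 2 * mesh$radius
  if (!is.finite(d) || d <= 0) abort("degenerate inlet cross-section")
  f <- target_diameter / d
  mesh$points <- mesh$points * f
  mesh$axial_coordinate <- mesh$axial_coordinate * f
  mesh$radius <- mesh$radius * f
  mesh$length <- mesh$length * f
  mesh$ports <- lapply(mesh$ports, function(p) {
    p$area <- p$area * f^2
    p
  })
  attr(mesh, "scale_factor") <- f
  mesh
}

#' Write a surface mesh (with optional point data) as legacy ASCII VTK
#'
#' Minimal plain-text export for visual inspection in ParaView-compatible
#' viewers. Only what inspection needs: points, triangles, and named scalar
#' point fields.
#'
#' @param mesh A `tube_mesh`.
#' @param path Output file path (conventionally `.vtk`).
#' @param point_data Optional named list of per-point numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk_surface <- function(mesh, path, point_data = NULL) {
  n <- nrow(mesh$points); m <- nrow(mesh$triangles)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "flowgrade surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  writeLines(apply(mesh$points, 1, paste, collapse = " "), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(t)
    paste(c(3L, t), collapse = " ")), con)
  if (!is.null(point_data) && length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], scientific = TRUE), con)
    }
  }
  invisible(path)
}
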