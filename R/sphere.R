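## Curved-membrane geometry: sphere fitting, offset surface meshes and
## membranogram-style density projection.

#' Least-squares sphere fit
#'
#' Algebraic (Coope) linear solve followed by geometric Gauss-Newton
#' refinement of the orthogonal residuals.  Works on partial coverage
#' (e.g. a spherical cap, the minicell situation).
#'
#' @param points n x 3 matrix of coordinates (Angstrom), n >= 10,
#'   non-coplanar.
#' @return list with \code{centre}, \code{radius} and \code{rms_residual}.
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 10) stop_param("need at least 10 points")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))$d
  if (sv[3] < 1e-8 * sv[1])
    stop("points are (near-)coplanar: sphere fit is degenerate",
         call. = FALSE)
  ## algebraic: |p|^2 = 2 p . c + (R^2 - |c|^2)
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  sol <- qr.solve(A, b)
  c0 <- sol[1:3]
  r0 <- sqrt(sol[4] + sum(c0^2))
  ## geometric refinement: minimise sum (|p - c| - R)^2
  cc <- c0
  for (it in 1:50) {
    d <- sqrt(rowSums(sweep(points, 2, cc)^2))
    R <- mean(d)
    ## fixed-point update: c = mean(p) + R * mean((c - p)/|c - p|)
    u <- sweep(matrix(cc, nrow(points), 3, byrow = TRUE) - points, 1, d, "/")
    cnew <- colMeans(points) + R * colMeans(u)
    if (sqrt(sum((cnew - cc)^2)) < 1e-10 * R) { cc <- cnew; break }
    cc <- cnew
  }
  d <- sqrt(rowSums(sweep(points, 2, cc)^2))
  R <- mean(d)
  list(centre = cc, radius = R, rms_residual = sqrt(mean((d - R)^2)))
}

#' Extract bright voxel coordinates from a volume
#'
#' Returns the physical coordinates of voxels above a density quantile,
#' optionally restricted to a z window -- the simple segmentation used to
#' collect membrane-shell points for sphere fitting (the membrane is the
#' densest shell; a z window excludes the equally dense baseplate layer).
#'
#' @param volume a \code{volume_density}.
#' @param quantile density quantile threshold (default 0.995).
#' @param z_range optional length-2 numeric: keep voxels with z inside.
#' @return n x 3 matrix of coordinates, Angstrom.
#' @export
bright_points <- function(volume, quantile = 0.995, z_range = NULL) {
  stopifnot(inherits(volume, "volume_density"))
  g <- volume$grid
  if (!is.null(z_range)) {
    zs <- volume$origin[3] + (seq_len(dim(g)[3]) - 1) * volume$voxel_size
    keepz <- zs >= z_range[1] & zs <= z_range[2]
    g[, , !keepz] <- -Inf
  }
  thr <- stats::quantile(g[is.finite(g)], quantile)
  idx <- which(g >= thr & is.finite(g), arr.ind = TRUE)
  sweep((idx - 1) * volume$voxel_size, 2, volume$origin, "+")
}

## Icosahedron subdivision sphere mesh (unit radius, centred at origin).
icosphere <- function(subdiv) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  list(vertices = v, triangles = f)
}

#' Build a triangulated offset surface beneath a fitted sphere
#'
#' Meshes the spherical surface at \code{radius - offset} (an icosphere
#' subdivided until the edge length is at or below \code{mesh_density}),
#' optionally restricted to a polar cap, with all vertex normals pointing
#' towards the sphere centre (inward, i.e. deeper into the cell).
#'
#' @param sphere list with \code{centre} and \code{radius} (e.g. from
#'   \code{\link{fit_sphere}}).
#' @param offset distance below the sphere surface, Angstrom (0 meshes
#'   the sphere itself); must be smaller than the radius.
#' @param mesh_density target edge length, Angstrom.
#' @param cap_angle polar half-angle in radians about the +z pole to keep
#'   (default pi: the whole sphere).
#' @return object of class \code{surface_mesh}: \code{vertices},
#'   \code{triangles}, \code{normals}.
#' @export
build_offset_surface <- function(sphere, offset = 0, mesh_density = 50,
                                 cap_angle = pi) {
  if (offset >= sphere$radius) stop_param("offset must be below the radius")
  r <- sphere$radius - offset
  ## icosahedron edge at unit radius is ~1.0515; each subdivision halves it
  subdiv <- max(0, ceiling(log2(1.0515 * r / mesh_density)))
  ico <- icosphere(subdiv)
  if (cap_angle < pi) {
    keep_v <- acos(pmin(pmax(ico$vertices[, 3], -1), 1)) <= cap_angle
    keep_f <- keep_v[ico$triangles[, 1]] & keep_v[ico$triangles[, 2]] &
              keep_v[ico$triangles[, 3]]
    old_idx <- which(keep_v)
    remap <- integer(nrow(ico$vertices)); remap[old_idx] <- seq_along(old_idx)
    ico$vertices <- ico$vertices[keep_v, , drop = FALSE]
    tri <- ico$triangles[keep_f, , drop = FALSE]
    ico$triangles <- matrix(remap[tri], ncol = 3)
  }
  vertices <- sweep(ico$vertices * r, 2, sphere$centre, "+")
  normals <- -ico$vertices                 # unit, towards the centre
  structure(list(vertices = vertices, triangles = ico$triangles,
                 normals = normals, sphere = sphere, offset = offset),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("Surface mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' Project volume density onto a surface mesh
#'
#' Samples the volume by trilinear interpolation at each mesh vertex
#' displaced by \code{normal_offset} along its normal (positive offsets
#' move along the normal direction, i.e. deeper for an inward-oriented
#' membrane mesh).  Sweeping \code{normal_offset} reproduces the
#' membranogram exploration of density at different depths beneath a
#' membrane.  Out-of-bounds vertices are masked, not zeroed.
#'
#' @param volume a \code{\link{volume_density}}.
#' @param mesh a \code{surface_mesh}.
#' @param normal_offset displacement along the vertex normals, Angstrom.
#' @return data frame with the sample positions, \code{value} (NA outside
#'   the volume) and logical \code{oob} mask.
#' @export
project_density <- function(volume, mesh, normal_offset = 0) {
  stopifnot(inherits(volume, "volume_density"),
            inherits(mesh, "surface_mesh"))
  p <- mesh$vertices + normal_offset * mesh$normals
  idx <- sweep(sweep(p, 2, volume$origin), 2, rep(volume$voxel_size, 3), "/") + 1
  val <- trilinear(volume$grid, idx[, 1], idx[, 2], idx[, 3])
  data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
             value = val, oob = is.na(val))
}

#' Flatten a spherical membranogram into a 2D density image
#'
#' Samples the volume on the offset sphere surface over a regular grid of
#' azimuthal-equidistant (flattened) coordinates about the +z pole --
#' the inverse of the projection used to wrap planar lattices onto a
#' sphere -- yielding an image directly comparable to planar baseplate
#' renders (pixel size in membrane arc length).
#'
#' @param volume a \code{volume_density}.
#' @param sphere list with \code{centre}, \code{radius}.
#' @param normal_offset depth below the sphere surface to sample, Angstrom.
#' @param pixel_size image pixel size, Angstrom of arc.
#' @param half_width half-extent of the flattened image, Angstrom.
#' @return a \code{\link{density_image}} (out-of-volume samples are 0 and
#'   reported via the \code{oob_fraction} attribute).
#' @export
flatten_membranogram <- function(volume, sphere, normal_offset,
                                 pixel_size, half_width) {
  stopifnot(inherits(volume, "volume_density"))
  uu <- seq(-half_width, half_width, by = pixel_size)
  U <- matrix(rep(uu, length(uu)), length(uu))
  V <- matrix(rep(uu, each = length(uu)), length(uu))
  rho <- sqrt(U^2 + V^2)
  th <- atan2(V, U)
  al <- rho / sphere$radius
  r <- sphere$radius - normal_offset
  px <- sphere$centre[1] + r * sin(al) * cos(th)
  py <- sphere$centre[2] + r * sin(al) * sin(th)
  pz <- sphere$centre[3] + r * cos(al)
  idx1 <- (px - volume$origin[1]) / volume$voxel_size + 1
  idx2 <- (py - volume$origin[2]) / volume$voxel_size + 1
  idx3 <- (pz - volume$origin[3]) / volume$voxel_size + 1
  val <- trilinear(volume$grid, as.numeric(idx1), as.numeric(idx2),
                   as.numeric(idx3))
  oob <- mean(is.na(val))
  val[is.na(val)] <- 0
  img <- density_image(matrix(val, nrow(U)), pixel_size,
                       origin = c(-half_width, -half_width))
  attr(img, "oob_fraction") <- oob
  img
}

#' Locate the baseplate layer by sweeping the projection offset
#'
#' Projects the volume at a range of depths below the fitted membrane
#' sphere and returns the offset with the highest mean projected density
#' -- the membranogram exploration used to find the kinase baseplate,
#' which appears as a density layer tens of nanometres beneath the
#' membrane shell.
#'
#' @param volume a \code{volume_density}.
#' @param sphere list with \code{centre}, \code{radius}.
#' @param offsets candidate depths, Angstrom (default 150 to 450 in
#'   voxel-size steps).
#' @param cap_angle polar half-angle of the evaluation cap, radians.
#' @return list with \code{offset} (best depth), and the swept
#'   \code{profile} data frame (offset, mean_density).
#' @export
find_baseplate_offset <- function(volume, sphere,
                                  offsets = seq(150, 450,
                                                by = volume$voxel_size / 2),
                                  cap_angle = 0.15) {
  mesh <- build_offset_surface(sphere, offset = 0,
                               mesh_density = 4 * volume$voxel_size,
                               cap_angle = cap_angle)
  prof <- vapply(offsets, function(o)
    mean(project_density(volume, mesh, o)$value, na.rm = TRUE), numeric(1))
  list(offset = offsets[which.max(prof)],
       profile = data.frame(offset = offsets, mean_density = prof))
}

#' Write a surface mesh as Wavefront OBJ
#'
#' @param mesh a \code{surface_mesh}.
#' @param path output file.
#' @param values optional per-vertex scalars written alongside as
#'   \code{<path>.csv}.
#' @export
write_mesh_obj <- function(mesh, path, values = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.4f %.4f %.4f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("vn %.6f %.6f %.6f", mesh$normals[, 1],
                     mesh$normals[, 2], mesh$normals[, 3]), con)
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     mesh$triangles[, 1], mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 2],
                     mesh$triangles[, 3], mesh$triangles[, 3]), con)
  if (!is.null(values))
    utils::write.csv(data.frame(vertex = seq_len(nrow(mesh$vertices)),
                                value = values),
                     paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
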