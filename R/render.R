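## 2D baseplate density rendering.

#' Rendering mass weights
#'
#' \code{render_weights_ring_layer} (the default) shows the baseplate
#' plane as seen in tomographic top views: receptor dimer tips and the
#' CheA.P5/CheW ring members at equal mass, with the CheA body (P4, P3),
#' which hangs beneath the ring layer, excluded.  With these weights the
#' rendered density of both architectures is exactly periodic with the
#' ring-lattice constant -- the hallmark honeycomb.
#'
#' \code{render_weights_chea} adds the CheA body and gives CheA.P5 extra
#' mass; this compositional contrast between CheA-containing and
#' CheW-only ring positions is what makes the p2 and p6 architectures
#' distinguishable by rotational self-similarity, and is the weighting
#' used by the symmetry-classification pipeline.
#'
#' @name render_weights
#' @export
render_weights_ring_layer <- c(MCP_DIMER = 1, CHEA_P5 = 1, CHEW_CORE = 1,
                               CHEW_FLANK = 1, CHEA_P4 = 0, CHEA_P3 = 0,
                               CHEA_LINKER_ANCHOR = 0, CHEA_ATP_SITE = 0)

#' @rdname render_weights
#' @export
render_weights_chea <- c(MCP_DIMER = 1, CHEA_P5 = 1.5, CHEW_CORE = 1,
                         CHEW_FLANK = 1, CHEA_P4 = 1, CHEA_P3 = 0.8,
                         CHEA_LINKER_ANCHOR = 0, CHEA_ATP_SITE = 0)

default_render_weights <- render_weights_ring_layer

#' Create a density image container
#'
#' @param grid numeric matrix (first index along x, second along y).
#' @param pixel_size pixel edge in Angstrom.
#' @param origin physical coordinate of the centre of pixel (1,1).
#' @return object of class \code{density_image}.
#' @export
density_image <- function(grid, pixel_size, origin = c(0, 0)) {
  if (pixel_size <= 0) stop_param("pixel_size must be positive")
  if (!all(is.finite(grid))) stop_param("density grid must be finite")
  structure(list(grid = grid, pixel_size = pixel_size, origin = origin),
            class = "density_image")
}

## physical coordinates -> continuous 1-based grid indices
img_index <- function(image, x, y) {
  list(ix = (x - image$origin[1]) / image$pixel_size + 1,
       iy = (y - image$origin[2]) / image$pixel_size + 1)
}

#' Render the baseplate of an array model as a 2D density image
#'
#' Sums normalised isotropic Gaussian splats at the in-plane (planar)
#' baseplate positions of the model's sites, with per-kind masses.  The
#' image integral (sum times pixel area) equals the total splatted mass
#' for a patch fully inside the frame.  Sphere-mapped models are rendered
#' in their flattened (azimuthal-equidistant) coordinates.
#'
#' @param model an \code{array_model}.
#' @param pixel_size pixel edge, Angstrom.
#' @param sigma Gaussian width, Angstrom.  A warning is raised when
#'   \code{pixel_size > sigma} (undersampling).
#' @param weights named vector of masses per component kind; kinds absent
#'   from the vector get zero mass.
#' @param margin empty border around the site bounding box, Angstrom.
#' @return a \code{\link{density_image}}.
#' @export
render_baseplate <- function(model, pixel_size = 2, sigma = 8,
                             weights = default_render_weights,
                             margin = 4 * sigma) {
  stopifnot(inherits(model, "array_model"))
  if (pixel_size <= 0 || sigma <= 0)
    stop_param("pixel_size and sigma must be positive")
  if (pixel_size > sigma)
    warning("pixel_size exceeds sigma: the rendering is undersampled")
  s <- model$sites
  w <- weights[s$kind]
  w[is.na(w)] <- 0
  keep <- w > 0
  s <- s[keep, , drop = FALSE]; w <- w[keep]
  if (nrow(s) == 0)
    return(density_image(matrix(0, 2, 2), pixel_size))
  x0 <- min(s$u) - margin; x1 <- max(s$u) + margin
  y0 <- min(s$v) - margin; y1 <- max(s$v) + margin
  nx <- ceiling((x1 - x0) / pixel_size) + 1
  ny <- ceiling((y1 - y0) / pixel_size) + 1
  grid <- matrix(0, nx, ny)
  hw <- ceiling(4 * sigma / pixel_size)
  norm <- 1 / (2 * pi * sigma^2)
  for (i in seq_len(nrow(s))) {
    cx <- (s$u[i] - x0) / pixel_size + 1
    cy <- (s$v[i] - y0) / pixel_size + 1
    ix <- max(1, floor(cx) - hw):min(nx, ceiling(cx) + hw)
    iy <- max(1, floor(cy) - hw):min(ny, ceiling(cy) + hw)
    dx2 <- ((ix - cx) * pixel_size)^2
    dy2 <- ((iy - cy) * pixel_size)^2
    grid[ix, iy] <- grid[ix, iy] +
      w[i] * norm * exp(-outer(dx2, dy2, "+") / (2 * sigma^2))
  }
  density_image(grid, pixel_size, origin = c(x0, y0))
}

#' @export
print.density_image <- function(x, ...) {
  cat("Density image ", nrow(x$grid), "x", ncol(x$grid), " pixels at ",
      x$pixel_size, " A/px\n", sep = "")
  invisible(x)
}

#' Plot a density image
#'
#' @param x a \code{density_image}.
#' @param ... passed to \code{graphics::image}.
#' @export
plot.density_image <- function(x, ...) {
  xs <- x$origin[1] + (seq_len(nrow(x$grid)) - 1) * x$pixel_size
  ys <- x$origin[2] + (seq_len(ncol(x$grid)) - 1) * x$pixel_size
  graphics::image(xs, ys, x$grid, asp = 1, col = grDevices::gray.colors(64),
                  xlab = "x (A)", ylab = "y (A)", ...)
  invisible(x)
}
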