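## Wallpaper-group tiling of CSU templates into p2 and p6 arrays.
##
## Both architectures decorate the same hexagonal lattice of six-membered
## baseplate rings (spacing a) and hence share the universal hexagonal
## receptor arrangement; they differ only in how CSUs are oriented:
##   * p6: three CSUs per unit cell at 0/120/240 degrees, sharing one
##     (A.P5/W)_3 ring; translation vectors of length a*sqrt(3), 60 degrees
##     apart.
##   * p2: one CSU per unit cell, all CSUs parallel; translation vectors are
##     the primitive ring-lattice vectors (length a, 60 degrees apart).

#' Lattice specification
#'
#' @param symmetry "p2" or "p6".
#' @param a lattice constant in Angstrom (default 126).
#' @param extent integer pair: number of unit cells along each lattice
#'   vector.
#' @param flank_occupancy_prob probability in \[0,1\] that each
#'   flanking-CheW slot is occupied.
#' @param seed integer seed for the keyed occupancy stream.
#' @return object of class \code{lattice_spec}.
#' @export
lattice_spec <- function(symmetry = c("p6", "p2"), a = 126,
                         extent = c(3, 3), flank_occupancy_prob = 1,
                         seed = 1L) {
  symmetry <- match.arg(tolower(symmetry[1]), c("p6", "p2"))
  if (a <= 0) stop_param("lattice constant must be positive")
  extent <- as.integer(extent)
  if (length(extent) != 2 || any(extent < 1))
    stop_param("extent must be a pair of positive integers")
  if (flank_occupancy_prob < 0 || flank_occupancy_prob > 1)
    stop_param("flank_occupancy_prob must lie in [0, 1]")
  structure(list(symmetry = symmetry, a = a, extent = extent,
                 flank_occupancy_prob = flank_occupancy_prob,
                 seed = as.integer(seed)),
            class = "lattice_spec")
}

## Primitive vectors of the ring-centre lattice in the CSU frame used by
## build_csu_template (rings of one CSU at (0, +/-a/2) and
## (+/-sqrt(3)a/2, 0)).
ring_lattice_vectors <- function(a) {
  cbind(u1 = c(0, a), u2 = c(sqrt(3) * a / 2, a / 2))
}

#' Build the three-CSU p6 unit cell
#'
#' Places three copies of the template at relative orientations 0, 120 and
#' 240 degrees so that their three intra-CSU (A.P5/W) pairs close one
#' six-membered ring at the cell origin.  Flanking slots are left vacant;
#' under tiling they surround the all-CheW ring centres.
#'
#' @param template a \code{csu_template} (without flanking CheW; occupancy
#'   is applied at tiling time).
#' @param a lattice constant, Angstrom.
#' @return object of class \code{unit_cell}.
#' @export
build_p6_unit_cell <- function(template, a = template$geometry$a) {
  if (a <= 0) stop_param("lattice constant must be positive")
  u <- ring_lattice_vectors(a)
  csus <- lapply(0:2, function(k) {
    th <- 2 * pi * k / 3
    tr <- -rot2(th) %*% c(0, a / 2)
    place_csu(template, th, as.numeric(tr), csu_id = k + 1L)
  })
  structure(list(csus = csus, orientations = 2 * pi * (0:2) / 3,
                 lattice_vectors = cbind(a1 = u[, 1] + u[, 2],
                                         a2 = 2 * u[, 2] - u[, 1]),
                 symmetry = "p6", a = a, template = template),
            class = "unit_cell")
}

#' Build the one-CSU p2 unit cell
#'
#' The p2 unit cell is the CSU itself; tiling it along the primitive
#' ring-lattice vectors yields parallel CheA stripes, and complete rings
#' form only when flanking-CheW slots are occupied.
#'
#' @inheritParams build_p6_unit_cell
#' @return object of class \code{unit_cell}.
#' @export
build_p2_unit_cell <- function(template, a = template$geometry$a) {
  if (a <= 0) stop_param("lattice constant must be positive")
  u <- ring_lattice_vectors(a)
  structure(list(csus = list(place_csu(template, 0, c(0, 0), 1L)),
                 orientations = 0,
                 lattice_vectors = u, symmetry = "p2", a = a,
                 template = template),
            class = "unit_cell")
}

#' Tile a unit cell into an array model
#'
#' Translates the unit cell by all integer combinations of its lattice
#' vectors within \code{spec$extent}, then fills flanking-CheW slots
#' independently with probability \code{spec$flank_occupancy_prob} using a
#' keyed pseudo-random stream (reproducible for a given seed, independent
#' of evaluation order).
#'
#' @param unit_cell a \code{unit_cell}.
#' @param spec a \code{\link{lattice_spec}} (its symmetry/a must match the
#'   cell).
#' @return object of class \code{array_model}: fields \code{sites},
#'   \code{registry}, \code{lattice_vectors}, \code{symmetry}, \code{a},
#'   \code{baseplate_z}, \code{surface} (NULL for planar models).
#' @export
tile <- function(unit_cell, spec) {
  stopifnot(inherits(unit_cell, "unit_cell"), inherits(spec, "lattice_spec"))
  A <- unit_cell$lattice_vectors
  n1 <- spec$extent[1]; n2 <- spec$extent[2]
  z <- -unit_cell$template$geometry$baseplate_z
  all_sites <- vector("list", n1 * n2 * length(unit_cell$csus))
  reg <- vector("list", length(all_sites))
  csu_id <- 0L
  k <- 0L
  for (i in seq_len(n1) - 1L) {
    for (j in seq_len(n2) - 1L) {
      tr <- A[, 1] * i + A[, 2] * j
      for (m in seq_along(unit_cell$csus)) {
        csu_id <- csu_id + 1L
        k <- k + 1L
        s <- unit_cell$csus[[m]]
        s$csu_id <- csu_id
        s$x <- s$x + tr[1]; s$y <- s$y + tr[2]
        s$u <- s$x; s$v <- s$y
        s$slot_x <- s$slot_x + tr[1]; s$slot_y <- s$slot_y + tr[2]
        s$ring_x <- s$ring_x + tr[1]; s$ring_y <- s$ring_y + tr[2]
        ## keyed flanking-CheW occupancy, one draw per (csu, tod)
        bare <- bare_receptors(s)
        occ_rows <- list()
        for (b in seq_len(nrow(bare))) {
          p <- key_runif(spec$seed, csu_id, bare$tod_id[b])
          if (p < spec$flank_occupancy_prob)
            occ_rows[[length(occ_rows) + 1]] <- flank_row_for(bare[b, ], z)
        }
        if (length(occ_rows)) s <- rbind(s, do.call(rbind, occ_rows))
        all_sites[[k]] <- s
        reg[[k]] <- data.frame(csu_id = csu_id, cell_i = i, cell_j = j,
                               motif_index = m,
                               orientation = unit_cell$orientations[m])
      }
    }
  }
  sites <- do.call(rbind, all_sites)
  sites$site_id <- seq_len(nrow(sites))
  rownames(sites) <- NULL
  structure(list(sites = sites, registry = do.call(rbind, reg),
                 lattice_vectors = A, symmetry = unit_cell$symmetry,
                 a = unit_cell$a,
                 baseplate_z = unit_cell$template$geometry$baseplate_z,
                 surface = NULL),
            class = "array_model")
}

#' Build a tiled array model in one call
#'
#' Convenience wrapper: constructs the template, the unit cell matching
#' \code{spec$symmetry}, and tiles it.
#'
#' @param spec a \code{\link{lattice_spec}}.
#' @param geometry optional \code{\link{csu_geometry}}; its lattice
#'   constant is overridden by \code{spec$a}.
#' @param sphere_radius if positive, the planar model is mapped onto a
#'   sphere of this radius with \code{\link{map_to_sphere}}.
#' @return an \code{array_model}.
#' @export
build_array <- function(spec, geometry = NULL, sphere_radius = 0) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (is.null(geometry)) geometry <- csu_geometry(a = spec$a)
  else if (abs(geometry$a - spec$a) > 1e-9)
    geometry <- csu_geometry(a = spec$a, baseplate_z = geometry$baseplate_z,
                             tod_radius = geometry$tod_radius)
  tmpl <- build_csu_template(geometry)
  cell <- if (spec$symmetry == "p6") build_p6_unit_cell(tmpl, spec$a)
          else build_p2_unit_cell(tmpl, spec$a)
  model <- tile(cell, spec)
  if (sphere_radius > 0) model <- map_to_sphere(model, sphere_radius)
  model
}

## CSU centres and dimer-axis orientations of a model (from the CheA.P3
## site, which sits on the C2 axis and carries the axis angle).
csu_centres <- function(model) {
  p3 <- model$sites[model$sites$kind == "CHEA_P3", , drop = FALSE]
  data.frame(csu_id = p3$csu_id, x = p3$u, y = p3$v, angle = p3$angle)
}

#' Recover the minimal translational repeating motif of a planar model
#'
#' Identifies translations that map the set of CSU centres and dimer-axis
#' orientation classes onto itself, Gauss-reduces them to a primitive pair,
#' and counts the distinct CSU residue classes modulo that translation
#' lattice.  For the p6 architecture this recovers 3 CSUs per cell, for p2
#' a single CSU, independent of any global rotation of the model.
#'
#' @param model a planar \code{array_model} with extent at least 3x3.
#' @param tol positional tolerance in Angstrom.
#' @return list with \code{motif_csu_count} and \code{lattice_vectors}
#'   (2x2 matrix, columns t1, t2).
#' @export
reduce_unit_cell <- function(model, tol = 1e-3) {
  stopifnot(inherits(model, "array_model"))
  cc <- csu_centres(model)
  n <- nrow(cc)
  if (n < 9) stop_param("need a model with at least 9 CSUs (extent >= 3x3)")
  pts <- cbind(cc$x, cc$y)
  ang <- cc$angle %% pi          # C2-symmetric CSU: axis defined mod 180 deg
  ## orientation classes
  cls <- integer(n); cls[1] <- 1L; ncls <- 1L
  reps <- ang[1]
  for (i in seq_len(n)[-1]) {
    d <- axis_angle_diff(rad2deg(ang[i]), rad2deg(reps))
    j <- which(d < 1)
    if (length(j)) cls[i] <- j[1]
    else { ncls <- ncls + 1L; reps <- c(reps, ang[i]); cls[i] <- ncls }
  }
  ## The translation lattice of the decorated pattern is generated by the
  ## difference vectors between same-orientation-class CSU centres: each
  ## orientation class is one coset of that lattice for both the p2 and p6
  ## architectures.  Take the two shortest non-collinear same-class
  ## differences and verify that every same-class difference (all classes)
  ## is an integer combination of them.
  diffs <- list()
  for (c in seq_len(ncls)) {
    idx <- which(cls == c)
    if (length(idx) < 2) next
    p <- pts[idx, , drop = FALSE]
    dd <- cbind(rep(p[, 1], each = nrow(p)) - p[, 1],
                rep(p[, 2], each = nrow(p)) - p[, 2])
    diffs[[c]] <- dd[rowSums(dd^2) > tol^2, , drop = FALSE]
  }
  ref_class <- cls[which.min(rowSums((pts - rep(colMeans(pts), each = n))^2))]
  cand <- diffs[[ref_class]]
  if (is.null(cand) || nrow(cand) < 2)
    stop("no translational periodicity found (aperiodic model?)",
         call. = FALSE)
  cand <- cand[order(rowSums(cand^2)), , drop = FALSE]
  all_diffs <- do.call(rbind, diffs)
  integral <- function(M) {
    co <- solve(M, t(all_diffs))
    all(abs(co - round(co)) < 1e-4)
  }
  M <- NULL
  for (i in seq_len(min(nrow(cand), 12L))) {
    t1 <- cand[i, ]
    for (j in seq_len(min(nrow(cand), 24L))) {
      t2 <- cand[j, ]
      crossz <- t1[1] * t2[2] - t1[2] * t2[1]
      if (abs(crossz) < tol * sqrt(sum(t2^2))) next
      Mij <- cbind(t1, t2)
      if (integral(Mij)) { M <- Mij; break }
    }
    if (!is.null(M)) break
  }
  if (is.null(M))
    stop("no translational periodicity found (aperiodic model?)",
         call. = FALSE)
  ## distinct residue classes of all CSU centres modulo the lattice
  fr <- solve(M, t(pts - rep(pts[1, ], each = n)))
  fr <- fr - floor(fr + 1e-9)
  fr[fr > 1 - 1e-6] <- 0
  fr2 <- t(fr)
  used <- rep(FALSE, n); k <- 0L
  for (i in seq_len(n)) {
    if (used[i]) next
    k <- k + 1L
    d <- pmin(abs(fr2[, 1] - fr2[i, 1]), 1 - abs(fr2[, 1] - fr2[i, 1])) +
         pmin(abs(fr2[, 2] - fr2[i, 2]), 1 - abs(fr2[, 2] - fr2[i, 2]))
    used[d < 1e-4] <- TRUE
  }
  list(motif_csu_count = k, lattice_vectors = M)
}

#' Map a planar array model onto a sphere
#'
#' Azimuthal-equidistant projection about the patch origin: a planar point
#' at in-plane radius rho maps to polar angle rho/radius on a sphere
#' tangent to the membrane plane at the origin (sphere centre at
#' (0, 0, -radius)).  Site depths below the membrane are preserved along
#' the local surface normal, and half-site bearings are rotated into the
#' local tangent frame.
#'
#' @param model planar \code{array_model}.
#' @param radius sphere radius in Angstrom; must exceed 10 lattice
#'   constants (small-distortion regime).
#' @return the sphere-mapped \code{array_model} (planar coordinates are
#'   retained in columns \code{u}, \code{v}).
#' @export
map_to_sphere <- function(model, radius) {
  stopifnot(inherits(model, "array_model"))
  if (!is.null(model$surface))
    stop_param("model is already sphere-mapped")
  if (radius <= 10 * model$a)
    stop_param("sphere radius must exceed 10 lattice constants (",
               10 * model$a, " A)")
  C <- c(0, 0, -radius)
  s <- model$sites
  ## centre the patch at the sphere's north pole
  shift <- c(mean(range(s$u)), mean(range(s$v)))
  s$u <- s$u - shift[1]; s$v <- s$v - shift[2]
  for (pref in c("slot_", "ring_")) {
    px <- paste0(pref, "x"); py <- paste0(pref, "y")
    s[[px]] <- s[[px]] - shift[1]
    s[[py]] <- s[[py]] - shift[2]
  }
  map_point <- function(u, v, depth) {
    rho <- sqrt(u^2 + v^2)
    th <- atan2(v, u)
    al <- rho / radius
    nrm <- cbind(sin(al) * cos(th), sin(al) * sin(th), cos(al))
    list(pos = cbind(C[1] + (radius - depth) * nrm[, 1],
                     C[2] + (radius - depth) * nrm[, 2],
                     C[3] + (radius - depth) * nrm[, 3]),
         normal = nrm, alpha = al, theta = th)
  }
  mp <- map_point(s$u, s$v, -s$z)
  ## rotate in-plane vectors into the local tangent frame: rotation by
  ## alpha about the axis perpendicular to the radial direction
  rot_vec <- function(bx, by, bz, al, th) {
    ok <- !is.na(bx)
    out <- cbind(bx, by, bz)
    if (!any(ok)) return(out)
    ax <- cbind(-sin(th[ok]), cos(th[ok]), 0)     # rotation axis
    vv <- cbind(bx[ok], by[ok], ifelse(is.na(bz[ok]), 0, bz[ok]))
    ca <- cos(al[ok]); sa <- sin(al[ok])
    dotav <- rowSums(ax * vv)
    crossav <- cbind(ax[, 2] * vv[, 3] - ax[, 3] * vv[, 2],
                     ax[, 3] * vv[, 1] - ax[, 1] * vv[, 3],
                     ax[, 1] * vv[, 2] - ax[, 2] * vv[, 1])
    rv <- vv * ca + crossav * sa + ax * dotav * (1 - ca)
    out[ok, ] <- rv
    out
  }
  b1 <- rot_vec(s$b1x, s$b1y, s$b1z, mp$alpha, mp$theta)
  b2 <- rot_vec(s$b2x, s$b2y, s$b2z, mp$alpha, mp$theta)
  s$x <- mp$pos[, 1]; s$y <- mp$pos[, 2]; s$z <- mp$pos[, 3]
  s$b1x <- b1[, 1]; s$b1y <- b1[, 2]; s$b1z <- b1[, 3]
  s$b2x <- b2[, 1]; s$b2y <- b2[, 2]; s$b2z <- b2[, 3]
  ok <- !is.na(s$slot_x)
  if (any(ok)) {
    mps <- map_point(s$slot_x[ok], s$slot_y[ok], rep(model$baseplate_z, sum(ok)))
    s$slot_x[ok] <- mps$pos[, 1]; s$slot_y[ok] <- mps$pos[, 2]
    s$slot_z[ok] <- mps$pos[, 3]
  }
  model$sites <- s
  model$surface <- list(centre = C, radius = radius)
  model
}

#' @export
print.array_model <- function(x, ...) {
  cat("Chemosensory array model (", x$symmetry, ")\n", sep = "")
  cat("  CSUs:", nrow(x$registry), " sites:", nrow(x$sites),
      " lattice constant:", x$a, "A\n")
  if (is.null(x$surface)) cat("  planar (membrane z = 0, baseplate z = -",
                              x$baseplate_z, " A)\n", sep = "")
  else cat("  sphere-mapped, radius", x$surface$radius, "A\n")
  invisible(x)
}

#' Plot the baseplate of an array model
#'
#' Draws the in-plane (planar) positions of baseplate sites, coloured by
#' component kind.
#'
#' @param x an \code{array_model}.
#' @param ... passed to \code{plot}.
#' @export
plot.array_model <- function(x, ...) {
  s <- x$sites
  cols <- c(MCP_DIMER = "firebrick", CHEA_P5 = "dodgerblue3",
            CHEW_CORE = "goldenrod2", CHEW_FLANK = "orange",
            CHEA_P4 = "skyblue", CHEA_P3 = "navy",
            CHEA_LINKER_ANCHOR = "grey60", CHEA_ATP_SITE = "purple")
  graphics::plot(s$u, s$v, col = cols[s$kind], pch = 19, cex = 0.6,
                 asp = 1, xlab = "x (A)", ylab = "y (A)", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   cex = 0.6, bg = "white")
  invisible(x)
}
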