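## Synthetic tomogram-like volume generation.
##
## Emulates the features of a minicell cryo-electron tomogram that the
## analysis stages consume: a Gaussian-profiled membrane shell (spherical
## cap or plane), receptor rods spanning membrane to baseplate, baseplate
## blobs at the lattice site positions, additive white Gaussian noise and
## an optional hard Fourier missing-wedge mask.  Relative component
## masses (membrane 3, rod 1 per length unit, baseplate 2) are fixed
## defaults recorded in the volume metadata.

#' Simulation specification
#'
#' @param lattice a \code{\link{lattice_spec}}.
#' @param sphere_radius membrane sphere radius, Angstrom; 0 for a planar
#'   membrane.
#' @param membrane_thickness full width of the membrane density profile,
#'   Angstrom.
#' @param baseplate_depth depth of the baseplate beneath the membrane,
#'   Angstrom (default 300, i.e. 30 nm).
#' @param receptor_rod_density rod mass per Angstrom of length.
#' @param noise_sigma additive white-noise sd relative to the signal RMS.
#' @param wedge_half_angle missing-wedge half angle, degrees in \[0, 90);
#'   0 disables the mask.
#' @param voxel_size cubic voxel edge, Angstrom.
#' @param seed integer seed (noise stream; the lattice uses
#'   \code{lattice$seed}).
#' @return object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(lattice = lattice_spec(), sphere_radius = 0,
                            membrane_thickness = 50, baseplate_depth = 300,
                            receptor_rod_density = 0.02, noise_sigma = 0,
                            wedge_half_angle = 0, voxel_size = 8,
                            seed = 1L) {
  if (wedge_half_angle < 0 || wedge_half_angle >= 90)
    stop_param("wedge_half_angle must lie in [0, 90)")
  if (voxel_size <= 0 || membrane_thickness <= 0 || baseplate_depth <= 0)
    stop_param("lengths must be positive")
  if (noise_sigma < 0) stop_param("noise_sigma must be non-negative")
  structure(list(lattice = lattice, sphere_radius = sphere_radius,
                 membrane_thickness = membrane_thickness,
                 baseplate_depth = baseplate_depth,
                 receptor_rod_density = receptor_rod_density,
                 noise_sigma = noise_sigma,
                 wedge_half_angle = wedge_half_angle,
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "simulation_spec")
}

## splat isotropic 3D Gaussians into a grid (positions in voxel index
## space, 1-based); modifies and returns the grid
splat3 <- function(grid, pos, mass, sigma_vox) {
  d <- dim(grid)
  hw <- ceiling(3 * sigma_vox)
  for (i in seq_len(nrow(pos))) {
    c1 <- pos[i, 1]; c2 <- pos[i, 2]; c3 <- pos[i, 3]
    lo <- c(max(1, floor(c1) - hw), max(1, floor(c2) - hw),
            max(1, floor(c3) - hw))
    hi <- c(min(d[1], ceiling(c1) + hw), min(d[2], ceiling(c2) + hw),
            min(d[3], ceiling(c3) + hw))
    if (any(lo > hi)) next                 # splat entirely outside
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    gx <- exp(-(ix - c1)^2 / (2 * sigma_vox^2))
    gy <- exp(-(iy - c2)^2 / (2 * sigma_vox^2))
    gz <- exp(-(iz - c3)^2 / (2 * sigma_vox^2))
    add <- mass[i] * outer(outer(gx, gy), gz)
    grid[ix, iy, iz] <- grid[ix, iy, iz] + as.numeric(add)
  }
  grid
}

#' Apply a hard Fourier missing-wedge mask
#'
#' Zeroes Fourier components whose out-of-plane angle (from the xy plane
#' towards the z axis, the optical axis) exceeds 90 - wedge_half_angle
#' degrees, the unsampled region of a limited-tilt series.  The
#' zero-frequency component is always kept, so the volume mean is
#' preserved.
#'
#' @param volume a \code{volume_density}.
#' @param wedge_half_angle degrees in \[0, 90).
#' @return the masked \code{volume_density}.
#' @export
apply_missing_wedge <- function(volume, wedge_half_angle) {
  if (wedge_half_angle <= 0) return(volume)
  d <- dim(volume$grid)
  fr <- function(n) c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
  kx <- fr(d[1]); ky <- fr(d[2]); kz <- fr(d[3])
  KX <- array(rep(kx, times = d[2] * d[3]), d)
  KY <- array(rep(rep(ky, each = d[1]), times = d[3]), d)
  KZ <- array(rep(kz, each = d[1] * d[2]), d)
  kxy <- sqrt(KX^2 + KY^2)
  ang <- atan2(abs(KZ), kxy)               # 0 in-plane, pi/2 on z axis
  keep <- ang <= deg2rad(90 - wedge_half_angle)
  keep[1, 1, 1] <- TRUE
  F <- stats::fft(volume$grid)
  volume$grid <- Re(stats::fft(F * keep, inverse = TRUE)) / prod(d)
  volume
}

#' Simulate a tomogram-like volume of a chemosensory array
#'
#' Builds the lattice model requested by \code{spec$lattice} (planar or
#' wrapped onto a sphere), renders membrane shell, receptor rods and
#' baseplate blobs into a voxel grid, adds seeded white Gaussian noise
#' scaled to the signal RMS, and finally applies the missing-wedge mask.
#' Deterministic for a given spec and seed.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param margin empty border around the structure, Angstrom.
#' @return a \code{\link{volume_density}}; the generating parameters are
#'   attached as attribute \code{sim_spec}, and the underlying model as
#'   attribute \code{model}.
#' @export
simulate_volume <- function(spec, margin = 40) {
  stopifnot(inherits(spec, "simulation_spec"))
  geometry <- csu_geometry(a = spec$lattice$a,
                           baseplate_z = spec$baseplate_depth)
  model <- build_array(spec$lattice, geometry = geometry,
                       sphere_radius = spec$sphere_radius)
  s <- model$sites
  vx <- spec$voxel_size
  ## membrane attachment point above each receptor tip (rod top)
  rod_top <- function(tip) {
    if (spec$sphere_radius > 0) {
      C <- c(0, 0, -spec$sphere_radius)
      u <- (tip - C) / sqrt(sum((tip - C)^2))
      C + spec$sphere_radius * u
    } else c(tip[1], tip[2], 0)
  }
  mcp <- s[s$kind == "MCP_DIMER", , drop = FALSE]
  tops <- t(vapply(seq_len(nrow(mcp)),
                   function(i) rod_top(c(mcp$x[i], mcp$y[i], mcp$z[i])),
                   numeric(3)))
  ## bounds: membrane (z near 0) down to baseplate, covering the rod tops
  x0 <- min(s$x, tops[, 1]) - margin; x1 <- max(s$x, tops[, 1]) + margin
  y0 <- min(s$y, tops[, 2]) - margin; y1 <- max(s$y, tops[, 2]) + margin
  z0 <- min(s$z) - margin; z1 <- margin + spec$membrane_thickness
  d <- c(ceiling((x1 - x0) / vx), ceiling((y1 - y0) / vx),
         ceiling((z1 - z0) / vx)) + 1
  origin <- c(x0, y0, z0)
  grid <- array(0, d)
  ## membrane shell: Gaussian profile of the distance to the surface
  sig_m <- spec$membrane_thickness / (2 * sqrt(2 * log(2)))
  xs <- x0 + (seq_len(d[1]) - 1) * vx
  ys <- y0 + (seq_len(d[2]) - 1) * vx
  zs <- z0 + (seq_len(d[3]) - 1) * vx
  if (spec$sphere_radius > 0) {
    C <- c(0, 0, -spec$sphere_radius)
    ## restrict to the cap above the patch: polar angle of the patch
    max_rho <- max(sqrt(s$u^2 + s$v^2)) + margin
    cap_al <- max_rho / spec$sphere_radius
    for (k in seq_len(d[3])) {
      dz2 <- (zs[k] - C[3])^2
      rr <- sqrt(outer((xs - C[1])^2, (ys - C[2])^2, "+") + dz2)
      dist <- rr - spec$sphere_radius
      ## polar angle of each voxel w.r.t. +z pole
      cosal <- (zs[k] - C[3]) / rr
      inside_cap <- cosal >= cos(cap_al)
      grid[, , k] <- grid[, , k] +
        3 * exp(-dist^2 / (2 * sig_m^2)) * inside_cap
    }
  } else {
    prof <- 3 * exp(-(zs - 0)^2 / (2 * sig_m^2))
    for (k in seq_len(d[3])) grid[, , k] <- grid[, , k] + prof[k]
  }
  ## receptor rods: from the membrane attachment above each receptor tip
  ## down to the tip, sampled at one-voxel steps
  if (nrow(mcp)) {
    rod_pts <- list()
    for (i in seq_len(nrow(mcp))) {
      tip <- c(mcp$x[i], mcp$y[i], mcp$z[i])
      top <- tops[i, ]
      len <- sqrt(sum((top - tip)^2))
      nstep <- max(2, ceiling(len / vx))
      tt <- seq(0, 1, length.out = nstep)
      pts <- cbind(tip[1] + tt * (top[1] - tip[1]),
                   tip[2] + tt * (top[2] - tip[2]),
                   tip[3] + tt * (top[3] - tip[3]))
      rod_pts[[i]] <- cbind(pts, spec$receptor_rod_density * len / nstep)
    }
    rp <- do.call(rbind, rod_pts)
    idx <- cbind((rp[, 1] - origin[1]) / vx + 1,
                 (rp[, 2] - origin[2]) / vx + 1,
                 (rp[, 3] - origin[3]) / vx + 1)
    grid <- splat3(grid, idx, rp[, 4], sigma_vox = 8 / vx)
  }
  ## baseplate blobs, CheA-contrasted masses scaled so the strongest blob
  ## peaks at amplitude 2, below the membrane shell's 3 (the membrane is
  ## always the densest feature of the volume)
  w <- render_weights_chea[s$kind] * (2 / max(render_weights_chea))
  w[is.na(w)] <- 0
  bp <- s[w > 0, , drop = FALSE]
  idx <- cbind((bp$x - origin[1]) / vx + 1,
               (bp$y - origin[2]) / vx + 1,
               (bp$z - origin[3]) / vx + 1)
  grid <- splat3(grid, idx, w[w > 0], sigma_vox = 10 / vx)
  ## noise, then missing wedge
  if (spec$noise_sigma > 0) {
    rms <- sqrt(mean(grid^2))
    set.seed(derive_seed(spec$seed, "volume-noise"))
    grid <- grid + stats::rnorm(length(grid), 0, spec$noise_sigma * rms)
  }
  vol <- volume_density(grid, vx, origin)
  if (spec$wedge_half_angle > 0)
    vol <- apply_missing_wedge(vol, spec$wedge_half_angle)
  attr(vol, "sim_spec") <- spec
  attr(vol, "model") <- model
  vol
}

#' Generate the documented fixture suite
#'
#' Writes planar p2/p6 models (3x3 and 6x6, as pseudo-atom PDB with JSON
#' sidecars), a flanking-CheW occupancy sweep (0, 0.5, 1), one spherical
#' volume per symmetry and a noise ladder, plus a manifest with MD5
#' checksums.  Deterministic for a given seed.
#'
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @param sphere_radius radius for the spherical volumes, Angstrom.
#' @return the manifest data frame (file, kind, md5), invisibly written
#'   to \code{manifest.csv}.
#' @export
make_fixture_suite <- function(seed, outdir, sphere_radius = 1530) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  kinds <- character()
  add <- function(path, kind) {
    files[[length(files) + 1]] <<- path
    kinds[[length(kinds) + 1]] <<- kind
  }
  for (sym in c("p2", "p6")) {
    for (ext in c(3, 6)) {
      m <- build_array(lattice_spec(sym, extent = c(ext, ext),
                                    flank_occupancy_prob = 1, seed = seed))
      p <- file.path(outdir, sprintf("model_%s_%dx%d.pdb", sym, ext, ext))
      write_model_pdb(m, p)
      add(p, paste0("model_", sym))
      add(paste0(p, ".json"), "model_sidecar")
    }
  }
  for (occ in c(0, 0.5, 1)) {
    m <- build_array(lattice_spec("p2", extent = c(4, 4),
                                  flank_occupancy_prob = occ, seed = seed))
    p <- file.path(outdir, sprintf("model_p2_occ%03d.pdb", round(100 * occ)))
    write_model_pdb(m, p)
    add(p, "occupancy_sweep")
    add(paste0(p, ".json"), "model_sidecar")
  }
  for (sym in c("p2", "p6")) {
    ext <- if (sym == "p6") c(2, 2) else c(3, 3)
    sp <- simulation_spec(lattice_spec(sym, extent = ext, seed = seed),
                          sphere_radius = sphere_radius, voxel_size = 10,
                          seed = seed)
    p <- file.path(outdir, sprintf("volume_%s_sphere.mrc", sym))
    write_volume(simulate_volume(sp), p)
    add(p, paste0("volume_", sym))
  }
  for (ns in c(0, 0.5, 1, 2)) {
    sp <- simulation_spec(lattice_spec("p2", extent = c(3, 3), seed = seed),
                          noise_sigma = ns, voxel_size = 10, seed = seed)
    p <- file.path(outdir, sprintf("volume_p2_noise%03d.mrc",
                                   round(100 * ns)))
    write_volume(simulate_volume(sp), p)
    add(p, "noise_ladder")
  }
  manifest <- data.frame(file = basename(unlist(files)),
                         kind = unlist(kinds),
                         md5 = unname(tools::md5sum(unlist(files))))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
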