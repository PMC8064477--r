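sphere_cloud <- function(n, radius, centre, sigma, seed,
                         hemisphere = FALSE) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), n)
  u <- u / sqrt(rowSums(u^2))
  if (hemisphere) u[, 3] <- abs(u[, 3])
  sweep(u * radius, 2, centre, "+") + matrix(rnorm(3 * n, 0, sigma), n)
}

test_that("sphere fitting recovers radius exactly, under noise and on a hemisphere", {
  pts <- sphere_cloud(200, 1530, c(5, -7, 11), sigma = 0, seed = 1)
  f <- fit_sphere(pts)
  expect_equal(f$radius, 1530, tolerance = 1e-6)
  expect_equal(as.numeric(f$centre), c(5, -7, 11), tolerance = 1e-3)
  expect_lt(f$rms_residual, 1e-6)

  fn <- fit_sphere(sphere_cloud(500, 1530, c(0, 0, 0), 10, seed = 2))
  expect_equal(fn$radius, 1530, tolerance = 0.01)

  fh <- fit_sphere(sphere_cloud(500, 1530, c(0, 0, 0), 10, seed = 3,
                                hemisphere = TRUE))
  expect_equal(fh$radius, 1530, tolerance = 0.02)
})

test_that("degenerate point sets are rejected", {
  set.seed(1)
  flat <- cbind(rnorm(50), rnorm(50), 0)
  expect_error(fit_sphere(flat), "coplanar")
  expect_error(fit_sphere(flat[1:5, ]), "at least 10")
})

test_that("offset surfaces sit at the right radius with inward normals and bounded edges", {
  sph <- list(centre = c(10, -20, 30), radius = 1530)
  mesh <- build_offset_surface(sph, offset = 0, mesh_density = 80,
                               cap_angle = pi / 3)
  r <- sqrt(rowSums(sweep(mesh$vertices, 2, sph$centre)^2))
  expect_lt(max(abs(r - 1530)), 1e-6)
  ## normals point towards the centre
  radial <- sweep(mesh$vertices, 2, sph$centre)
  expect_true(all(rowSums(radial * mesh$normals) < 0))
  ## edge lengths within a factor 2 of the requested density
  tri <- mesh$triangles
  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  el <- sqrt(rowSums((mesh$vertices[edges[, 1], ] -
                      mesh$vertices[edges[, 2], ])^2))
  expect_lt(max(el), 2 * 80)
  expect_gt(min(el), 80 / 4)
  ## offset moves the surface inward
  mesh3 <- build_offset_surface(sph, offset = 300, mesh_density = 80,
                                cap_angle = pi / 3)
  r3 <- sqrt(rowSums(sweep(mesh3$vertices, 2, sph$centre)^2))
  expect_lt(max(abs(r3 - 1230)), 1e-6)
  expect_error(build_offset_surface(sph, offset = 2000), "radius")
})

test_that("projection returns constants on uniform volumes and masks out-of-bounds", {
  vol <- volume_density(array(3.7, c(30, 30, 30)), 10)
  sph <- list(centre = c(150, 150, 150), radius = 100)
  mesh <- build_offset_surface(sph, offset = 0, mesh_density = 30)
  pr <- project_density(vol, mesh, 0)
  expect_true(all(abs(pr$value[!pr$oob] - 3.7) < 1e-9))
  ## push the sampling surface outside: everything masked, nothing zeroed
  pr_out <- project_density(vol, mesh, -500)
  expect_true(all(pr_out$oob))
  expect_true(all(is.na(pr_out$value)))
})

test_that("the membranogram sweep finds the membrane and the baseplate layers", {
  sp <- simulation_spec(lattice_spec("p2", extent = c(3, 3), seed = 2),
                        sphere_radius = 1530, voxel_size = 8, seed = 2)
  vol <- cached("vol_p2_sphere_33", simulate_volume(sp))
  sph <- list(centre = c(0, 0, -1530), radius = 1530)
  mesh <- build_offset_surface(sph, offset = 0, mesh_density = 30,
                               cap_angle = 0.12)
  mem <- mean(project_density(vol, mesh, 0)$value, na.rm = TRUE)
  base <- mean(project_density(vol, mesh, 300)$value, na.rm = TRUE)
  above <- mean(project_density(vol, mesh, 250)$value, na.rm = TRUE)
  below <- mean(project_density(vol, mesh, 350)$value, na.rm = TRUE)
  expect_gt(mem, base)            # membrane shell dominates
  expect_gt(base, above)          # baseplate layer is a local maximum
  expect_gt(base, below)
  bo <- find_baseplate_offset(vol, sph, offsets = seq(200, 400, 10))
  expect_lt(abs(bo$offset - 300), 11)
})

test_that("template matching finds itself and separated copies", {
  tm <- array(0, c(9, 9, 9))
  tm[5, 5, 5] <- 2; tm[3, 5, 5] <- 1; tm[5, 7, 5] <- 1.5
  tmv <- volume_density(tm, 4)
  vol <- array(0, c(40, 40, 40))
  vol[10:18, 12:20, 8:16] <- tm
  vol[26:34, 24:32, 22:30] <- tm
  pk <- template_match(volume_density(vol, 4), tmv, angular_step = 360,
                       threshold = 0.9)
  expect_equal(nrow(pk), 2)
  expect_true(all(pk$score > 0.99))
  centres <- pk[order(pk$x), ]
  expect_equal(centres$x, c(13, 29) * 4, tolerance = 1e-6)
})

test_that("template peaks in a minicell volume form a layer at the baseplate depth", {
  ## template: the baseplate neighbourhood of one ring, cropped from a
  ## small planar simulation
  spt <- simulation_spec(lattice_spec("p2", extent = c(2, 2), seed = 2),
                         voxel_size = 8, seed = 2)
  vt <- simulate_volume(spt)
  mt <- attr(vt, "model")
  rc <- c(mt$sites$ring_x[1], mt$sites$ring_y[1])
  i0 <- round((rc[1] - vt$origin[1]) / 8) + 1
  j0 <- round((rc[2] - vt$origin[2]) / 8) + 1
  k0 <- round((-300 - vt$origin[3]) / 8) + 1
  tmpl <- volume_density(vt$grid[(i0 - 7):(i0 + 7), (j0 - 7):(j0 + 7),
                                 (k0 - 5):(k0 + 5)], 8)
  sp <- simulation_spec(lattice_spec("p2", extent = c(3, 3), seed = 2),
                        sphere_radius = 1530, voxel_size = 8, seed = 2)
  vol <- cached("vol_p2_sphere_33", simulate_volume(sp))
  pk <- template_match(vol, tmpl, angular_step = 360, threshold = 0.5)
  depth <- 1530 - sqrt(pk$x^2 + pk$y^2 + (pk$z + 1530)^2)
  ## an intense response at the membrane itself, plus the CSU layer below
  expect_gt(sum(abs(depth) < 60), 3)
  layer <- depth[depth > 100]
  expect_gt(length(layer), 3)
  expect_lt(abs(stats::median(layer) - 300), 8)   # within one voxel
})
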