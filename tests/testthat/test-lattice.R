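test_that("unit cells hold 3 CSUs (p6) and 1 CSU (p2)", {
  tmpl <- build_csu_template()
  expect_length(build_p6_unit_cell(tmpl)$csus, 3)
  expect_length(build_p2_unit_cell(tmpl)$csus, 1)
  ## p6 cell closes one alternating six-membered ring at the origin
  cell <- build_p6_unit_cell(tmpl)
  sites <- do.call(rbind, cell$csus)
  mem <- sites[sites$kind %in% c("CHEA_P5", "CHEW_CORE"), ]
  at_origin <- mem[sqrt(mem$ring_x^2 + mem$ring_y^2) < 1e-6, ]
  expect_equal(nrow(at_origin), 6)
  ord <- at_origin[order(atan2(at_origin$y, at_origin$x)), ]
  expect_true(all(ord$kind == rep(c("CHEA_P5", "CHEW_CORE"), 3)) ||
              all(ord$kind == rep(c("CHEW_CORE", "CHEA_P5"), 3)))
})

test_that("tiling conserves per-CSU stoichiometry for any extent and seed", {
  for (cfg in list(list("p6", 1), list("p2", 2), list("p6", 3))) {
    m <- build_array(lattice_spec(cfg[[1]], extent = c(cfg[[2]], 2),
                                  flank_occupancy_prob = 0.5,
                                  seed = 7 * cfg[[2]]))
    per <- split(m$sites$kind, m$sites$csu_id)
    for (kinds in per) {
      expect_equal(sum(kinds == "MCP_DIMER"), 6)
      expect_equal(sum(kinds == "CHEA_P5"), 2)
      expect_equal(sum(kinds == "CHEW_CORE"), 2)
      expect_lte(sum(kinds == "CHEW_FLANK"), 2)
    }
  }
})

test_that("flanking occupancy honours its probability bounds and seed", {
  m1 <- build_array(lattice_spec("p2", extent = c(3, 3),
                                 flank_occupancy_prob = 1))
  expect_equal(sum(m1$sites$kind == "CHEW_FLANK"), 2 * nrow(m1$registry))
  m0 <- build_array(lattice_spec("p2", extent = c(3, 3),
                                 flank_occupancy_prob = 0))
  expect_equal(sum(m0$sites$kind == "CHEW_FLANK"), 0)
  ## same seed reproduces the same occupancy pattern; different seed not
  ma <- build_array(lattice_spec("p6", extent = c(3, 3),
                                 flank_occupancy_prob = 0.5, seed = 11))
  mb <- build_array(lattice_spec("p6", extent = c(3, 3),
                                 flank_occupancy_prob = 0.5, seed = 11))
  mc <- build_array(lattice_spec("p6", extent = c(3, 3),
                                 flank_occupancy_prob = 0.5, seed = 12))
  fl <- function(m) m$sites$csu_id[m$sites$kind == "CHEW_FLANK"]
  expect_identical(fl(ma), fl(mb))
  expect_false(identical(fl(ma), fl(mc)))
})

test_that("p2 and p6 tilings share the hexagonal receptor point set", {
  p6 <- model_fix("p6", ext = 2)
  p2 <- model_fix("p2", ext = 3)
  a6 <- as.matrix(p6$sites[p6$sites$kind == "MCP_DIMER", c("x", "y")])
  a2 <- as.matrix(p2$sites[p2$sites$kind == "MCP_DIMER", c("x", "y")])
  ## optimal alignment is a pure translation (both builders use the same
  ## lattice orientation); find it by matching one receptor, then demand
  ## every interior p2 receptor has a p6 twin within 1e-6 A
  ref <- a2[which.min(rowSums(sweep(a2, 2, colMeans(a2))^2)), ]
  best <- c(0, 0); best_n <- -1
  for (i in seq_len(nrow(a6))) {
    delta <- a6[i, ] - ref
    shifted <- sweep(a2, 2, -delta)
    nn <- vapply(seq_len(nrow(shifted)), function(j)
      min(colSums((t(a6) - shifted[j, ])^2)), numeric(1))
    n_match <- sum(nn < 1e-12)
    if (n_match > best_n) { best_n <- n_match; best <- delta }
  }
  shifted <- sweep(a2, 2, -best)
  nn <- sqrt(vapply(seq_len(nrow(shifted)), function(j)
    min(colSums((t(a6) - shifted[j, ])^2)), numeric(1)))
  ## interior of the p2 patch (the p6 patch is smaller; boundary receptors
  ## of one patch have no partner in the other)
  ctr <- colMeans(a2)
  interior <- sqrt(rowSums(sweep(a2, 2, ctr)^2)) < 126
  expect_gt(sum(interior), 10)
  expect_lt(max(nn[interior]), 1e-6)
})

test_that("unit-cell reduction recovers the constructed motif", {
  expect_equal(reduce_unit_cell(model_fix("p6", 3))$motif_csu_count, 3)
  expect_equal(reduce_unit_cell(model_fix("p2", 4))$motif_csu_count, 1)
  ## invariant under an arbitrary global rotation
  rot <- rotate_model(model_fix("p6", 3), 0.7)
  expect_equal(reduce_unit_cell(rot)$motif_csu_count, 3)
  ## aperiodic input is rejected
  bad <- model_fix("p6", 3)
  set.seed(4)
  jit <- matrix(rnorm(2 * nrow(bad$sites), 0, 20), ncol = 2)
  bad$sites$u <- bad$sites$u + jit[, 1]
  bad$sites$v <- bad$sites$v + jit[, 2]
  expect_error(reduce_unit_cell(bad), "periodicity")
})

test_that("sphere mapping preserves the flat limit and surface contracts", {
  m <- model_fix("p6", 2)
  flat <- map_to_sphere(m, 1e9)
  ## the mapping centres the patch; compare after the same centring
  sc <- m$sites
  shift <- c(mean(range(sc$u)), mean(range(sc$v)))
  expect_lt(max(abs(flat$sites$x - (sc$x - shift[1]))), 1e-3)
  expect_lt(max(abs(flat$sites$y - (sc$y - shift[2]))), 1e-3)
  expect_lt(max(abs(flat$sites$z - sc$z)), 1e-3)

  ms <- map_to_sphere(m, 1530)
  ## all baseplate sites lie on the depth-offset sphere within 1e-6 A
  r <- sqrt(ms$sites$x^2 + ms$sites$y^2 + (ms$sites$z + 1530)^2)
  expect_lt(max(abs(r - (1530 - m$baseplate_z))), 1e-6)
  ## radius guard
  expect_error(map_to_sphere(m, 5 * m$a), "radius")
})

test_that("geodesic ring spacing on the membrane sphere stays within 1% of a", {
  m <- model_fix("p6", 2)
  ms <- map_to_sphere(m, 1530)
  ## ring centres in (centred) flattened coordinates
  rc <- unique(round(cbind(ms$sites$ring_x, ms$sites$ring_y), 6))
  rc <- rc[stats::complete.cases(rc), ]
  ## geodesic distance on the membrane sphere between mapped directions
  al <- sqrt(rowSums(rc^2)) / 1530
  th <- atan2(rc[, 2], rc[, 1])
  dirs <- cbind(sin(al) * cos(th), sin(al) * sin(th), cos(al))
  gd <- function(i, j) 1530 * acos(pmin(1, sum(dirs[i, ] * dirs[j, ])))
  nn <- vapply(seq_len(nrow(rc)), function(i) {
    d <- vapply(seq_len(nrow(rc)), function(j)
      if (i == j) Inf else gd(i, j), numeric(1))
    min(d)
  }, numeric(1))
  expect_lt(max(abs(nn - 126) / 126), 0.01)
})
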