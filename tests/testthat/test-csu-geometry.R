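test_that("the CSU template carries the canonical stoichiometry", {
  for (occ in list(c(FALSE, FALSE), c(TRUE, FALSE), c(TRUE, TRUE))) {
    tmpl <- build_csu_template(flank_occupancy = occ)
    counts <- table(tmpl$sites$kind)
    expect_equal(unname(counts["MCP_DIMER"]), 6)
    expect_equal(unname(counts["CHEA_P5"]), 2)
    expect_equal(unname(counts["CHEA_P4"]), 2)
    expect_equal(unname(counts["CHEA_P3"]), 1)
    expect_equal(unname(counts["CHEA_LINKER_ANCHOR"]), 2)
    expect_equal(unname(counts["CHEA_ATP_SITE"]), 2)
    expect_equal(unname(counts["CHEW_CORE"]), 2)
    expect_equal(sum(tmpl$sites$kind == "CHEW_FLANK"), sum(occ))
    ## three receptor dimers per ToD
    expect_equal(as.integer(table(tmpl$sites$tod_id[tmpl$sites$kind ==
                                                    "MCP_DIMER"])), c(3L, 3L))
  }
})

test_that("the template is C2-symmetric about its centre", {
  tmpl <- build_csu_template(flank_occupancy = c(TRUE, TRUE))
  s <- tmpl$sites
  for (k in unique(s$kind)) {
    p <- cbind(s$x, s$y)[s$kind == k, , drop = FALSE]
    q <- -p                               # 180 degrees about the origin
    d <- vapply(seq_len(nrow(p)), function(i)
      min(colSums((t(q) - p[i, ])^2)), numeric(1))
    expect_lt(max(sqrt(d)), 1e-6)
  }
})

test_that("ring members carry two distinct half-site bearings, receptors a slot", {
  tmpl <- build_csu_template(flank_occupancy = c(TRUE, TRUE))
  s <- tmpl$sites
  mem <- s[s$kind %in% c("CHEA_P5", "CHEW_CORE", "CHEW_FLANK"), ]
  expect_true(all(!is.na(mem$b1x) & !is.na(mem$b2x)))
  expect_true(all(abs(mem$b1x - mem$b2x) + abs(mem$b1y - mem$b2y) > 1e-9))
  ## unit bearings
  expect_equal(mem$b1x^2 + mem$b1y^2, rep(1, nrow(mem)))
  mcp <- s[s$kind == "MCP_DIMER", ]
  expect_true(all(!is.na(mcp$slot_x)))
  expect_true(all(is.na(mcp$b1x)))
})

test_that("invalid geometry parameters are rejected", {
  expect_error(csu_geometry(a = -1), "positive")
  expect_error(csu_geometry(baseplate_z = 0), "positive")
  expect_error(csu_geometry(tod_radius = -5), "positive")
})

test_that("flanking CheW addition fills bare receptors and guards state", {
  tmpl <- build_csu_template()
  expect_identical(add_flanking_chew(tmpl, c(FALSE, FALSE)), tmpl)
  t1 <- add_flanking_chew(tmpl, c(TRUE, FALSE))
  expect_equal(sum(t1$sites$kind == "CHEW_FLANK"), 1)
  expect_error(add_flanking_chew(t1, c(TRUE, FALSE)), "already filled")
  t2 <- add_flanking_chew(t1, c(FALSE, TRUE))
  expect_equal(sum(t2$sites$kind == "CHEW_FLANK"), 2)
  ## flank positions mirror under C2: the two flank sites are antipodal
  fl <- t2$sites[t2$sites$kind == "CHEW_FLANK", ]
  expect_equal(fl$x[1], -fl$x[2], tolerance = 1e-9)
  expect_equal(fl$y[1], -fl$y[2], tolerance = 1e-9)
  ## each flank sits at the binding slot of a formerly bare receptor
  bare0 <- chemoarray:::bare_receptors(tmpl$sites)
  expect_true(all(vapply(seq_len(nrow(fl)), function(i)
    min((bare0$slot_x - fl$x[i])^2 + (bare0$slot_y - fl$y[i])^2) < 1e-12,
    logical(1))))
})

test_that("place_csu is a rigid transform acting on every geometric field", {
  tmpl <- build_csu_template(flank_occupancy = c(TRUE, TRUE))
  s0 <- place_csu(tmpl, 0, c(0, 0))
  expect_equal(s0$x, tmpl$sites$x)
  expect_equal(s0$y, tmpl$sites$y)
  ## involution: two half-turns restore the original
  tmpl_pi <- tmpl; tmpl_pi$sites <- place_csu(tmpl, pi, c(0, 0))
  s2 <- place_csu(tmpl_pi, pi, c(0, 0))
  expect_equal(s2$x, tmpl$sites$x, tolerance = 1e-9)
  expect_equal(s2$y, tmpl$sites$y, tolerance = 1e-9)
  ## rigidity: pairwise distances preserved under arbitrary placement
  sr <- place_csu(tmpl, 0.83, c(37, -11))
  d0 <- dist(cbind(tmpl$sites$x, tmpl$sites$y))
  dr <- dist(cbind(sr$x, sr$y))
  expect_equal(as.numeric(dr), as.numeric(d0), tolerance = 1e-9)
  ## bearings rotate with the template
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mem0 <- tmpl$sites$kind %in% c("CHEA_P5", "CHEW_CORE", "CHEW_FLANK")
  b_expect <- cbind(tmpl$sites$b1x[mem0], tmpl$sites$b1y[mem0]) %*% t(R)
  expect_equal(sr$b1x[mem0], b_expect[, 1], tolerance = 1e-12)
  expect_equal(sr$b1y[mem0], b_expect[, 2], tolerance = 1e-12)
})
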