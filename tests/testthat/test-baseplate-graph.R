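test_that("an isolated CSU has exactly its two intra-unit kinase/coupling contacts", {
  tmpl <- build_csu_template()
  one <- tile(build_p2_unit_cell(tmpl),
              lattice_spec("p2", extent = c(1, 1), flank_occupancy_prob = 0))
  g <- classify_interfaces(build_contact_graph(one))
  ring <- g$edges[g$edges$klass %in% c("I", "II", "III"), ]
  expect_equal(nrow(ring), 2)
  expect_true(all(ring$klass == "I"))
  expect_true(all(ring$same_csu))
  cen <- interface_census(g)
  expect_equal(unlist(cen$per_csu[1, c("nI", "nII", "nIII")],
                      use.names = FALSE), c(2, 0, 0))
  ## cutoff semantics: matched half-sites are exactly coincident, so the
  ## intra contacts survive any positive cutoff; once the members are
  ## jittered beyond the cutoff only receptor-binding edges remain
  g_tiny <- build_contact_graph(one, cutoff = 1e-9)
  expect_equal(sum(g_tiny$edges$klass != "RECEPTOR_BIND" |
                   is.na(g_tiny$edges$klass)), 2)
  jit <- one
  mem <- jit$sites$kind %in% c("CHEA_P5", "CHEW_CORE")
  set.seed(3)
  jit$sites$x[mem] <- jit$sites$x[mem] + runif(sum(mem), 0.5, 1)
  g0 <- build_contact_graph(jit, cutoff = 0.1)
  expect_true(all(g0$edges$klass == "RECEPTOR_BIND"))
})

test_that("interface classes follow the subdomain pairing rules", {
  g6 <- graph_fix("p6", 3)
  s <- g6$model$sites
  e <- g6$edges[g6$edges$klass %in% c("I", "II", "III"), ]
  kind_a <- s$kind[match(e$a_site, s$site_id)]
  kind_b <- s$kind[match(e$b_site, s$site_id)]
  ## class I and II join P5 with a CheW; class III joins two CheW
  expect_true(all(xor(kind_a[e$klass != "III"] == "CHEA_P5",
                      kind_b[e$klass != "III"] == "CHEA_P5")))
  expect_true(all(kind_a[e$klass == "III"] != "CHEA_P5" &
                  kind_b[e$klass == "III"] != "CHEA_P5"))
  ## in the p6 interior every class II contact couples two different CSUs
  int <- interior_ids(g6)
  csu_a <- s$csu_id[match(e$a_site, s$site_id)]
  csu_b <- s$csu_id[match(e$b_site, s$site_id)]
  both_int <- csu_a %in% int & csu_b %in% int
  expect_true(all(!e$same_csu[e$klass == "II" & both_int]))
  expect_true(all(e$same_csu[e$klass == "I"]))
})

test_that("fully occupied interiors leave no free docking half-site", {
  for (sym in c("p6", "p2")) {
    g <- graph_fix(sym, 3)
    int <- interior_ids(g)
    expect_gt(length(int), 0)
    s <- g$model$sites
    mem <- s[s$kind %in% c("CHEA_P5", "CHEW_CORE", "CHEW_FLANK") &
             s$csu_id %in% int, ]
    used <- paste(c(g$edges$a_site, g$edges$b_site),
                  c(g$edges$a_sub, g$edges$b_sub))
    expect_true(all(paste(mem$site_id, 1) %in% used))
    expect_true(all(paste(mem$site_id, 2) %in% used))
  }
})

test_that("ring taxonomy matches the two architectures", {
  r6 <- enumerate_rings(graph_fix("p6", 3))
  c6 <- r6[r6$complete, ]
  expect_true(all(c6$size == 6))
  expect_setequal(unique(c6$klass), c("APW3", "W6"))
  r2 <- enumerate_rings(graph_fix("p2", 4))
  c2 <- r2[r2$complete, ]
  expect_true(all(c2$size == 6))
  expect_setequal(unique(c2$klass), "APWW2")
  ## without flanking CheW: p6 keeps its alternating rings, p2 loses all
  r60 <- enumerate_rings(graph_fix("p6", 3, occ = 0))
  expect_setequal(unique(r60$klass[r60$complete]), "APW3")
  r20 <- enumerate_rings(graph_fix("p2", 3, occ = 0))
  expect_equal(sum(r20$complete), 0)
})

test_that("ring edge-class multisets match the published patterns", {
  g6 <- graph_fix("p6", 3)
  r6 <- enumerate_rings(g6)
  for (i in which(r6$complete)) {
    cls <- ring_edge_classes(g6, r6$members[[i]])
    if (r6$klass[i] == "APW3") {
      expect_setequal(unique(cls), c("I", "II"))       # alternating
      expect_true(all(cls[c(TRUE, FALSE)] == cls[1]))
      expect_equal(sum(cls == "I"), 3)
    } else if (r6$klass[i] == "W6") {
      expect_true(all(cls == "III"))
    }
  }
  g2 <- graph_fix("p2", 4)
  r2 <- enumerate_rings(g2)
  for (i in which(r2$complete)) {
    cls <- ring_edge_classes(g2, r2$members[[i]])
    expect_equal(as.integer(table(cls)[c("I", "II", "III")]), c(2L, 2L, 2L))
    ## each class adjacent to the other two: no two consecutive edges equal
    expect_true(all(cls != c(cls[-1], cls[1])))
  }
})

test_that("ring enumeration agrees with an independent igraph cycle search", {
  for (sym in c("p6", "p2")) {
    g <- graph_fix(sym, 3)
    e <- g$edges[g$edges$klass %in% c("I", "II", "III"), ]
    ig <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e$a_site), to = as.character(e$b_site)),
      directed = FALSE)
    comp <- igraph::components(ig)
    cycle_sets <- list()
    for (ci in seq_len(comp$no)) {
      vs <- names(comp$membership)[comp$membership == ci]
      degs <- igraph::degree(ig, vs)
      if (all(degs == 2))
        cycle_sets[[length(cycle_sets) + 1]] <- sort(as.integer(vs))
    }
    ours <- enumerate_rings(g)
    our_sets <- lapply(ours$members[ours$complete], sort)
    expect_equal(length(our_sets), length(cycle_sets))
    key <- function(x) paste(x, collapse = "+")
    expect_setequal(vapply(our_sets, key, ""),
                    vapply(cycle_sets, key, ""))
  }
})

test_that("interior interface census is 2/4/4 for both architectures", {
  for (sym in c("p6", "p2")) {
    cen <- interface_census(graph_fix(sym, 3))
    int <- cen$per_csu[cen$per_csu$interior, ]
    expect_gt(nrow(int), 0)
    expect_true(all(int$nI == 2))
    expect_true(all(int$nII == 4))
    expect_true(all(int$nIII == 4))
  }
})

test_that("receptor-to-kinase hop counts separate the two architectures", {
  g2 <- graph_fix("p2", 3)
  h2 <- receptor_to_kinase_hops(g2)
  int2 <- interior_ids(g2)
  tods <- split(h2$hops[h2$csu_id %in% int2],
                paste(h2$csu_id, h2$tod_id)[h2$csu_id %in% int2])
  expect_true(all(vapply(tods, function(v)
    identical(sort(v), c(1, 2, 2)), logical(1))))

  g6 <- graph_fix("p6", 3)
  h6 <- receptor_to_kinase_hops(g6)
  int6 <- interior_ids(g6)
  tods6 <- split(h6$hops[h6$csu_id %in% int6],
                 paste(h6$csu_id, h6$tod_id)[h6$csu_id %in% int6])
  expect_true(all(vapply(tods6, function(v)
    sum(v <= 2) == 2 && sum(is.infinite(v)) == 1, logical(1))))
  ## the unreachable receptor is the flanking-CheW-bound one: its ring is
  ## CheA-free
  expect_true(all(vapply(tods6, function(v) identical(sort(v[is.finite(v)]),
                                                      c(1, 2)), logical(1))))
})

test_that("hop counts agree with an independent breadth-first search", {
  g <- graph_fix("p6", 3)
  h <- receptor_to_kinase_hops(g)
  s <- g$model$sites
  p5 <- s$site_id[s$kind == "CHEA_P5"]
  set.seed(21)
  pick <- h[sample.int(nrow(h), 12), ]
  for (i in seq_len(nrow(pick))) {
    expect_equal(pick$hops[i],
                 bfs_hops_oracle(g$edges, pick$site_id[i], p5))
  }
})

test_that("CheA neighbour geometry differs between the architectures", {
  nm6 <- chea_neighbour_metrics(model_fix("p6", 3))
  nm2 <- chea_neighbour_metrics(model_fix("p2", 3))
  ## p2: parallel stripes, all relative orientations 0 mod 180
  expect_lt(max(nm2$rel_orientation_deg), 1e-6)
  ## p6: nearest-neighbour dimers are 120-degree related (60 after
  ## folding undirected axes into [0, 90])
  near6 <- nm6[nm6$distance <= min(nm6$distance) + 1, ]
  expect_true(all(abs(near6$rel_orientation_deg - 60) < 1e-6))
  ## lattice periodicity: the nearest-neighbour distance multiset repeats
  ## across deep-interior dimers (per source monomer, 4 closest targets)
  m6 <- model_fix("p6", 3)
  cc <- chemoarray:::csu_centres(m6)
  ctr <- c(mean(cc$x), mean(cc$y))
  deep <- cc$csu_id[sqrt((cc$x - ctr[1])^2 + (cc$y - ctr[2])^2) < 1.2 * 126]
  expect_gt(length(deep), 1)
  nn4 <- lapply(split(nm6$distance[nm6$source_csu %in% deep],
                      paste(nm6$source_csu, nm6$source_monomer)[
                        nm6$source_csu %in% deep]),
                function(v) round(sort(v)[1:4], 6))
  expect_equal(length(unique(nn4)), 1)
})

test_that("doubling the lattice constant stretches CheA neighbour distances", {
  m1 <- model_fix("p6", 3)
  m2 <- build_array(lattice_spec("p6", a = 252, extent = c(3, 3)))
  nm1 <- chea_neighbour_metrics(m1, radius = 2 * 126)
  nm2 <- chea_neighbour_metrics(m2, radius = 2 * 252)
  key <- function(d) paste(d$source_csu, d$source_monomer,
                           d$target_csu, d$target_monomer)
  j <- match(key(nm1), key(nm2))
  ok <- !is.na(j)
  ratio <- nm2$distance[j[ok]] / nm1$distance[ok]
  expect_true(all(ratio >= 1 - 1e-9 & ratio <= 2 + 1e-9))
  expect_gt(min(nm2$distance), min(nm1$distance))
})
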