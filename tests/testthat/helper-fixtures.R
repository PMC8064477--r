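## Shared fixtures (built once per test run) and independent oracles.

.fixture_env <- new.env()

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

model_fix <- function(sym, ext = 3, occ = 1, seed = 1) {
  cached(paste("model", sym, ext, occ, seed),
         build_array(lattice_spec(sym, extent = c(ext, ext),
                                  flank_occupancy_prob = occ, seed = seed)))
}

graph_fix <- function(sym, ext = 3, occ = 1, seed = 1) {
  cached(paste("graph", sym, ext, occ, seed),
         classify_interfaces(build_contact_graph(model_fix(sym, ext, occ,
                                                           seed))))
}

## interior CSU ids of a classified graph
interior_ids <- function(graph) {
  as.integer(names(which(chemoarray:::csu_interior(graph))))
}

## Independent breadth-first search over an edge list (site ids), used as
## the oracle for the packaged hop computation.
bfs_hops_oracle <- function(edges, from, targets) {
  adj <- split(c(edges$b_site, edges$a_site),
               c(edges$a_site, edges$b_site))
  dist <- setNames(0L, as.character(from))
  frontier <- as.character(from)
  d <- 0L
  while (length(frontier)) {
    if (any(frontier %in% as.character(targets))) return(d)
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier]))
    nxt <- as.character(nxt[!as.character(nxt) %in% names(dist)])
    if (!length(nxt)) return(Inf)
    dist[nxt] <- d
    frontier <- nxt
  }
  Inf
}

## Edge classes around a complete ring record, in cyclic member order.
ring_edge_classes <- function(graph, members) {
  e <- graph$edges[graph$edges$klass %in% c("I", "II", "III"), ]
  n <- length(members)
  vapply(seq_len(n), function(i) {
    a <- members[i]; b <- members[if (i == n) 1 else i + 1]
    hit <- (e$a_site == a & e$b_site == b) | (e$a_site == b & e$b_site == a)
    e$klass[which(hit)[1]]
  }, "")
}

## Rigidly rotate a planar model in-plane (for rotation-invariance tests).
rotate_model <- function(model, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  s <- model$sites
  rot_cols <- function(cx, cy, translate = TRUE) {
    ok <- !is.na(s[[cx]])
    xy <- cbind(s[[cx]][ok], s[[cy]][ok]) %*% t(R)
    s[[cx]][ok] <<- xy[, 1]; s[[cy]][ok] <<- xy[, 2]
  }
  rot_cols("x", "y"); rot_cols("u", "v")
  rot_cols("b1x", "b1y"); rot_cols("b2x", "b2y")
  rot_cols("slot_x", "slot_y"); rot_cols("ring_x", "ring_y")
  s$angle <- s$angle + theta
  model$sites <- s
  model
}
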