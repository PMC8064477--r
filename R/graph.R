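## Baseplate docking-site contact graph.
##
## Every CheA.P5 and CheW site carries two docking half-sites (SUB1, SUB2)
## whose bearings point towards the two adjacent ring vertices.  A contact
## pairs two half-sites whose docking points (half-way along the bearing to
## the neighbouring vertex) coincide.  The three pseudosymmetric ring
## interfaces are classified from the subdomain combination:
##   I   : P5.SUB1 -- W.SUB2   (intra-CSU A.P5/W pair)
##   II  : P5.SUB2 -- W.SUB1   (inter-CSU A.P5/W)
##   III : W.SUB1  -- W.SUB2   (CheW/CheW)
## Receptor binding (MCP tip to its baseplate partner) is a fourth edge
## type, RECEPTOR_BIND, used by the connectivity analysis.

## Half-site table of a model: one row per (ring member, subdomain).
half_site_table <- function(model) {
  s <- model$sites
  mem <- s[s$kind %in% RING_KINDS, , drop = FALSE]
  if (nrow(mem) == 0)
    return(data.frame(site_id = integer(), sub = integer()))
  r <- model$a / (2 * sqrt(3))      # ring radius == adjacent-member chord
  hs <- rbind(
    data.frame(site_id = mem$site_id, sub = 1L,
               dx = mem$x + (r / 2) * mem$b1x,
               dy = mem$y + (r / 2) * mem$b1y,
               dz = mem$z + (r / 2) * ifelse(is.na(mem$b1z), 0, mem$b1z)),
    data.frame(site_id = mem$site_id, sub = 2L,
               dx = mem$x + (r / 2) * mem$b2x,
               dy = mem$y + (r / 2) * mem$b2y,
               dz = mem$z + (r / 2) * ifelse(is.na(mem$b2z), 0, mem$b2z)))
  hs[order(hs$site_id, hs$sub), ]
}

#' Build the baseplate docking-site contact graph
#'
#' Pairs each free docking half-site with its geometrically nearest
#' compatible half-site within \code{cutoff} (greedy, closest pairs first;
#' each half-site used at most once; exact distance ties broken towards the
#' lowest site id).  Adds a RECEPTOR_BIND edge from every receptor dimer
#' tip to the baseplate member sitting at its binding slot, when present.
#'
#' @param model an \code{array_model}.
#' @param cutoff maximum docking-point separation in Angstrom; default
#'   a/10.  Matched half-sites are coincident by construction, while the
#'   nearest non-partner docking points (two half-sites facing one vacant
#'   flanking slot) sit a/4 apart, so any cutoff comfortably below a/4 is
#'   safe.
#' @return object of class \code{baseplate_graph} with the edge table
#'   (\code{klass} is NA until \code{\link{classify_interfaces}}).
#' @export
build_contact_graph <- function(model, cutoff = model$a / 10) {
  stopifnot(inherits(model, "array_model"))
  if (cutoff <= 0) stop_param("cutoff must be positive")
  s <- model$sites
  hs <- half_site_table(model)
  edges <- list()
  if (nrow(hs) > 1) {
    ## candidate pairs within cutoff
    n <- nrow(hs)
    D2 <- (outer(hs$dx, hs$dx, "-"))^2 + (outer(hs$dy, hs$dy, "-"))^2 +
          (outer(hs$dz, hs$dz, "-"))^2
    cand <- which(upper.tri(D2) & D2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(cand)) {
      same_site <- hs$site_id[cand[, 1]] == hs$site_id[cand[, 2]]
      cand <- cand[!same_site, , drop = FALSE]
    }
    if (nrow(cand)) {
      dd <- sqrt(D2[cand])
      key_lo <- pmin(hs$site_id[cand[, 1]], hs$site_id[cand[, 2]])
      key_hi <- pmax(hs$site_id[cand[, 1]], hs$site_id[cand[, 2]])
      ord <- order(round(dd / 1e-6), key_lo, key_hi)
      used <- rep(FALSE, nrow(hs))
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used[i] || used[j]) next
        used[i] <- used[j] <- TRUE
        edges[[length(edges) + 1]] <- data.frame(
          a_site = hs$site_id[i], a_sub = hs$sub[i],
          b_site = hs$site_id[j], b_sub = hs$sub[j],
          klass = NA_character_, dist = dd[k])
      }
    }
  }
  ## receptor binding edges
  mcp <- s[s$kind == "MCP_DIMER" & !is.na(s$slot_x), , drop = FALSE]
  mem <- s[s$kind %in% RING_KINDS, , drop = FALSE]
  bind_tol <- 0.1 * model$a
  if (nrow(mcp) && nrow(mem)) {
    for (i in seq_len(nrow(mcp))) {
      d2 <- (mem$x - mcp$slot_x[i])^2 + (mem$y - mcp$slot_y[i])^2 +
            (mem$z - mcp$slot_z[i])^2
      j <- which.min(d2)
      if (d2[j] <= bind_tol^2)
        edges[[length(edges) + 1]] <- data.frame(
          a_site = mcp$site_id[i], a_sub = 0L,
          b_site = mem$site_id[j], b_sub = 0L,
          klass = "RECEPTOR_BIND", dist = sqrt(d2[j]))
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(a_site = integer(), a_sub = integer(),
                           b_site = integer(), b_sub = integer(),
                           klass = character(), dist = numeric())
  edges$same_csu <- s$csu_id[match(edges$a_site, s$site_id)] ==
                    s$csu_id[match(edges$b_site, s$site_id)]
  structure(list(model = model, edges = edges, cutoff = cutoff,
                 classified = FALSE),
            class = "baseplate_graph")
}

#' Classify ring-interface edges
#'
#' Assigns interface classes I, II, III from the endpoint kinds and
#' subdomains: P5.SUB1--W.SUB2 is I, P5.SUB2--W.SUB1 is II, W.SUB1--W.SUB2
#' is III.  Any P5--P5 pairing or a like-subdomain combination is a
#' geometry inconsistency and raises an error naming the offending sites.
#'
#' @param graph a \code{baseplate_graph}.
#' @return the graph with \code{klass} filled in.
#' @export
classify_interfaces <- function(graph) {
  stopifnot(inherits(graph, "baseplate_graph"))
  s <- graph$model$sites
  e <- graph$edges
  ring <- is.na(e$klass) | e$klass != "RECEPTOR_BIND"
  kind_a <- s$kind[match(e$a_site, s$site_id)]
  kind_b <- s$kind[match(e$b_site, s$site_id)]
  for (i in which(ring)) {
    ka <- kind_a[i]; kb <- kind_b[i]
    is_p5 <- c(ka, kb) == "CHEA_P5"
    subs <- c(e$a_sub[i], e$b_sub[i])
    bad <- function() stop("inconsistent half-site pairing between sites ",
                           e$a_site[i], " and ", e$b_site[i],
                           " (", ka, ".SUB", subs[1], " -- ", kb, ".SUB",
                           subs[2], ")", call. = FALSE)
    if (all(is_p5)) bad()
    if (!any(is_p5)) {                     # CheW -- CheW
      if (sum(subs == 1) != 1) bad()
      e$klass[i] <- "III"
    } else {
      p5_sub <- subs[which(is_p5)]
      w_sub <- subs[which(!is_p5)]
      if (p5_sub == 1 && w_sub == 2) e$klass[i] <- "I"
      else if (p5_sub == 2 && w_sub == 1) e$klass[i] <- "II"
      else bad()
    }
  }
  graph$edges <- e
  graph$classified <- TRUE
  graph
}

ring_edges <- function(graph) {
  e <- graph$edges
  e[e$klass %in% c("I", "II", "III"), , drop = FALSE]
}

#' Enumerate baseplate rings
#'
#' Each ring member carries exactly two docking half-sites, so the graph of
#' classified I/II/III edges has maximum degree two and decomposes into
#' simple cycles and paths.  Complete rings are the cycles (all chordless
#' by construction); cycles of length six are classified by composition:
#' \itemize{
#'   \item APW3: three CheA.P5 alternating with three CheW;
#'   \item W6: six flanking CheW;
#'   \item APWW2: two P5, two core CheW, two flanking CheW in two-fold
#'     order.
#' }
#' Maximal open paths of at least two ring edges are reported as PARTIAL.
#'
#' @param graph a classified \code{baseplate_graph}.
#' @return data frame of ring records: \code{klass}, \code{size},
#'   \code{centre_x}, \code{centre_y} and the cyclically ordered member
#'   site ids in \code{members} (list column).
#' @export
enumerate_rings <- function(graph) {
  stopifnot(inherits(graph, "baseplate_graph"))
  if (!graph$classified) graph <- classify_interfaces(graph)
  s <- graph$model$sites
  e <- ring_edges(graph)
  recs <- list()
  if (nrow(e)) {
    nodes <- sort(unique(c(e$a_site, e$b_site)))
    adj <- vector("list", length(nodes))
    names(adj) <- as.character(nodes)
    for (i in seq_len(nrow(e))) {
      adj[[as.character(e$a_site[i])]] <-
        c(adj[[as.character(e$a_site[i])]], e$b_site[i])
      adj[[as.character(e$b_site[i])]] <-
        c(adj[[as.character(e$b_site[i])]], e$a_site[i])
    }
    visited <- setNames(rep(FALSE, length(nodes)), as.character(nodes))
    for (start in nodes) {
      if (visited[[as.character(start)]]) next
      ## walk the component
      comp <- start
      visited[[as.character(start)]] <- TRUE
      frontier <- start
      while (length(frontier)) {
        nxt <- unique(unlist(adj[as.character(frontier)]))
        nxt <- nxt[!visited[as.character(nxt)]]
        visited[as.character(nxt)] <- TRUE
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      degs <- lengths(adj[as.character(comp)])
      is_cycle <- all(degs == 2)
      ## order members along the path/cycle
      first <- if (is_cycle) comp[1] else comp[which(degs == 1)[1]]
      ordered <- first
      prev <- NA
      cur <- first
      repeat {
        nbrs <- adj[[as.character(cur)]]
        nbrs <- nbrs[is.na(prev) | nbrs != prev]
        if (!length(nbrs)) break
        nxt <- nbrs[1]
        if (is_cycle && nxt == first) break
        ordered <- c(ordered, nxt)
        prev <- cur
        cur <- nxt
        if (length(ordered) > length(comp)) break
      }
      n_edges <- length(ordered) - !is_cycle
      if (!is_cycle && n_edges < 2) next
      kinds <- s$kind[match(ordered, s$site_id)]
      klass <- if (!is_cycle) "PARTIAL"
      else if (length(ordered) != 6) "PARTIAL"
      else {
        np5 <- sum(kinds == "CHEA_P5")
        ncw <- sum(kinds == "CHEW_CORE")
        nfw <- sum(kinds == "CHEW_FLANK")
        alternating <- all(kinds[c(TRUE, FALSE)] == "CHEA_P5") ||
                       all(kinds[c(FALSE, TRUE)] == "CHEA_P5")
        if (nfw == 6) "W6"
        else if (np5 == 3 && ncw + nfw == 3 && alternating) "APW3"
        else if (np5 == 2 && ncw == 2 && nfw == 2) "APWW2"
        else "PARTIAL"
      }
      recs[[length(recs) + 1]] <- data.frame(
        klass = klass, size = length(ordered), complete = is_cycle,
        centre_x = mean(s$u[match(ordered, s$site_id)]),
        centre_y = mean(s$v[match(ordered, s$site_id)]))
      recs[[length(recs)]]$members <- I(list(ordered))
    }
  }
  if (!length(recs))
    return(data.frame(klass = character(), size = integer(),
                      complete = logical(), centre_x = numeric(),
                      centre_y = numeric()))
  do.call(rbind, recs)
}

#' Per-CSU and lattice-wide interface census
#'
#' Counts interface edges of each class per CSU.  An edge is counted for a
#' CSU when at least one endpoint is owned by it; flanking CheW monomers
#' are owned by the CSU whose receptor binds them (the CSU they were
#' stamped with at construction).  For interior CSUs of fully occupied
#' lattices of either symmetry this yields the triple (I, II, III) =
#' (2, 4, 4).
#'
#' @param graph a classified \code{baseplate_graph}.
#' @return object of class \code{interface_census}: \code{per_csu} (data
#'   frame csu_id/nI/nII/nIII/interior) and \code{lattice_totals}.
#' @export
interface_census <- function(graph) {
  stopifnot(inherits(graph, "baseplate_graph"))
  if (!graph$classified) graph <- classify_interfaces(graph)
  s <- graph$model$sites
  e <- ring_edges(graph)
  csus <- sort(unique(s$csu_id))
  owner_a <- s$csu_id[match(e$a_site, s$site_id)]
  owner_b <- s$csu_id[match(e$b_site, s$site_id)]
  per <- data.frame(csu_id = csus, nI = 0L, nII = 0L, nIII = 0L)
  for (kl in c("I", "II", "III")) {
    sel <- e$klass == kl
    ## count each edge once per CSU owning at least one endpoint
    cnt <- table(factor(unlist(lapply(which(sel), function(i)
      unique(c(owner_a[i], owner_b[i])))), levels = csus))
    per[[paste0("n", kl)]] <- as.integer(cnt)
  }
  per$interior <- csu_interior(graph)[as.character(csus)]
  totals <- c(NI = sum(e$klass == "I"), NII = sum(e$klass == "II"),
              NIII = sum(e$klass == "III"))
  structure(list(per_csu = per, lattice_totals = totals),
            class = "interface_census")
}

#' @export
print.interface_census <- function(x, ...) {
  cat("Baseplate interface census\n")
  cat("  lattice totals: I =", x$lattice_totals["NI"],
      " II =", x$lattice_totals["NII"],
      " III =", x$lattice_totals["NIII"], "\n")
  int <- x$per_csu[x$per_csu$interior, , drop = FALSE]
  if (nrow(int)) {
    tri <- unique(int[, c("nI", "nII", "nIII")])
    cat("  interior CSUs:", nrow(int), "; count triples observed:\n")
    print(tri, row.names = FALSE)
  } else cat("  no interior CSUs\n")
  invisible(x)
}

## Interior CSUs: those whose owned ring members (including their flanking
## CheWs) have every docking half-site paired.  Named logical vector by
## csu id.
csu_interior <- function(graph) {
  s <- graph$model$sites
  e <- graph$edges
  mem <- s[s$kind %in% RING_KINDS, , drop = FALSE]
  paired <- paste(c(e$a_site, e$b_site), c(e$a_sub, e$b_sub))
  full <- paste(mem$site_id, 1) %in% paired & paste(mem$site_id, 2) %in% paired
  csus <- sort(unique(s$csu_id))
  out <- vapply(csus, function(cid) {
    m <- mem$csu_id == cid
    any(m) && all(full[m])
  }, logical(1))
  names(out) <- as.character(csus)
  out
}

#' Interface-hop distance from each receptor to the nearest CheA
#'
#' Breadth-first search from every receptor dimer tip over RECEPTOR_BIND
#' and I/II/III edges to the nearest CheA.P5 site; the receptor-to-
#' baseplate binding counts as one interface.  Receptors whose search
#' never reaches a P5 (e.g. those bound to an all-CheW ring in the p6
#' architecture) are reported as unreachable (\code{Inf}).
#'
#' @param graph a classified \code{baseplate_graph}.
#' @return data frame: receptor \code{site_id}, \code{csu_id},
#'   \code{tod_id}, \code{hops} (Inf when unreachable).
#' @export
receptor_to_kinase_hops <- function(graph) {
  stopifnot(inherits(graph, "baseplate_graph"))
  if (!graph$classified) graph <- classify_interfaces(graph)
  s <- graph$model$sites
  e <- graph$edges
  mcp <- s[s$kind == "MCP_DIMER", , drop = FALSE]
  p5 <- s$site_id[s$kind == "CHEA_P5"]
  ids <- as.character(s$site_id)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$a_site), to = as.character(e$b_site)),
    directed = FALSE, vertices = data.frame(name = ids))
  D <- igraph::distances(g, v = as.character(mcp$site_id),
                         to = as.character(p5))
  hops <- if (length(p5)) apply(D, 1, min) else rep(Inf, nrow(mcp))
  data.frame(site_id = mcp$site_id, csu_id = mcp$csu_id,
             tod_id = mcp$tod_id, hops = as.numeric(hops))
}

#' Distances and orientations between neighbouring CheA dimers
#'
#' For every CheA monomer, reports the Euclidean distance from the end of
#' its P2-P3 linker to the ATP-lid sites of all other CheA dimers within
#' \code{radius}, together with the in-plane angle between the two dimer
#' axes (folded to \[0, 90\] degrees; axes are undirected).
#'
#' @param model an \code{array_model}.
#' @param radius neighbourhood radius in Angstrom (default 2 lattice
#'   constants).
#' @return data frame with source/target csu and monomer, \code{distance}
#'   (Angstrom) and \code{rel_orientation_deg}.
#' @export
chea_neighbour_metrics <- function(model, radius = 2 * model$a) {
  stopifnot(inherits(model, "array_model"))
  s <- model$sites
  anchors <- s[s$kind == "CHEA_LINKER_ANCHOR", , drop = FALSE]
  atp <- s[s$kind == "CHEA_ATP_SITE", , drop = FALSE]
  if (!nrow(anchors) || !nrow(atp))
    stop_param("model lacks CheA linker-anchor or ATP-lid sites")
  out <- list()
  for (i in seq_len(nrow(anchors))) {
    other <- atp[atp$csu_id != anchors$csu_id[i], , drop = FALSE]
    d <- sqrt((other$x - anchors$x[i])^2 + (other$y - anchors$y[i])^2 +
              (other$z - anchors$z[i])^2)
    sel <- d <= radius
    if (!any(sel)) next
    out[[length(out) + 1]] <- data.frame(
      source_csu = anchors$csu_id[i], source_monomer = anchors$monomer[i],
      target_csu = other$csu_id[sel], target_monomer = other$monomer[sel],
      distance = d[sel],
      rel_orientation_deg = axis_angle_diff(
        rad2deg(anchors$angle[i]), rad2deg(other$angle[sel])))
  }
  if (!length(out))
    return(data.frame(source_csu = integer(), source_monomer = integer(),
                      target_csu = integer(), target_monomer = integer(),
                      distance = numeric(), rel_orientation_deg = numeric()))
  do.call(rbind, out)
}

#' @export
print.baseplate_graph <- function(x, ...) {
  e <- x$edges
  cat("Baseplate contact graph:", nrow(e), "edges\n")
  if (x$classified) print(table(e$klass)) else cat("  (unclassified)\n")
  invisible(x)
}
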