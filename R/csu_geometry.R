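## Core-signalling unit (CSU) template geometry.
##
## The CSU is the minimal signalling complex of the chemosensory array: two
## receptor trimers-of-dimers (ToDs) bridged by a CheA dimer and two core
## CheW monomers.  All coordinates here are coarse-grained pseudo-atoms in a
## local frame centred on the CSU two-fold axis, with the membrane plane at
## z = 0 and the kinase baseplate at z = -baseplate_z.
##
## Canonical geometry, derived from the lattice constant a:
##   * ToD centres sit on the honeycomb vertex lattice; nearest ToD-ToD
##     distance is a/sqrt(3) (the two ToDs of one CSU are such neighbours).
##   * Six-membered baseplate rings sit at honeycomb hexagon centres, which
##     form a hexagonal lattice of spacing a (the lattice constant).
##   * Ring members (CheA.P5 and CheW) sit on a circle of radius
##     a/(2*sqrt(3)) around each ring centre, at the azimuths of the six
##     surrounding ToDs -- i.e. at the midpoint between ring centre and ToD.

SITE_KINDS <- c("MCP_DIMER", "CHEA_P5", "CHEA_P4", "CHEA_P3",
                "CHEA_LINKER_ANCHOR", "CHEA_ATP_SITE", "CHEW_CORE",
                "CHEW_FLANK")
RING_KINDS <- c("CHEA_P5", "CHEW_CORE", "CHEW_FLANK")

#' Geometry parameters for the core-signalling unit template
#'
#' @param a lattice constant in Angstrom: the spacing of the hexagonal
#'   lattice of six-membered baseplate rings.  Default 126 Angstrom.
#' @param baseplate_z depth of the kinase baseplate beneath the inner
#'   membrane, in Angstrom (membrane at z = 0, baseplate at z =
#'   -baseplate_z).  Default 300 Angstrom (30 nm).
#' @param tod_radius in-plane distance from a ToD centre to each of its
#'   three receptor-dimer tip sites, in Angstrom.
#' @return an object of class \code{csu_geometry} with derived quantities
#'   \code{tod_spacing} (= a/sqrt(3)) and \code{ring_radius} (= a/(2 sqrt 3)).
#' @export
csu_geometry <- function(a = 126, baseplate_z = 300, tod_radius = 12) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    stop_param("lattice constant 'a' must be a positive number")
  if (!is.numeric(baseplate_z) || baseplate_z <= 0)
    stop_param("'baseplate_z' must be positive")
  if (!is.numeric(tod_radius) || tod_radius <= 0)
    stop_param("'tod_radius' must be positive")
  structure(list(a = a, baseplate_z = baseplate_z, tod_radius = tod_radius,
                 tod_spacing = a / sqrt(3), ring_radius = a / (2 * sqrt(3))),
            class = "csu_geometry")
}

## Construct one ring-member site row.  Half-site bearings SUB1/SUB2 point
## from the member towards its two prospective ring neighbours (the ring
## vertices at +/-60 degrees of azimuth around the ring centre); SUB1 is the
## counter-clockwise neighbour as seen from +z.
ring_member_row <- function(kind, monomer, tod, ring_c, pos, z) {
  u <- pos - ring_c
  r <- sqrt(sum(u^2))
  phi <- atan2(u[2], u[1])
  nb1 <- ring_c + r * c(cos(phi + pi / 3), sin(phi + pi / 3))
  nb2 <- ring_c + r * c(cos(phi - pi / 3), sin(phi - pi / 3))
  b1 <- (nb1 - pos) / sqrt(sum((nb1 - pos)^2))
  b2 <- (nb2 - pos) / sqrt(sum((nb2 - pos)^2))
  site_row(kind, monomer, tod, pos, z, angle = phi,
           b1 = b1, b2 = b2, ring = ring_c)
}

site_row <- function(kind, monomer, tod, pos, z, angle = 0,
                     b1 = c(NA, NA), b2 = c(NA, NA),
                     slot = c(NA, NA), ring = c(NA, NA)) {
  data.frame(site_id = NA_integer_, kind = kind, monomer = as.integer(monomer),
             csu_id = 1L, tod_id = as.integer(tod),
             x = pos[1], y = pos[2], z = z, u = pos[1], v = pos[2],
             angle = angle,
             b1x = b1[1], b1y = b1[2], b1z = ifelse(is.na(b1[1]), NA, 0),
             b2x = b2[1], b2y = b2[2], b2z = ifelse(is.na(b2[1]), NA, 0),
             slot_x = slot[1], slot_y = slot[2],
             slot_z = ifelse(is.na(slot[1]), NA, z),
             ring_x = ring[1], ring_y = ring[2],
             stringsAsFactors = FALSE)
}

#' Build the coarse-grained core-signalling unit template
#'
#' Constructs the pseudo-atom site set of one CSU in a local frame centred
#' on its two-fold (C2) axis: six receptor dimer tips (three per ToD), two
#' CheA.P5 and two core CheW ring members, two CheA.P4 sites, one shared
#' CheA.P3 dimerisation site, plus point sites for the end of the P2-P3
#' linker and the ATP lid of each CheA monomer.  Flanking CheW sites are
#' absent by default and can be added with \code{\link{add_flanking_chew}}.
#'
#' The CheA dimer axis lies along the local x axis (ToD 0 at negative x).
#' The two rings receiving the intra-CSU CheA.P5/CheW pairs are centred at
#' (0, +a/2) and (0, -a/2); the two rings holding the flanking-CheW slots of
#' the bare receptors are centred at (-/+ sqrt(3) a / 2, 0).
#'
#' @param geometry a \code{\link{csu_geometry}} object.
#' @param flank_occupancy logical pair: whether to attach a flanking CheW to
#'   the bare receptor of ToD 0 and ToD 1.
#' @return an object of class \code{csu_template} with elements
#'   \code{sites} (data frame of component sites), \code{geometry} and
#'   \code{flank_occupancy}.
#' @export
build_csu_template <- function(geometry = csu_geometry(),
                               flank_occupancy = c(FALSE, FALSE)) {
  if (!inherits(geometry, "csu_geometry"))
    geometry <- do.call(csu_geometry, as.list(geometry))
  a <- geometry$a
  d <- geometry$tod_spacing
  z <- -geometry$baseplate_z
  v <- rbind(c(-d / 2, 0), c(d / 2, 0))              # ToD centres
  rings <- list(L = c(0, a / 2), R = c(0, -a / 2),
                B0 = c(-sqrt(3) * a / 2, 0), B1 = c(sqrt(3) * a / 2, 0))

  rows <- list()
  ## Receptor dimer tips: each ToD presents one dimer towards each of its
  ## three adjacent rings; the binding slot is the ring-member position at
  ## the ring-centre/ToD midpoint.
  tod_rings <- list(`0` = c("L", "R", "B0"), `1` = c("L", "R", "B1"))
  for (tod in 0:1) {
    for (rn in tod_rings[[as.character(tod)]]) {
      c_r <- rings[[rn]]
      vv <- v[tod + 1, ]
      dir <- (c_r - vv) / sqrt(sum((c_r - vv)^2))
      pos <- vv + geometry$tod_radius * dir
      slot <- (vv + c_r) / 2
      rows[[length(rows) + 1]] <-
        site_row("MCP_DIMER", 0, tod, pos, z,
                 angle = atan2(dir[2], dir[1]), slot = slot, ring = c_r)
    }
  }
  ## Intra-CSU ring members: monomer 0's P5 serves ToD 0 in ring L, monomer
  ## 1's P5 serves ToD 1 in ring R; the core CheWs take the opposite slots.
  rows[[length(rows) + 1]] <- ring_member_row("CHEA_P5", 0, 0, rings$L, (v[1, ] + rings$L) / 2, z)
  rows[[length(rows) + 1]] <- ring_member_row("CHEA_P5", 1, 1, rings$R, (v[2, ] + rings$R) / 2, z)
  rows[[length(rows) + 1]] <- ring_member_row("CHEW_CORE", 0, 1, rings$L, (v[2, ] + rings$L) / 2, z)
  rows[[length(rows) + 1]] <- ring_member_row("CHEW_CORE", 0, 0, rings$R, (v[1, ] + rings$R) / 2, z)
  ## CheA body: P3 dimerisation site on the C2 axis; P4, P2-P3 linker end
  ## and ATP lid per monomer along the centre-to-P5 directions.
  p5 <- rbind((v[1, ] + rings$L) / 2, (v[2, ] + rings$R) / 2)
  rows[[length(rows) + 1]] <- site_row("CHEA_P3", 0, 0, c(0, 0), z, angle = 0)
  for (m in 0:1) {
    rows[[length(rows) + 1]] <- site_row("CHEA_P4", m, m, 0.55 * p5[m + 1, ], z, angle = 0)
    rows[[length(rows) + 1]] <- site_row("CHEA_LINKER_ANCHOR", m, m, 0.20 * p5[m + 1, ], z, angle = 0)
    rows[[length(rows) + 1]] <- site_row("CHEA_ATP_SITE", m, m, 0.72 * p5[m + 1, ], z, angle = 0)
  }
  sites <- do.call(rbind, rows)
  sites$site_id <- seq_len(nrow(sites))
  tmpl <- structure(list(sites = sites, geometry = geometry,
                         flank_occupancy = c(FALSE, FALSE)),
                    class = "csu_template")
  add_flanking_chew(tmpl, flank_occupancy)
}

## The bare receptor rows of a site table: receptor dimers whose binding
## slot holds no baseplate ring member.
bare_receptors <- function(sites, tol = 1e-6) {
  mcp <- sites[sites$kind == "MCP_DIMER", , drop = FALSE]
  members <- sites[sites$kind %in% RING_KINDS, , drop = FALSE]
  if (nrow(members) == 0) return(mcp)
  bare <- vapply(seq_len(nrow(mcp)), function(i) {
    d2 <- (members$x - mcp$slot_x[i])^2 + (members$y - mcp$slot_y[i])^2
    all(d2 > tol^2)
  }, logical(1))
  mcp[bare, , drop = FALSE]
}

## Build a flanking-CheW row bound to one bare receptor row (planar frame).
flank_row_for <- function(mcp_row, z) {
  ring_c <- c(mcp_row$ring_x, mcp_row$ring_y)
  pos <- c(mcp_row$slot_x, mcp_row$slot_y)
  r <- ring_member_row("CHEW_FLANK", 0, mcp_row$tod_id, ring_c, pos, z)
  r$csu_id <- mcp_row$csu_id
  r
}

#' Add flanking CheW monomers to the bare receptors of a CSU template
#'
#' Each ToD of a CSU has one receptor dimer bound to neither CheA.P5 nor a
#' core CheW (a "bare" receptor).  This places a flanking CheW at the
#' binding slot of that dimer, mirroring the core-CheW geometry under the
#' CSU two-fold axis.
#'
#' @param template a \code{\link{build_csu_template}} result.
#' @param occupancy logical pair, one flag per ToD.
#' @return the extended \code{csu_template}.
#' @export
add_flanking_chew <- function(template, occupancy) {
  stopifnot(inherits(template, "csu_template"))
  occupancy <- as.logical(occupancy)
  if (length(occupancy) != 2 || anyNA(occupancy))
    stop_param("'occupancy' must be a pair of logicals")
  if (any(occupancy & template$flank_occupancy))
    stop("flanking-CheW slot already filled on the requested ToD",
         call. = FALSE)
  if (!any(occupancy)) return(template)
  z <- -template$geometry$baseplate_z
  bare <- bare_receptors(template$sites)
  new_rows <- list()
  for (tod in which(occupancy) - 1L) {
    b <- bare[bare$tod_id == tod, , drop = FALSE]
    if (nrow(b) != 1)
      stop("no unique bare receptor on ToD ", tod, call. = FALSE)
    new_rows[[length(new_rows) + 1]] <- flank_row_for(b[1, ], z)
  }
  sites <- rbind(template$sites, do.call(rbind, new_rows))
  sites$site_id <- seq_len(nrow(sites))
  template$sites <- sites
  template$flank_occupancy <- template$flank_occupancy | occupancy
  template
}

#' Rigidly place a CSU template in the lattice plane
#'
#' Applies an in-plane rotation followed by a translation to every site,
#' including half-site bearings, binding slots and ring-centre annotations,
#' and stamps a fresh CSU identifier.
#'
#' @param template a \code{csu_template}.
#' @param rotation in-plane rotation in radians (counter-clockwise).
#' @param translation length-2 numeric, Angstrom.
#' @param csu_id integer identifier to assign.
#' @return a data frame of placed component sites.
#' @export
place_csu <- function(template, rotation = 0, translation = c(0, 0),
                      csu_id = 1L) {
  stopifnot(inherits(template, "csu_template"))
  s <- template$sites
  R <- rot2(rotation)
  xy <- cbind(s$x, s$y) %*% t(R)
  s$x <- xy[, 1] + translation[1]
  s$y <- xy[, 2] + translation[2]
  s$u <- s$x; s$v <- s$y
  s$angle <- s$angle + rotation
  for (pref in c("b1", "b2")) {
    bx <- s[[paste0(pref, "x")]]; by <- s[[paste0(pref, "y")]]
    ok <- !is.na(bx)
    if (any(ok)) {
      b <- cbind(bx[ok], by[ok]) %*% t(R)
      s[[paste0(pref, "x")]][ok] <- b[, 1]
      s[[paste0(pref, "y")]][ok] <- b[, 2]
    }
  }
  for (pref in c("slot_", "ring_")) {
    px <- s[[paste0(pref, "x")]]; py <- s[[paste0(pref, "y")]]
    ok <- !is.na(px)
    if (any(ok)) {
      p <- cbind(px[ok], py[ok]) %*% t(R)
      s[[paste0(pref, "x")]][ok] <- p[, 1] + translation[1]
      s[[paste0(pref, "y")]][ok] <- p[, 2] + translation[2]
    }
  }
  s$csu_id <- as.integer(csu_id)
  s
}

#' @export
print.csu_template <- function(x, ...) {
  counts <- table(x$sites$kind)
  cat("Core-signalling unit template\n")
  cat("  lattice constant a:", x$geometry$a, "A; baseplate depth:",
      x$geometry$baseplate_z, "A\n")
  cat("  flanking CheW occupancy:", paste(x$flank_occupancy, collapse = ", "), "\n")
  cat("  sites:", nrow(x$sites), "(",
      paste(names(counts), as.integer(counts), collapse = ", "), ")\n")
  invisible(x)
}
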