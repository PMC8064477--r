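## Rotational-symmetry scoring and p2/p6 classification of density images.
##
## The decisive signature of the p6 architecture is genuine three- and
## six-fold rotational self-similarity about ring centres; a p2 baseplate
## shows strong two-fold similarity only.  Two-fold similarity is high for
## BOTH architectures (every CSU centre and ring centre is a two-fold
## axis), which is why symmetrised averages can hide a p2 form -- the
## classifier therefore scores the two-fold evidence *not explained by* a
## higher rotation order.

## FFT Gaussian smoothing of a matrix grid (sigma in pixels).
gauss_smooth_grid <- function(g, sigma_px) {
  nx <- nrow(g); ny <- ncol(g)
  NX <- stats::nextn(nx + 4 * ceiling(sigma_px) + 1, 2)
  NY <- stats::nextn(ny + 4 * ceiling(sigma_px) + 1, 2)
  G <- matrix(0, NX, NY); G[seq_len(nx), seq_len(ny)] <- g
  kx <- c(0:(NX / 2), -((NX / 2 - 1):1)) / NX
  ky <- c(0:(NY / 2), -((NY / 2 - 1):1)) / NY
  H <- exp(-2 * pi^2 * sigma_px^2 * outer(kx^2, ky^2, "+"))
  Re(stats::fft(stats::fft(G) * H, inverse = TRUE))[seq_len(nx),
                                                    seq_len(ny)] / (NX * NY)
}

#' Rotational self-correlation of an image about a centre
#'
#' Mean Pearson correlation between the image and its rotations by
#' k*360/n degrees (k = 1..n-1) about \code{centre}, evaluated on a disc.
#' Rotated values are sampled by bilinear interpolation; the disc must lie
#' far enough inside the frame that no rotated sample leaves it.
#'
#' @param image a \code{\link{density_image}}.
#' @param centre length-2 physical coordinate (Angstrom).
#' @param n rotation order (2, 3 or 6).
#' @param disc_radius evaluation disc radius, Angstrom.
#' @return correlation score in \[-1, 1\].
#' @export
rotational_correlation <- function(image, centre, n, disc_radius) {
  stopifnot(inherits(image, "density_image"))
  if (!n %in% c(2, 3, 6)) stop_param("rotation order n must be 2, 3 or 6")
  px <- image$pixel_size
  nx <- nrow(image$grid); ny <- ncol(image$grid)
  xmax <- image$origin[1] + (nx - 1) * px
  ymax <- image$origin[2] + (ny - 1) * px
  if (centre[1] - disc_radius < image$origin[1] ||
      centre[1] + disc_radius > xmax ||
      centre[2] - disc_radius < image$origin[2] ||
      centre[2] + disc_radius > ymax)
    stop("evaluation disc exceeds the image frame", call. = FALSE)
  rr <- ceiling(disc_radius / px)
  ci <- img_index(image, centre[1], centre[2])
  ix0 <- round(ci$ix); iy0 <- round(ci$iy)
  ix <- (ix0 - rr):(ix0 + rr); iy <- (iy0 - rr):(iy0 + rr)
  gx <- image$origin[1] + (ix - 1) * px
  gy <- image$origin[2] + (iy - 1) * px
  X <- matrix(rep(gx, length(gy)), length(gx))
  Y <- matrix(rep(gy, each = length(gx)), length(gx))
  disc <- (X - centre[1])^2 + (Y - centre[2])^2 <= disc_radius^2
  xs <- X[disc]; ys <- Y[disc]
  ref <- bilinear(image$grid, (xs - image$origin[1]) / px + 1,
                  (ys - image$origin[2]) / px + 1)
  cors <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    th <- -2 * pi * k / n          # sample source: inverse rotation
    rx <- centre[1] + cos(th) * (xs - centre[1]) - sin(th) * (ys - centre[2])
    ry <- centre[2] + sin(th) * (xs - centre[1]) + cos(th) * (ys - centre[2])
    rot <- bilinear(image$grid, (rx - image$origin[1]) / px + 1,
                    (ry - image$origin[2]) / px + 1)
    cors[k] <- if (stats::sd(ref) < 1e-12 || stats::sd(rot) < 1e-12) 0
               else stats::cor(ref, rot)
  }
  mean(cors)
}

#' Locate candidate ring centres in a baseplate image
#'
#' Ring centres are local density minima surrounded by a high-density
#' annulus of ring members.  Scores every pixel by (mean density on an
#' annulus of radius \code{spacing}/(2 sqrt 3)) minus (density at the
#' centre, smoothed), and returns the strongest well-separated peaks whose
#' evaluation disc of radius \code{disc_radius} fits in the frame.
#'
#' @param image a \code{density_image}.
#' @param spacing expected ring-lattice spacing (the lattice constant),
#'   Angstrom.
#' @param n_centres maximum number of centres returned.
#' @param disc_radius required clearance from the frame edge, Angstrom
#'   (default 1.5 spacing, matching the classifier's disc).
#' @return matrix with columns x, y (physical coordinates).
#' @export
find_ring_centres <- function(image, spacing, n_centres = 9,
                              disc_radius = 1.5 * spacing) {
  stopifnot(inherits(image, "density_image"))
  px <- image$pixel_size
  r_ann <- spacing / (2 * sqrt(3))
  ## annulus and centre-disc kernels, applied by FFT convolution; the
  ## centre disc is wide enough that density from the CheA body parked at
  ## CSU centres (a competing low-density locus) is penalised
  rr <- ceiling((r_ann + 2 * px) / px)
  ix <- -rr:rr
  R2 <- outer(ix^2, ix^2, "+") * px^2
  ann <- (R2 >= (r_ann - 2 * px)^2) & (R2 <= (r_ann + 2 * px)^2)
  ctr <- R2 <= (0.6 * r_ann)^2
  conv2 <- function(g, kern) {
    nx <- nrow(g) + nrow(kern) - 1; ny <- ncol(g) + ncol(kern) - 1
    G <- matrix(0, nx, ny); G[seq_len(nrow(g)), seq_len(ncol(g))] <- g
    K <- matrix(0, nx, ny); K[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
    full <- Re(stats::fft(stats::fft(G) * stats::fft(K), inverse = TRUE)) / (nx * ny)
    off <- (nrow(kern) - 1) / 2
    full[off + seq_len(nrow(g)), off + seq_len(ncol(g))]
  }
  contrast <- conv2(image$grid, ann / sum(ann)) -
              conv2(image$grid, ctr / sum(ctr))
  ## restrict to pixels with clearance for the correlation disc plus a
  ## guard band (discs grazing the patch boundary lose symmetry to the
  ## asymmetric empty border)
  nx <- nrow(contrast); ny <- ncol(contrast)
  m <- ceiling((disc_radius + 0.3 * spacing) / px) + 1
  ok <- matrix(FALSE, nx, ny)
  if (nx > 2 * m && ny > 2 * m)
    ok[(m + 1):(nx - m), (m + 1):(ny - m)] <- TRUE
  if (!any(ok)) stop("image too small for the requested clearance",
                     call. = FALSE)
  ## exclude candidates outside the rendered patch: annulus kernels
  ## clipping the patch edge (or the empty corners framing a rotated
  ## patch) can score spuriously high in low-density surroundings
  rr2 <- ceiling(2 * r_ann / px)
  ix2 <- -rr2:rr2
  big <- outer(ix2^2, ix2^2, "+") * px^2 <= (2 * r_ann)^2
  dens <- conv2(image$grid, big / sum(big))
  dens_ref <- stats::quantile(dens[ok], 0.9)
  gated <- contrast
  gated[!ok | dens < 0.5 * dens_ref] <- -Inf
  if (!any(is.finite(gated))) { gated <- contrast; gated[!ok] <- -Inf }
  sep2 <- (0.6 * spacing / px)^2
  top_peaks <- function(cmap, n) {
    cand <- order(cmap, decreasing = TRUE)
    picks <- matrix(numeric(0), 0, 2)
    for (idx in cand) {
      if (nrow(picks) >= n || !is.finite(cmap[idx])) break
      i <- (idx - 1) %% nx + 1; j <- (idx - 1) %/% nx + 1
      if (nrow(picks) &&
          any((picks[, 1] - i)^2 + (picks[, 2] - j)^2 < sep2)) next
      picks <- rbind(picks, c(i, j))
    }
    picks
  }
  ## The ring centres form a hexagonal lattice of the given spacing; pin
  ## the candidate set to that lattice.  Lattice vectors come from the
  ## image's own autocorrelation (rotation-aware); the lattice phase is
  ## chosen as the anchor peak whose lattice translates show the best
  ## median ring contrast.
  latvec <- tryCatch({
    ap <- autocorrelation_periodicity(image, rel_threshold = 0.6)
    pk <- ap$peaks
    r <- sqrt(pk$dx^2 + pk$dy^2)
    near <- which(abs(r - ap$spacing) < 0.2 * ap$spacing)
    p1 <- near[which.min(r[near])]
    ang1 <- atan2(pk$dy[p1], pk$dx[p1])
    dang <- (atan2(pk$dy[near], pk$dx[near]) - ang1) * 180 / pi
    dang <- ((dang + 180) %% 360) - 180
    p2 <- near[which(abs(abs(dang) - 60) < 20)][1]
    if (is.na(p2)) NULL
    else rbind(c(pk$dx[p1], pk$dy[p1]), c(pk$dx[p2], pk$dy[p2]))
  }, error = function(e) NULL)
  anchors <- top_peaks(gated, 8)
  if (nrow(anchors) == 0) stop("no ring centres found", call. = FALSE)
  to_xy <- function(p) c(image$origin[1] + (p[1] - 1) * px,
                         image$origin[2] + (p[2] - 1) * px)
  contrast_at <- function(xy) {
    i <- round((xy[1] - image$origin[1]) / px) + 1
    j <- round((xy[2] - image$origin[2]) / px) + 1
    if (i < 1 || i > nx || j < 1 || j > ny) return(-Inf)
    gated[i, j]
  }
  if (!is.null(latvec)) {
    rng <- -4:4
    best <- NULL; best_score <- -Inf
    for (ai in seq_len(nrow(anchors))) {
      a_xy <- to_xy(anchors[ai, ])
      fam <- list(); vals <- numeric()
      for (i in rng) for (j in rng) {
        xy <- a_xy + i * latvec[1, ] + j * latvec[2, ]
        v <- contrast_at(xy)
        if (is.finite(v)) { fam[[length(fam) + 1]] <- xy; vals <- c(vals, v) }
      }
      if (length(fam) < 3) next
      sc <- stats::median(vals)
      if (sc > best_score) {
        best_score <- sc
        ord <- order(vals, decreasing = TRUE)
        best <- do.call(rbind, fam[ord[seq_len(min(n_centres,
                                                   length(fam)))]])
      }
    }
    if (!is.null(best)) return(cbind(x = best[, 1], y = best[, 2]))
  }
  picks <- top_peaks(gated, n_centres)
  if (nrow(picks) < 3) {                  # last resort: ungated interior
    ungated <- contrast
    ungated[!ok] <- -Inf
    picks <- top_peaks(ungated, max(3, n_centres))
  }
  if (nrow(picks) == 0) stop("no ring centres found", call. = FALSE)
  cbind(x = image$origin[1] + (picks[, 1] - 1) * px,
        y = image$origin[2] + (picks[, 2] - 1) * px)
}

#' Classify a baseplate image as p2 or p6 by rotational self-similarity
#'
#' Scores two-, three- and six-fold rotational correlations about each
#' candidate ring centre and aggregates them by medians: the six-fold
#' evidence is \code{median(min(C3, C6))} and the residual two-fold-only
#' evidence is \code{median(C2 - min(C3, C6))}.  The patch is assigned P6
#' or P2 when one evidence exceeds the other by the decision margin, and
#' AMBIGUOUS otherwise (explicit abstention on noisy patches).
#'
#' @param image a \code{density_image}.
#' @param candidate_centres matrix with columns x, y (at least 3 rows),
#'   e.g. from \code{\link{find_ring_centres}}.
#' @param spacing ring-lattice spacing in Angstrom (used for the default
#'   disc radius and the periodicity estimate).
#' @param disc_radius correlation disc radius, Angstrom (default
#'   1.5 spacing).
#' @param margin decision margin in correlation units (default 0.15).
#' @param presmooth Gaussian pre-smoothing width in Angstrom applied
#'   before scoring (matched filtering: white noise attenuates the Pearson
#'   correlations, pre-smoothing restores them without moving the rotation
#'   centres).  Default spacing/16; set 0 to disable.
#' @return object of class \code{symmetry_report}: per-centre scores,
#'   aggregate evidences, \code{assigned} in \{"P2","P6","AMBIGUOUS"\} and
#'   \code{periodicity_estimate} (NA when not computable).
#' @export
classify_symmetry <- function(image, candidate_centres, spacing,
                              disc_radius = 1.5 * spacing, margin = 0.15,
                              presmooth = spacing / 16) {
  stopifnot(inherits(image, "density_image"))
  candidate_centres <- as.matrix(candidate_centres)
  if (nrow(candidate_centres) < 3)
    stop_param("need at least 3 candidate centres")
  if (presmooth > 0)
    image$grid <- gauss_smooth_grid(image$grid, presmooth / image$pixel_size)
  sc <- data.frame(x = candidate_centres[, 1], y = candidate_centres[, 2],
                   C2 = NA_real_, C3 = NA_real_, C6 = NA_real_)
  for (i in seq_len(nrow(sc))) {
    ctr <- c(sc$x[i], sc$y[i])
    sc$C2[i] <- rotational_correlation(image, ctr, 2, disc_radius)
    sc$C3[i] <- rotational_correlation(image, ctr, 3, disc_radius)
    sc$C6[i] <- rotational_correlation(image, ctr, 6, disc_radius)
  }
  ## uninformative centres (no self-similarity of any order, e.g.
  ## boundary-degraded picks) dilute the medians; drop them when enough
  ## informative centres remain
  informative <- pmax(sc$C2, sc$C3, sc$C6) >= 0.3
  use <- if (sum(informative) >= 3) sc[informative, ] else sc
  s6 <- stats::median(pmin(use$C3, use$C6))
  s2only <- stats::median(use$C2 - pmin(use$C3, use$C6))
  assigned <- if (s6 - s2only >= margin) "P6"
              else if (s2only - s6 >= margin) "P2"
              else "AMBIGUOUS"
  per <- tryCatch(autocorrelation_periodicity(image)$spacing,
                  error = function(e) NA_real_)
  structure(list(scores = sc, evidence_p6 = s6, evidence_p2 = s2only,
                 margin = margin, disc_radius = disc_radius,
                 assigned = assigned, periodicity_estimate = per),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat("Symmetry classification:", x$assigned, "\n")
  cat("  evidence p6 (median min(C3,C6)):", round(x$evidence_p6, 3),
      "; p2-only (median C2 - min(C3,C6)):", round(x$evidence_p2, 3),
      "; margin:", x$margin, "\n")
  cat("  centres scored:", nrow(x$scores),
      "; periodicity estimate:", round(x$periodicity_estimate, 2), "A\n")
  invisible(x)
}

#' Lattice periodicity by image autocorrelation
#'
#' Computes the 2D autocorrelation of the mean-subtracted image via FFT,
#' locates the significant off-origin peak nearest the origin, refines it
#' to sub-pixel precision by separable quadratic interpolation, and
#' returns the origin-to-peak spacing plus the in-plane angles of up to
#' six nearest significant peaks.
#'
#' The autocorrelation is normalised by the overlap area of the finite
#' frame at each shift (unbiased estimate), so a true lattice translation
#' scores near 1 irrespective of patch size, while pseudo-translations
#' (e.g. the half-period shift that partially exchanges receptor and ring
#' sublattices) score distinctly lower.  "Significant" is therefore
#' defined relative to the strongest off-origin peak.
#'
#' @param image a \code{density_image} covering at least ~4 lattice
#'   periods.
#' @param min_spacing peaks closer to the origin than this many pixels
#'   are ignored (suppresses the origin blob); default 8.
#' @param rel_threshold significance threshold relative to the strongest
#'   off-origin peak (default 0.8).
#' @return list with \code{spacing} (Angstrom), \code{angles_deg} of the
#'   nearest peaks, and the peak table.
#' @export
autocorrelation_periodicity <- function(image, min_spacing = NULL,
                                        rel_threshold = 0.8) {
  stopifnot(inherits(image, "density_image"))
  px <- image$pixel_size
  g <- image$grid - mean(image$grid)
  nx <- nrow(g); ny <- ncol(g)
  ## zero-pad to avoid wraparound
  NX <- stats::nextn(2 * nx, 2); NY <- stats::nextn(2 * ny, 2)
  G <- matrix(0, NX, NY); G[seq_len(nx), seq_len(ny)] <- g
  F <- stats::fft(G)
  A <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / (NX * NY)
  ## overlap (support) autocorrelation for the unbiased normalisation
  Msk <- matrix(0, NX, NY); Msk[seq_len(nx), seq_len(ny)] <- 1
  FM <- stats::fft(Msk)
  M <- Re(stats::fft(FM * Conj(FM), inverse = TRUE)) / (NX * NY)
  valid <- M >= 0.25 * M[1, 1]
  A <- ifelse(valid, A / pmax(M, 1), 0)
  A <- A / A[1, 1]
  ## recentre: shift index k corresponds to displacement (k-1) with wrap
  sx <- c((NX / 2 + 1):NX, 1:(NX / 2))
  sy <- c((NY / 2 + 1):NY, 1:(NY / 2))
  Ac <- A[sx, sy]
  cx <- NX / 2 + 1; cy <- NY / 2 + 1
  if (is.null(min_spacing)) min_spacing <- 8
  ## off-origin local maxima
  peaks <- NULL
  for (i in 2:(NX - 1)) {
    row <- Ac[i, 2:(NY - 1)]
    cand <- which(row > 0 &
                  row > Ac[i - 1, 2:(NY - 1)] & row > Ac[i + 1, 2:(NY - 1)] &
                  row >= Ac[i, 1:(NY - 2)] & row >= Ac[i, 3:NY]) + 1
    if (length(cand))
      peaks <- rbind(peaks, cbind(i, cand, Ac[cbind(i, cand)]))
  }
  if (is.null(peaks)) stop("no significant autocorrelation peak",
                           call. = FALSE)
  dx <- peaks[, 1] - cx; dy <- peaks[, 2] - cy
  r <- sqrt(dx^2 + dy^2)
  sel <- r >= min_spacing
  if (any(sel)) {
    vmax <- max(peaks[sel, 3])
    sel <- sel & peaks[, 3] >= rel_threshold * vmax
  }
  if (!any(sel)) stop("no significant off-origin autocorrelation peak",
                      call. = FALSE)
  peaks <- peaks[sel, , drop = FALSE]
  dx <- dx[sel]; dy <- dy[sel]; r <- r[sel]
  ord <- order(r)
  nearest <- ord[1]
  ## sub-pixel quadratic refinement around the nearest peak
  refine <- function(i, j) {
    qx <- (Ac[i - 1, j] - Ac[i + 1, j]) /
          (2 * (Ac[i - 1, j] - 2 * Ac[i, j] + Ac[i + 1, j]))
    qy <- (Ac[i, j - 1] - Ac[i, j + 1]) /
          (2 * (Ac[i, j - 1] - 2 * Ac[i, j] + Ac[i, j + 1]))
    c(ifelse(is.finite(qx), qx, 0), ifelse(is.finite(qy), qy, 0))
  }
  q <- refine(peaks[nearest, 1], peaks[nearest, 2])
  spacing <- sqrt((dx[nearest] + q[1])^2 + (dy[nearest] + q[2])^2) * px
  near6 <- ord[seq_len(min(6, length(ord)))]
  list(spacing = spacing,
       angles_deg = rad2deg(atan2(dy[near6], dx[near6])),
       peaks = data.frame(dx = dx * px, dy = dy * px, value = peaks[, 3]))
}
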