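## Simplified template matching by exhaustive normalised cross-correlation.

## Rotate a volume's grid about its centre (trilinear resampling of the
## inverse mapping).  R is a 3x3 rotation matrix.
rotate_grid <- function(grid, R) {
  d <- dim(grid)
  ctr <- (d + 1) / 2
  idx <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
  rel <- sweep(idx, 2, ctr)
  src <- rel %*% R + rep(ctr, each = nrow(rel))   # inverse map: R^T forward
  out <- trilinear(grid, src[, 1], src[, 2], src[, 3])
  out[is.na(out)] <- 0
  array(out, dim = d)
}

## Orientation set for a grid search: in-plane rotations about z crossed
## with out-of-plane tilts about x, both at angular_step degrees.
orientation_grid <- function(angular_step) {
  if (angular_step >= 360)
    return(list(list(phi = 0, psi = 0, R = diag(3))))
  if (360 %% angular_step != 0)
    stop_param("angular_step must divide 360")
  phis <- seq(0, 360 - angular_step, by = angular_step)
  psis <- seq(0, 90, by = angular_step)
  out <- list()
  for (psi in psis) for (phi in phis) {
    out[[length(out) + 1]] <-
      list(phi = phi, psi = psi,
           R = rot3x(deg2rad(psi)) %*% rot3z(deg2rad(phi)))
  }
  out
}

## Fast NCC of a template against a volume via FFT (zero-mean template;
## local volume statistics over the template box from FFT box sums).
ncc_map <- function(vol, tmpl) {
  dv <- dim(vol); dt <- dim(tmpl)
  t0 <- tmpl - mean(tmpl)
  st <- sqrt(sum(t0^2))
  if (st == 0) return(array(0, dv))
  N <- prod(dv)
  pad <- function(a) {
    out <- array(0, dv)
    out[seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3])] <- a
    out
  }
  Fv <- stats::fft(vol)
  Fv2 <- stats::fft(vol^2)
  Ft <- stats::fft(pad(t0))
  Fb <- stats::fft(pad(array(1, dt)))
  xc <- Re(stats::fft(Fv * Conj(Ft), inverse = TRUE)) / N
  s1 <- Re(stats::fft(Fv * Conj(Fb), inverse = TRUE)) / N
  s2 <- Re(stats::fft(Fv2 * Conj(Fb), inverse = TRUE)) / N
  nt <- prod(dt)
  varl <- pmax(s2 - s1^2 / nt, 0)
  ncc <- xc / (sqrt(varl) * st)
  ncc[varl < 1e-12] <- 0
  ncc
}

#' Template matching by exhaustive normalised cross-correlation
#'
#' Scans the volume with the template over a grid of orientations
#' (in-plane and out-of-plane sampling at \code{angular_step} degrees, 12
#' by default) and reports local NCC maxima above \code{threshold} after
#' non-maximum suppression within one template radius.  Peak positions are
#' the template centre in physical coordinates.
#'
#' @param volume a \code{\link{volume_density}}.
#' @param template a smaller \code{volume_density} with the same voxel
#'   size.
#' @param angular_step orientation sampling in degrees (must divide 360;
#'   >= 360 searches the identity orientation only).
#' @param threshold minimum NCC score for a peak.
#' @return data frame of peaks: position (Angstrom), orientation angles
#'   (degrees) and \code{score}, strongest first.
#' @export
template_match <- function(volume, template, angular_step = 12,
                           threshold = 0.5) {
  stopifnot(inherits(volume, "volume_density"),
            inherits(template, "volume_density"))
  dv <- dim(volume$grid); dt <- dim(template$grid)
  if (any(dt >= dv)) stop_param("template must be smaller than the volume")
  if (abs(volume$voxel_size - template$voxel_size) >
      1e-6 * volume$voxel_size)
    stop_param("volume and template voxel sizes differ")
  best <- array(-Inf, dv)
  best_ori <- array(0L, dv)
  oris <- orientation_grid(angular_step)
  for (k in seq_along(oris)) {
    tg <- if (k == 1 && oris[[k]]$phi == 0 && oris[[k]]$psi == 0)
      template$grid else rotate_grid(template$grid, oris[[k]]$R)
    sc <- ncc_map(volume$grid, tg)
    upd <- sc > best
    best[upd] <- sc[upd]
    best_ori[upd] <- k
  }
  ## valid placements: template fully inside
  valid <- array(FALSE, dv)
  valid[seq_len(dv[1] - dt[1] + 1), seq_len(dv[2] - dt[2] + 1),
        seq_len(dv[3] - dt[3] + 1)] <- TRUE
  best[!valid] <- -Inf
  cand <- which(best >= threshold)
  if (!length(cand))
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      phi = numeric(), psi = numeric(), score = numeric()))
  ord <- cand[order(best[cand], decreasing = TRUE)]
  sup_r <- max(dt) / 2
  coords <- arrayInd(ord, dv)
  picked <- matrix(numeric(0), 0, 3)
  rows <- list()
  for (i in seq_along(ord)) {
    p <- coords[i, ]
    if (nrow(picked) &&
        any(rowSums(sweep(picked, 2, p)^2) < sup_r^2)) next
    picked <- rbind(picked, p)
    o <- oris[[best_ori[ord[i]]]]
    ctr <- p - 1 + (dt + 1) / 2 - 1       # template centre, 0-based voxels
    rows[[length(rows) + 1]] <- data.frame(
      x = volume$origin[1] + ctr[1] * volume$voxel_size,
      y = volume$origin[2] + ctr[2] * volume$voxel_size,
      z = volume$origin[3] + ctr[3] * volume$voxel_size,
      phi = o$phi, psi = o$psi, score = best[ord[i]])
  }
  do.call(rbind, rows)
}
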