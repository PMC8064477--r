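#' @keywords internal
"_PACKAGE"

## 2D rotation matrix (counter-clockwise, radians)
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

## normalize rows of an n x k matrix
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Fold an undirected in-plane axis angle difference into [0, 90] degrees.
axis_angle_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Deterministic per-key uniform deviates
#'
#' A small 32-bit mixing hash used wherever a reproducible random value is
#' needed per structural element (for example flanking-CheW occupancy per
#' trimer-of-dimers).  Keyed draws are independent of evaluation order,
#' unlike draws from R's global stream.
#'
#' @param seed integer global seed.
#' @param k1,k2 integer subkeys (e.g. unit id and position-within-unit).
#' @return numeric vector of deviates in \[0, 1).
#' @keywords internal
key_runif <- function(seed, k1, k2 = 0L) {
  m <- 2^31
  h <- (as.numeric(seed) %% m) * 2654435761 %% m
  h <- (h + (as.numeric(k1) %% m) * 40503 + 97) %% m
  h <- (h * 69069 + 1) %% m
  h <- (h + (as.numeric(k2) %% m) * 9973) %% m
  h <- (h * 1103515245 + 12345) %% m
  h <- (h * 69069 + 1) %% m
  h / m
}

## Derive a bounded integer sub-seed for set.seed() from a global seed and a
## stage label, keeping the result below 2^31.
derive_seed <- function(seed, stage) {
  chars <- utf8ToInt(stage)
  h <- as.numeric(seed) %% 2^31
  for (c in chars) h <- (h * 131 + c) %% (2^31 - 1)
  as.integer(h)
}

## Bilinear interpolation of a matrix grid at continuous index coordinates
## (1-based, ix along dim 1, iy along dim 2).  Out-of-range points give NA.
bilinear <- function(grid, ix, iy) {
  nx <- nrow(grid); ny <- ncol(grid)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  out <- rep(NA_real_, length(ix))
  if (!any(ok)) return(out)
  x <- pmin(pmax(ix[ok], 1), nx)
  y <- pmin(pmax(iy[ok], 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  v00 <- grid[cbind(x0, y0)]
  v10 <- grid[cbind(x0 + 1, y0)]
  v01 <- grid[cbind(x0, y0 + 1)]
  v11 <- grid[cbind(x0 + 1, y0 + 1)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
  out
}

## Trilinear interpolation of a 3D array at continuous index coordinates.
trilinear <- function(arr, ix, iy, iz) {
  d <- dim(arr)
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  out <- rep(NA_real_, length(ix))
  if (!any(ok)) return(out)
  x <- ix[ok]; y <- iy[ok]; z <- iz[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  g <- function(dx, dy, dz) arr[cbind(x0 + dx, y0 + dy, z0 + dz)]
  out[ok] <-
    g(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    g(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    g(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    g(1, 1, 0) * fx * fy * (1 - fz) +
    g(1, 0, 1) * fx * (1 - fy) * fz +
    g(0, 1, 1) * (1 - fx) * fy * fz +
    g(1, 1, 1) * fx * fy * fz
  out
}

## 3D rotation matrices about principal axes
rot3z <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
rot3x <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)

stop_param <- function(...) stop(..., call. = FALSE)
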