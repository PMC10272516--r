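## Single-sphere (Sarvas) forward model for planar gradiometers.
##
## The magnetic field of a current dipole q at r0 inside a spherically
## symmetric conductor, observed at r outside the sphere, is
##
##   B(r) = mu0/(4 pi F^2) * ( F (q x r0) - ((q x r0) . r) grad F )
##   F    = a (r a + r^2 - r0 . r),   a = |r - r0|, r = |r|
##   gradF = (a^2/r + (a.r)/a + 2a + 2r) r - (a + 2r + (a.r)/a) r0
##
## (all positions relative to the sphere centre).  The field does not depend
## on the conductivity profile, and a radial dipole (q parallel to r0) is
## silent.  A planar gradiometer channel is modelled as the two-point finite
## difference of the field component along the site normal, sampled at
## +/- baseline/2 along the channel's tangential axis, divided by the
## baseline; units are tesla/metre per (ampere metre).

MU0_4PI <- 1e-7

## B at `points` (m x 3, absolute coords) for the three unit moments of a
## dipole at `location`; returns list of three m x 3 matrices.
sarvas_unit_fields <- function(points, location, center) {
  r <- sweep(points, 2, center)
  r0 <- as.numeric(location) - center
  av <- sweep(r, 2, r0)                     # a = r - r0
  a <- sqrt(rowSums(av^2))
  rn <- sqrt(rowSums(r^2))
  ar <- rowSums(av * r)
  r0r <- as.numeric(r %*% r0)
  F <- a * (rn * a + rn^2 - r0r)
  k1 <- a^2 / rn + ar / a + 2 * a + 2 * rn
  k2 <- a + 2 * rn + ar / a
  gradF <- k1 * r - outer(k2, r0)
  ey <- diag(3)
  lapply(1:3, function(i) {
    ci <- cross3(ey[i, ], r0)
    cir <- as.numeric(r %*% ci)
    MU0_4PI * (outer(1 / F, ci) - (cir / F^2) * gradF)
  })
}

## Finite-difference evaluation geometry of an array: the field points
## (+/- baseline/2 along each channel's tangential axis), duplicated
## normals, and channel count.  Built once, reused across many lead-field
## evaluations (the nonlinear dipole search calls this in its inner loop).
fd_context <- function(array) {
  s <- array$channel_site
  ax1 <- array$ax1[s, , drop = FALSE]
  ax2 <- array$ax2[s, , drop = FALSE]
  ev <- ifelse(array$channel_axis == 1L, 1, 0) * ax1 +
    ifelse(array$channel_axis == 2L, 1, 0) * ax2
  pos <- array$site_pos[s, , drop = FALSE]
  nrm <- array$site_normal[s, , drop = FALSE]
  h <- array$baseline / 2
  list(pts = rbind(pos + h * ev, pos - h * ev), nn = rbind(nrm, nrm),
       nch = length(s), baseline = array$baseline)
}

leadfield_at <- function(head, ctx, location) {
  Bu <- sarvas_unit_fields(ctx$pts, location, head$center)
  nch <- ctx$nch
  L <- vapply(Bu, function(B) {
    bn <- rowSums(B * ctx$nn)
    (bn[seq_len(nch)] - bn[nch + seq_len(nch)]) / ctx$baseline
  }, numeric(nch))
  dimnames(L) <- NULL
  L
}

## Lead field of one dipole location: channels x 3 matrix, channel k row maps
## a moment (A m) to the planar gradient reading (T/m).
dipole_leadfield <- function(head, array, location)
  leadfield_at(head, fd_context(array), location)

check_inside <- function(head, location, what = "dipole location") {
  d <- sqrt(sum((as.numeric(location) - head$center)^2))
  if (!(d < head$radius))
    stop(sprintf("%s must lie strictly inside the head sphere (|r| = %.1f mm, radius = %.1f mm)",
                 what, 1e3 * d, 1e3 * head$radius))
  invisible(d)
}

#' Planar-gradient field of a current dipole in a spherical conductor
#'
#' Computes the signal of every gradiometer channel for a single current
#' dipole, using the closed-form spherical-conductor (Sarvas) field and a
#' two-point finite-difference gradiometer model.  The output is linear in
#' `moment`; radial dipoles are silent (zero on all channels).
#'
#' @param head a [head_model()].
#' @param array a [build_sensor_array()].
#' @param location dipole position (metres), strictly inside the sphere.
#' @param moment dipole moment vector (ampere metres).
#' @return Numeric vector of planar-gradient values (T/m), one per channel.
#' @export
dipole_field <- function(head, array, location, moment) {
  check_inside(head, location)
  if (min(sqrt(rowSums(sweep(array$site_pos, 2, head$center)^2))) <= head$radius)
    stop("sensor sites must lie outside the head sphere")
  as.numeric(dipole_leadfield(head, array, location) %*% as.numeric(moment))
}

#' Lead-field matrix over a source grid
#'
#' For every grid point, the three columns are the channel signals of unit
#' dipoles along x, y, z.  Columns are grouped per point: columns
#' `3 (i - 1) + 1:3` belong to point `i`.
#'
#' @param head,array,grid geometry objects.
#' @return Object of class `leadfield` with `matrix` (channels x 3 N),
#'   `grid`, and the generating `head`/`array`.
#' @export
leadfield_matrix <- function(head, array, grid) {
  stopifnot(inherits(grid, "source_grid"))
  n <- nrow(grid$points)
  if (n == 0L) stop("empty source grid")
  L <- matrix(NA_real_, n_channels(array), 3L * n)
  for (i in seq_len(n))
    L[, 3L * (i - 1L) + 1:3] <- dipole_leadfield(head, array, grid$points[i, ])
  structure(list(matrix = L, grid = grid, head = head, array = array,
                 cache = new.env(parent = emptyenv())),
            class = "leadfield")
}

## per-orientation slabs (channels x points), cached: the exhaustive dipole
## scan touches them once per fitted time point
lf_split <- function(lf) {
  if (is.null(lf$cache)) lf$cache <- new.env(parent = emptyenv())
  sp <- lf$cache$split
  if (is.null(sp)) {
    N <- ncol(lf$matrix) / 3L
    sp <- list(Ax = lf$matrix[, seq(1L, 3L * N, by = 3L), drop = FALSE],
               Ay = lf$matrix[, seq(2L, 3L * N, by = 3L), drop = FALSE],
               Az = lf$matrix[, seq(3L, 3L * N, by = 3L), drop = FALSE])
    lf$cache$split <- sp
  }
  sp
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("Lead field: %d channels x %d sources (3 orientations each)\n",
              nrow(x$matrix), ncol(x$matrix) / 3))
  invisible(x)
}

lf_block <- function(lf, i) lf$matrix[, 3L * (i - 1L) + 1:3, drop = FALSE]

#' Principal source orientations of a lead-field block
#'
#' Returns the two right singular vectors with the largest singular values of
#' the channels x 3 lead-field block of one grid point.  In a spherical
#' conductor the third singular value is (numerically) zero: the radial
#' orientation is silent, and the two principal orientations span the
#' tangential plane.  These are the orientations used when simulating
#' benchmark dipoles.
#'
#' @param lf a [leadfield_matrix()] result.
#' @param point_index grid point index.
#' @return 3 x 2 matrix whose columns are orthonormal moment orientations,
#'   ordered by decreasing singular value (attribute `"d"` holds all three
#'   singular values).
#' @export
principal_orientations <- function(lf, point_index) {
  A <- lf_block(lf, point_index)
  s <- svd(A)
  if (s$d[1] <= 0 || !is.finite(s$d[1]) ||
      s$d[2] < 1e-12 * max(s$d[1], 1e-300))
    stop("degenerate lead field at this point (sphere centre?)")
  out <- s$v[, 1:2, drop = FALSE]
  attr(out, "d") <- s$d
  out
}
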