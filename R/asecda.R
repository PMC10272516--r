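## Automatic single equivalent current dipole analysis.
##
## At every time step of the averaged evoked field the algorithm:
##   1. combines each site's two planar gradiometers into one non-negative
##      value and smooths the 102-site pattern on the 2-D layout with a
##      Gaussian kernel of SD = min pairwise layout distance;
##   2. finds up to five local field maxima (Delaunay neighbourhoods),
##      keeps those above 10% of the global maximum, splits them by
##      hemisphere and keeps those above 75% of their hemisphere's maximum;
##   3. around each surviving maximum, fits a 1-D Gaussian to field value
##      vs. layout distance (over sites closer than 0.4) and selects all
##      sites within Rad_Cutoff = min(max(Sigma_Factor * sigma, Min_Rad),
##      Max_Rad);
##   4. fits a single dipole to the selected channels: an exhaustive linear
##      scan over the volumetric grid seeds a Nelder-Mead refinement of the
##      location, with the moment re-solved linearly at every step.
## Dipoles with field correlation >= 0.90 and relative residual variance
## < 0.20 are accepted; a spatiotemporal ranking (Gaussian kernels of 10 mm
## and 50 ms) then prunes isolated dipoles, keeping the top 70%.

#' Parameters of the automatic dipole algorithm
#'
#' Defaults are the published operating point of the method on
#' 204-gradiometer planar arrays; all distances in steps 1-3 are in the
#' normalized (unit-diameter) layout units of [project_layout()].
#'
#' @param sigma_factor,min_rad,max_rad channel-selection radius rule:
#'   `Rad_Cutoff = min(max(sigma_factor * sigma, min_rad), max_rad)`.
#' @param neighbor_distance_cap only sites closer than this to the central
#'   maximum enter the 1-D Gaussian fit.
#' @param max_maxima at most this many local maxima per time step.
#' @param global_fraction local maxima below this fraction of the global
#'   maximum are discarded.
#' @param hemisphere_fraction per-hemisphere retention fraction of the
#'   hemisphere's own maximum.
#' @param gof_min,rv_max dipole acceptance: field correlation >= `gof_min`
#'   and relative residual variance < `rv_max`.
#' @param sigma_s,sigma_t spatiotemporal ranking kernels (metres, seconds).
#' @param keep_fraction fraction of accepted dipoles retained by rank.
#' @param min_channels minimum selected channels for a determined fit.
#' @param midline pipe-exclusion half-width (metres): dipoles with fitted
#'   |x| below this are counted in neither hemisphere.
#' @return A list of class `ecd_params`.
#' @export
ecd_params <- function(sigma_factor = 1.0, min_rad = 0.1, max_rad = 0.25,
                       neighbor_distance_cap = 0.4, max_maxima = 5L,
                       global_fraction = 0.10, hemisphere_fraction = 0.75,
                       gof_min = 0.90, rv_max = 0.20,
                       sigma_s = 0.010, sigma_t = 0.050,
                       keep_fraction = 0.70, min_channels = 8L,
                       midline = 0.002) {
  stopifnot(min_rad > 0, min_rad <= max_rad,
            global_fraction > 0, global_fraction <= 1,
            hemisphere_fraction > 0, hemisphere_fraction <= 1,
            sigma_s > 0, sigma_t > 0,
            keep_fraction > 0, keep_fraction <= 1)
  structure(as.list(environment()), class = "ecd_params")
}

#' Gaussian smoothing of site values on the 2-D layout
#'
#' Normalized Gaussian kernel smoothing with SD equal to the layout's
#' minimum pairwise site distance:
#' `smoothed_i = sum_j K(d_ij) v_j / sum_j K(d_ij)`.
#'
#' @param values non-negative site values (length = number of sites).
#' @param layout a [project_layout()] result.
#' @return Smoothed site values.
#' @export
smooth_layout <- function(values, layout) {
  W <- layout_smoother(layout)
  as.numeric(W %*% values)
}

layout_smoother <- function(layout) {
  if (!is.null(layout$smooth_w)) return(layout$smooth_w)
  sd <- layout$pairwise_min_distance
  D2 <- as.matrix(stats::dist(layout$coords))^2
  K <- exp(-D2 / (2 * sd^2))
  K / rowSums(K)
}

#' Local field maxima per hemisphere
#'
#' A site is a local maximum if its smoothed value is >= that of all its
#' Delaunay neighbours.  The strongest `max_maxima` with value at least
#' `global_fraction` of the global maximum are kept, split by hemisphere
#' (sign of the layout left-right coordinate), and within each hemisphere
#' only maxima at `hemisphere_fraction` of that hemisphere's maximum
#' survive.  Ties are broken towards lower site index.
#'
#' @param smoothed smoothed site values; `layout` the layout;
#'   `params` an [ecd_params()].
#' @return `list(left = , right = )` of site indices (possibly empty).
#' @export
find_local_maxima <- function(smoothed, layout, params = ecd_params()) {
  n <- length(smoothed)
  adj <- layout$adjacency
  eps <- .Machine$double.eps
  is_max <- vapply(seq_len(n), function(i) {
    smoothed[i] > eps && all(smoothed[i] >= smoothed[adj[[i]]])
  }, logical(1))
  cand <- which(is_max)
  if (!length(cand)) return(list(left = integer(0), right = integer(0)))
  gmax <- max(smoothed)
  cand <- cand[smoothed[cand] >= params$global_fraction * gmax]
  ord <- cand[order(-smoothed[cand], cand)]
  keep <- utils::head(ord, params$max_maxima)
  lr <- layout$coords[keep, 1]
  out <- list(left = keep[lr < 0], right = keep[lr >= 0])
  for (h in c("left", "right")) {
    if (length(out[[h]])) {
      hm <- max(smoothed[out[[h]]])
      out[[h]] <- sort(out[[h]][smoothed[out[[h]]] >=
                                  params$hemisphere_fraction * hm])
    }
  }
  out
}

#' Channel-subset selection around a field maximum
#'
#' Fits `v(d) = a exp(-d^2 / (2 sigma^2))` by least squares to the smoothed
#' site values against layout distance from the central site, over sites
#' with `d <= neighbor_distance_cap`, and returns both gradiometer channels
#' of every site with `d < Rad_Cutoff` (Rad_Cutoff clamped to
#' `[min_rad, max_rad]`).  If the profile does not decrease with distance
#' the fit is abandoned and `sigma = min_rad` is used.
#'
#' @param central_site site index of the maximum.
#' @param smoothed smoothed site values; `layout`, `params` as above.
#' @return list with `channels` (channel indices), `sites`, `sigma`,
#'   `rad_cutoff`, `fallback` (logical).
#' @export
select_channel_subset <- function(central_site, smoothed, layout,
                                  params = ecd_params()) {
  d <- sqrt(rowSums(sweep(layout$coords, 2,
                          layout$coords[central_site, ])^2))
  use <- d <= params$neighbor_distance_cap
  v <- smoothed[use]; du <- d[use]
  fallback <- FALSE
  sigma <- params$min_rad
  if (sum(use) >= 3 && stats::sd(v) > 0 &&
      stats::cor(v, -du^2) > 0) {
    sse <- function(s) {
      w <- exp(-du^2 / (2 * s^2))
      a <- sum(w * v) / sum(w^2)
      sum((v - a * w)^2)
    }
    sigma <- stats::optimize(sse, c(1e-3, 2))$minimum
  } else fallback <- TRUE
  rad <- min(max(params$sigma_factor * sigma, params$min_rad),
             params$max_rad)
  sites <- which(d < rad)
  list(channels = which(layout_site_index(layout) %in% sites),
       sites = sites, sigma = sigma, rad_cutoff = rad, fallback = fallback)
}

## channel -> site mapping implied by the layout (2 channels per site)
layout_site_index <- function(layout) rep(seq_len(layout$n_sites), each = 2L)

## least-squares dipole moment and residual for a channels x 3 lead field
solve_moment <- function(A, b) {
  s <- svd(A)
  tol <- max(s$d) * 1e-10
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  m <- s$v %*% (dinv * crossprod(s$u, b))
  pred <- A %*% m
  list(moment = as.numeric(m), pred = as.numeric(pred),
       rv = sum((b - pred)^2) / sum(b^2))
}

## restrict a sensor array to a subset of sites
array_subset_sites <- function(array, sites) {
  structure(list(site_pos = array$site_pos[sites, , drop = FALSE],
                 site_normal = array$site_normal[sites, , drop = FALSE],
                 ax1 = array$ax1[sites, , drop = FALSE],
                 ax2 = array$ax2[sites, , drop = FALSE],
                 baseline = array$baseline,
                 helmet_radius = array$helmet_radius, center = array$center,
                 n_sites = length(sites),
                 channel_names = array$channel_names[array$channel_site %in% sites],
                 channel_site = rep(seq_along(sites), each = 2L),
                 channel_axis = rep(c(1L, 2L), length(sites))),
            class = "sensor_array")
}

## vectorized whole-grid scan: per-point linear LS residual of b against the
## selected-channel lead-field triplet; 3x3 systems solved in closed form
## with a tiny ridge (the radial direction is silent, so the Gram matrix is
## rank 2; the ridge only suppresses the null direction).
grid_scan <- function(lf, sel, b) {
  sp <- lf_split(lf)
  Ax <- sp$Ax[sel, , drop = FALSE]
  Ay <- sp$Ay[sel, , drop = FALSE]
  Az <- sp$Az[sel, , drop = FALSE]
  gxx <- colSums(Ax^2); gyy <- colSums(Ay^2); gzz <- colSums(Az^2)
  gxy <- colSums(Ax * Ay); gxz <- colSums(Ax * Az); gyz <- colSums(Ay * Az)
  cx <- as.numeric(crossprod(Ax, b))
  cy <- as.numeric(crossprod(Ay, b))
  cz <- as.numeric(crossprod(Az, b))
  eps <- 1e-12 * (gxx + gyy + gzz)
  gxx <- gxx + eps; gyy <- gyy + eps; gzz <- gzz + eps
  a11 <- gyy * gzz - gyz^2
  a12 <- gxz * gyz - gxy * gzz
  a13 <- gxy * gyz - gxz * gyy
  a22 <- gxx * gzz - gxz^2
  a23 <- gxy * gxz - gxx * gyz
  a33 <- gxx * gyy - gxy^2
  det <- gxx * a11 + gxy * a12 + gxz * a13
  mx <- (a11 * cx + a12 * cy + a13 * cz) / det
  my <- (a12 * cx + a22 * cy + a23 * cz) / det
  mz <- (a13 * cx + a23 * cy + a33 * cz) / det
  explained <- cx * mx + cy * my + cz * mz
  res <- sum(b^2) - explained
  list(residual = res, best = which.min(res))
}

#' Fit a single dipole to a selected channel subset
#'
#' Two stages: (1) every grid point is scanned with the dipole moment solved
#' by linear least squares against the selected-channel lead field; (2) the
#' best point seeds a derivative-free Nelder-Mead search over location (the
#' moment re-solved linearly at each step), constrained inside the sphere.
#'
#' @param b measured values of the selected channels (T/m).
#' @param head,array,grid geometry; `sel_channels` channel indices;
#'   `leadfield` a precomputed [leadfield_matrix()] (computed when `NULL`).
#' @param min_channels fits with fewer selected channels are refused.
#' @return list with `location`, `moment`, `gof` (Pearson correlation of
#'   predicted vs measured), `rv` (relative residual variance),
#'   `n_channels`; or `NULL` when under-determined.
#' @export
fit_single_dipole <- function(b, head, array, grid, sel_channels,
                              leadfield = NULL, min_channels = 8L) {
  if (length(sel_channels) < min_channels) return(NULL)
  if (is.null(leadfield)) leadfield <- leadfield_matrix(head, array, grid)
  if (sum(b^2) == 0) return(NULL)
  scan <- grid_scan(leadfield, sel_channels, b)
  p0 <- grid$points[scan$best, ]

  sites <- sort(unique(array$channel_site[sel_channels]))
  sub <- array_subset_sites(array, sites)
  ## order of channels in `sub` vs `sel_channels`: both site-major, axis
  ## H then V, and sel_channels always contains both channels of a site
  bs <- b[order(match(array$channel_site[sel_channels], sites),
                array$channel_axis[sel_channels])]
  rmax <- 0.995 * head$radius
  ctr <- head$center
  ctx <- fd_context(sub)
  bb <- sum(bs^2)
  obj <- function(p) {
    d <- sqrt(sum((p - ctr)^2))
    pen <- 0
    if (d >= rmax) {
      p <- ctr + (p - ctr) * (rmax * 0.999 / d)
      pen <- (d - rmax) * 100
    }
    A <- leadfield_at(head, ctx, p)
    ## closed-form ridge solve of the 3x3 Gram system (radial direction
    ## silent -> rank 2; ridge suppresses only the null direction)
    G <- crossprod(A)
    cc <- crossprod(A, bs)
    G <- G + diag(1e-12 * sum(diag(G)), 3)
    m <- solve(G, cc)
    max(0, (bb - sum(cc * m))) / bb + pen
  }
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-9,
                                     parscale = rep(grid$spacing, 3)))
  p <- opt$par
  d <- sqrt(sum((p - ctr)^2))
  if (d >= rmax) p <- ctr + (p - ctr) * (rmax * 0.999 / d)
  A <- dipole_leadfield(head, sub, p)
  fit <- solve_moment(A, bs)
  gof <- if (stats::sd(fit$pred) > 0 && stats::sd(bs) > 0)
    stats::cor(fit$pred, bs) else 0
  list(location = as.numeric(p), moment = fit$moment, gof = gof,
       rv = fit$rv, n_channels = length(sel_channels))
}

#' One-snapshot automatic dipole fitting path
#'
#' Runs steps 1-4 of the algorithm (combine, smooth, maxima, channel
#' subsets, dipole fits) on a single field snapshot and returns one row per
#' attempted fit with the acceptance decision.
#'
#' @param b full channel vector (length 2 x sites, T/m).
#' @param head,array,grid,layout geometry; `leadfield` optional precomputed
#'   lead field; `params` an [ecd_params()].
#' @return data.frame (possibly 0 rows) with columns site, x, y, z, qx, qy,
#'   qz, gof, rv, n_channels, accepted.
#' @export
fit_dipole_snapshot <- function(b, head, array, grid, layout,
                                leadfield = NULL, params = ecd_params()) {
  sv <- combine_planar(b, array)[, 1]
  sm <- smooth_layout(sv, layout)
  mx <- find_local_maxima(sm, layout, params)
  cand <- c(mx$left, mx$right)
  rows <- list()
  for (site in cand) {
    ss <- select_channel_subset(site, sm, layout, params)
    fit <- fit_single_dipole(b[ss$channels], head, array, grid,
                             ss$channels, leadfield,
                             min_channels = params$min_channels)
    if (is.null(fit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      site = site, x = fit$location[1], y = fit$location[2],
      z = fit$location[3], qx = fit$moment[1], qy = fit$moment[2],
      qz = fit$moment[3], gof = fit$gof, rv = fit$rv,
      n_channels = fit$n_channels,
      accepted = fit$gof >= params$gof_min && fit$rv < params$rv_max)
  }
  if (!length(rows))
    return(data.frame(site = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), qx = numeric(0), qy = numeric(0),
                      qz = numeric(0), gof = numeric(0), rv = numeric(0),
                      n_channels = integer(0), accepted = logical(0)))
  do.call(rbind, rows)
}

#' Spatiotemporal ranking and pruning of accepted dipoles
#'
#' Each dipole's rank is the sum over all other dipoles of the product of
#' Gaussian kernels in 3-D distance (`sigma_s`) and latency difference
#' (`sigma_t`): spatiotemporally clustered dipoles rank high, isolated ones
#' low.  Dipoles at or above the `(1 - keep_fraction)` rank quantile are
#' retained (ties kept); a single dipole has rank 0 and is retained.
#'
#' @param dipoles data.frame with columns x, y, z (metres) and latency (s).
#' @param params an [ecd_params()].
#' @return `dipoles` with added `rank` and logical `retained` columns.
#' @export
rank_and_prune <- function(dipoles, params = ecd_params()) {
  n <- nrow(dipoles)
  if (n == 0L) return(cbind(dipoles, rank = numeric(0), retained = logical(0)))
  P <- as.matrix(dipoles[, c("x", "y", "z")])
  D2 <- as.matrix(stats::dist(P))^2
  T2 <- outer(dipoles$latency, dipoles$latency, `-`)^2
  G <- exp(-D2 / (2 * params$sigma_s^2)) * exp(-T2 / (2 * params$sigma_t^2))
  diag(G) <- 0
  rank <- rowSums(G)
  thr <- if (n == 1L) 0 else stats::quantile(rank, 1 - params$keep_fraction,
                                             names = FALSE)
  dipoles$rank <- rank
  dipoles$retained <- rank >= thr
  dipoles
}

#' Automatic single-dipole analysis of an evoked field
#'
#' The complete automatic equivalent-current-dipole pipeline: at every time
#' step inside `window` (1 ms steps when the sampling rate allows, otherwise
#' every sample) the snapshot path of [fit_dipole_snapshot()] is run;
#' accepted dipoles are rank-pruned, assigned to atlas ROIs via the nearest
#' grid point, and counted into a language laterality index.
#'
#' @param evoked an [evoked()] object covering `window`.
#' @param head,array,grid geometry; `atlas` a [make_fixture_atlas()] result
#'   (or `NULL` to skip ROI/laterality bookkeeping).
#' @param window analysis window in seconds, default `c(0.15, 0.6)`.
#' @param params an [ecd_params()].
#' @param leadfield optional precomputed [leadfield_matrix()].
#' @param layout optional precomputed [project_layout()].
#' @return Object of class `ecd_fit` with the dipole table (`$dipoles`),
#'   the laterality result (`$li`) and the configuration used.  Methods:
#'   `print`, `summary`, `coef` (retained dipoles), `plot`,
#'   [laterality()].
#' @export
auto_ecd <- function(evoked, head, array, grid, atlas = NULL,
                     window = c(0.15, 0.6), params = ecd_params(),
                     leadfield = NULL, layout = NULL) {
  stopifnot(inherits(evoked, "evoked"))
  if (is.null(layout)) layout <- project_layout(array)
  layout$smooth_w <- layout_smoother(layout)
  if (is.null(leadfield)) leadfield <- leadfield_matrix(head, array, grid)
  step <- max(1L, round(evoked$fs / 1000))
  idx <- which(evoked$times >= window[1] & evoked$times <= window[2])
  if (!length(idx)) stop("`window` lies outside the evoked data")
  idx <- idx[seq(1L, length(idx), by = step)]
  all <- list()
  for (i in idx) {
    df <- fit_dipole_snapshot(evoked$data[, i], head, array, grid, layout,
                              leadfield, params)
    if (nrow(df)) {
      df$latency <- evoked$times[i]
      all[[length(all) + 1L]] <- df
    }
  }
  dip <- if (length(all)) do.call(rbind, all) else
    data.frame(site = integer(0), x = numeric(0), y = numeric(0),
               z = numeric(0), qx = numeric(0), qy = numeric(0),
               qz = numeric(0), gof = numeric(0), rv = numeric(0),
               n_channels = integer(0), accepted = logical(0),
               latency = numeric(0))
  acc <- dip[dip$accepted, , drop = FALSE]
  acc <- rank_and_prune(acc, params)
  ret <- acc[acc$retained, , drop = FALSE]

  ## ROI / hemisphere assignment of retained dipoles
  if (nrow(ret)) {
    P <- as.matrix(ret[, c("x", "y", "z")])
    nn <- nearest_grid_point(grid, P)
    xrel <- P[, 1] - head$center[1]
    ret$hemisphere <- ifelse(abs(xrel) < params$midline, "M",
                             ifelse(xrel < 0, "L", "R"))
    if (!is.null(atlas)) {
      ret$roi <- atlas$table$roi[nn]
      ret$is_language <- atlas$table$is_language[nn]
    } else {
      ret$roi <- NA_character_; ret$is_language <- NA
    }
  } else {
    ret$hemisphere <- character(0); ret$roi <- character(0)
    ret$is_language <- logical(0)
  }

  li <- if (!is.null(atlas)) {
    L <- sum(ret$hemisphere == "L" & ret$is_language, na.rm = TRUE)
    R <- sum(ret$hemisphere == "R" & ret$is_language, na.rm = TRUE)
    laterality_result(L, R, method = "ecd")
  } else NULL

  structure(list(dipoles = dip, accepted = acc, retained = ret, li = li,
                 params = params, window = window, step_s = step / evoked$fs,
                 n_steps = length(idx), head = head, call = match.call()),
            class = "ecd_fit")
}

nearest_grid_point <- function(grid, P) {
  G <- grid$points
  d2 <- outer(rowSums(P^2), rowSums(G^2), `+`) - 2 * P %*% t(G)
  max.col(-d2, ties.method = "first")
}

#' @export
print.ecd_fit <- function(x, ...) {
  cat("Automatic single-dipole analysis\n")
  cat(sprintf("  window %g..%g s, %d time steps (%.0f ms step)\n",
              x$window[1], x$window[2], x$n_steps, 1e3 * x$step_s))
  cat(sprintf("  %d fits, %d accepted (gof >= %.2f, rv < %.2f), %d retained after ranking\n",
              nrow(x$dipoles), nrow(x$accepted), x$params$gof_min,
              x$params$rv_max, nrow(x$retained)))
  if (!is.null(x$li)) print(x$li)
  invisible(x)
}

#' @export
summary.ecd_fit <- function(object, ...) {
  ret <- object$retained
  out <- list(n_fits = nrow(object$dipoles),
              n_accepted = nrow(object$accepted),
              n_retained = nrow(ret),
              by_hemisphere = if (nrow(ret)) table(ret$hemisphere) else table(character(0)),
              gof = if (nrow(ret)) summary(ret$gof) else NULL,
              li = object$li)
  class(out) <- "summary.ecd_fit"
  out
}

#' @export
print.summary.ecd_fit <- function(x, ...) {
  cat(sprintf("Dipole fits: %d attempted, %d accepted, %d retained\n",
              x$n_fits, x$n_accepted, x$n_retained))
  if (x$n_retained) {
    cat("Retained dipoles by hemisphere:\n"); print(x$by_hemisphere)
    cat("Goodness of fit (correlation):\n"); print(x$gof)
  }
  if (!is.null(x$li)) print(x$li)
  invisible(x)
}

#' @export
coef.ecd_fit <- function(object, ...) object$retained

#' @export
plot.ecd_fit <- function(x, ...) {
  ret <- x$retained
  if (!nrow(ret)) { graphics::plot.new(); graphics::title("no retained dipoles"); return(invisible(x)) }
  r <- x$head$radius * 1e3
  graphics::plot(ret$x * 1e3, ret$y * 1e3, xlim = c(-r, r), ylim = c(-r, r),
                 xlab = "x [mm] (left < 0)", ylab = "y [mm]", asp = 1,
                 col = ifelse(ret$hemisphere == "L", "royalblue",
                              ifelse(ret$hemisphere == "R", "firebrick", "grey40")),
                 pch = 19, cex = 0.4 + ret$gof, ...)
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(r * cos(th), r * sin(th), col = "grey60")
  graphics::title("Retained dipoles (axial view)")
  invisible(x)
}

#' Export a dipole table as TSV
#' @param fit an `ecd_fit`; `path` output file.
#' @export
write_dipoles_tsv <- function(fit, path) {
  ret <- fit$retained
  out <- data.frame(latency_ms = 1e3 * ret$latency,
                    x_mm = 1e3 * ret$x, y_mm = 1e3 * ret$y,
                    z_mm = 1e3 * ret$z,
                    qx = ret$qx, qy = ret$qy, qz = ret$qz,
                    gof = ret$gof, rv = ret$rv, rank = ret$rank,
                    hemisphere = ret$hemisphere, roi = ret$roi,
                    is_language_roi = ret$is_language)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
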