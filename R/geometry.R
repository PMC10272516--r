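#' Single-sphere volume conductor
#'
#' The head is modelled as a homogeneous conducting sphere.  For MEG only the
#' sphere centre matters for the magnetic field outside the head (the Sarvas
#' field is independent of the conductivity profile), but the radius is kept to
#' validate source positions and to define source-grid extent.
#'
#' @param center numeric(3), sphere centre in metres.
#' @param radius sphere radius in metres, must be positive.
#' @return An object of class `head_model`.
#' @examples
#' head <- head_model(radius = 0.09)
#' @export
head_model <- function(center = c(0, 0, 0), radius = 0.09) {
  center <- as.numeric(center)
  if (length(center) != 3L || anyNA(center))
    stop("`center` must be a numeric 3-vector")
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("`radius` must be a positive scalar (metres)")
  structure(list(center = center, radius = radius), class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("Single-sphere head model: radius %.1f mm, centre (%g, %g, %g) mm\n",
              1e3 * x$radius, 1e3 * x$center[1], 1e3 * x$center[2],
              1e3 * x$center[3]))
  invisible(x)
}

#' Synthetic planar-gradiometer helmet array
#'
#' Places `n_sites` sensor sites quasi-uniformly on the upper part of a sphere
#' of radius `helmet_radius` (a Fibonacci lattice on the spherical cap covering
#' about two thirds of the sphere's surface, i.e. down to a polar angle of
#' ~109 degrees, mimicking a whole-head helmet).  Each site carries two planar
#' gradiometer channels oriented along two orthogonal tangential axes, as in
#' 204-gradiometer whole-head systems.
#'
#' The coordinate frame follows the usual MEG head convention: +x towards the
#' right ear, +y towards the nasion, +z up.  Left hemisphere is x < 0.
#'
#' @param n_sites number of sensor sites (>= 4); each site has 2 channels.
#' @param helmet_radius radius of the sensor shell in metres; must exceed the
#'   head radius the array will be used with.
#' @param seed integer; sets the random azimuthal offset of the lattice so
#'   that distinct arrays can be generated reproducibly.
#' @param baseline planar gradiometer baseline (two-point finite-difference
#'   separation) in metres.  Default 16.8 mm.
#' @param center centre of the sensor shell (should equal the head centre).
#' @return An object of class `sensor_array` with fields `site_pos`,
#'   `site_normal`, `ax1`, `ax2` (n_sites x 3 matrices), `baseline`,
#'   `channel_names`, `channel_site` (site index of each channel) and
#'   `channel_axis` (1 or 2).
#' @export
build_sensor_array <- function(n_sites = 102L, helmet_radius = 0.12,
                               seed = 1L, baseline = 0.0168,
                               center = c(0, 0, 0)) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 4)
    stop("`n_sites` must be an integer >= 4")
  n_sites <- as.integer(n_sites)
  if (helmet_radius <= 0) stop("`helmet_radius` must be positive")
  center <- as.numeric(center)

  ## Fibonacci lattice on the cap cos(theta) in [-1/3, 1], i.e. the upper
  ## two thirds of the sphere's area.  The seed only rotates the lattice
  ## about z, so layouts are quasi-uniform and reproducible.
  set.seed(as.integer(seed))
  phi0 <- stats::runif(1, 0, 2 * pi)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_sites) - 0.5
  cmin <- -1 / 3
  costh <- 1 - (1 - cmin) * i / n_sites
  sinth <- sqrt(pmax(0, 1 - costh^2))
  phi <- phi0 + golden * (seq_len(n_sites) - 1L)
  u <- unname(cbind(sinth * cos(phi), sinth * sin(phi), costh))
  dimnames(u) <- NULL                                    # outward unit normals
  pos <- sweep(u * helmet_radius, 2, center, `+`)

  ## Tangential frame: ax1 ~ "horizontal" (east), ax2 = n x ax1 so that
  ## ax1 x ax2 = n (right-handed).
  zhat <- c(0, 0, 1)
  ax1 <- t(apply(u, 1, function(n) {
    v <- c(-n[2], n[1], 0)              # zhat x n
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) v <- c(1, 0, 0) else v <- v / nv
    v
  }))
  ax2 <- t(vapply(seq_len(n_sites),
                  function(k) cross3(u[k, ], ax1[k, ]),
                  numeric(3)))

  channel_site <- rep(seq_len(n_sites), each = 2L)
  channel_axis <- rep(c(1L, 2L), times = n_sites)
  channel_names <- sprintf("MEG%03d%s", channel_site,
                           c("H", "V")[channel_axis])

  structure(list(site_pos = pos, site_normal = u, ax1 = ax1, ax2 = ax2,
                 baseline = baseline, helmet_radius = helmet_radius,
                 center = center, n_sites = n_sites,
                 channel_names = channel_names,
                 channel_site = channel_site, channel_axis = channel_axis),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf(
    "Planar-gradiometer array: %d sites / %d channels, shell radius %.0f mm, baseline %.1f mm\n",
    x$n_sites, 2L * x$n_sites, 1e3 * x$helmet_radius, 1e3 * x$baseline))
  invisible(x)
}

n_channels <- function(array) 2L * array$n_sites

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Regular volumetric source grid inside the head sphere
#'
#' Builds a regular grid with the given spacing covering the interior of the
#' sphere, together with a 6-neighbour adjacency at one grid spacing (used for
#' cluster-based statistics).  Grid planes are offset by half a spacing along
#' x so the grid is mirror-symmetric about the sagittal midplane and no point
#' lies exactly on it; this gives every point an unambiguous hemisphere and
#' makes mirrored (left/right) source pairs exact grid points.
#'
#' @param head a [head_model()].
#' @param spacing grid spacing in metres (default 8 mm).
#' @param margin minimum depth below the sphere surface in metres (default
#'   half a spacing), keeping sources strictly inside the conductor.
#' @return Object of class `source_grid` with `points` (N x 3), `spacing`,
#'   `adjacency` (list of integer neighbour vectors) and `head`.
#' @export
source_grid <- function(head, spacing = 0.008, margin = spacing / 2) {
  stopifnot(inherits(head, "head_model"))
  if (spacing <= 0) stop("`spacing` must be positive")
  r <- head$radius - margin
  if (r <= 0) stop("`margin` leaves no interior volume")
  m <- ceiling(r / spacing)
  ix <- seq(-m - 1L, m) + 0.5       # half-offset: symmetric, no x == 0
  iy <- seq(-m, m)
  iz <- seq(-m, m)
  g <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  pts <- sweep(g * spacing, 2, head$center, `+`)
  d2 <- rowSums(sweep(pts, 2, head$center)^2)
  keep <- d2 < r^2
  pts <- pts[keep, , drop = FALSE]
  g <- g[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n == 0L) stop("grid is empty; decrease `spacing` or `margin`")

  ## integer-key lookup for 6-neighbour adjacency
  key <- function(ijk) paste(ijk[, 1] * 2, ijk[, 2] * 2, ijk[, 3] * 2)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  ks <- key(g)
  for (i in seq_len(n)) assign(ks[i], i, envir = idx)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  adjacency <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (o in seq_len(6)) {
      k <- key(matrix(g[i, ] + offs[o, ], nrow = 1))
      j <- idx[[k]]
      if (!is.null(j)) nb <- c(nb, j)
    }
    adjacency[[i]] <- sort(nb)
  }
  structure(list(points = unname(pts), spacing = spacing, margin = margin,
                 adjacency = adjacency, head = head),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("Volumetric source grid: %d points, %.1f mm spacing, sphere radius %.1f mm\n",
              nrow(x$points), 1e3 * x$spacing, 1e3 * x$head$radius))
  invisible(x)
}

#' Azimuthal-equidistant 2-D sensor layout
#'
#' Projects the sensor sites onto a plane by an azimuthal equidistant
#' projection about the mean site direction (great-circle distance from the
#' projection pole is preserved, so small inter-sensor distances are nearly
#' undistorted), then rescales so the site cloud fits a unit-diameter disk.
#' Both gradiometer channels of a site share the site's 2-D coordinate.  The
#' layout's first coordinate is aligned with the head x axis (left-right), so
#' hemisphere membership of a site is the sign of its layout x.
#'
#' The minimum pairwise site distance of the normalized layout
#' (`pairwise_min_distance`) is the standard deviation used by the 2-D
#' Gaussian field smoothing of the automatic dipole algorithm.
#'
#' @param array a [build_sensor_array()] result.
#' @return Object of class `layout2d` with `coords` (sites x 2, normalized),
#'   `channel_coords` (channels x 2), `pairwise_min_distance`, `adjacency`
#'   (Delaunay neighbour list over sites) and `scale` (metres-per-unit before
#'   normalization has no meaning; the layout is dimensionless).
#' @export
project_layout <- function(array) {
  stopifnot(inherits(array, "sensor_array"))
  u <- array$site_normal
  m <- colMeans(u); m <- m / sqrt(sum(m^2))
  ## tangent basis at the pole, b1 aligned with head +x as far as possible
  b1 <- c(1, 0, 0) - sum(c(1, 0, 0) * m) * m
  if (sqrt(sum(b1^2)) < 1e-9) b1 <- c(0, 1, 0) - sum(c(0, 1, 0) * m) * m
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- cross3(m, b1)
  dotm <- pmin(1, pmax(-1, as.numeric(u %*% m)))
  alpha <- acos(dotm)
  x1 <- as.numeric(u %*% b1)
  x2 <- as.numeric(u %*% b2)
  phi <- atan2(x2, x1)
  phi[alpha < 1e-12] <- 0
  xy <- cbind(alpha * cos(phi), alpha * sin(phi))

  D <- as.matrix(stats::dist(xy))
  dmax <- max(D)
  if (dmax < 1e-12) stop("degenerate sensor geometry: sites are coincident")
  ## collinearity check
  sv <- svd(scale(xy, scale = FALSE))$d
  if (sv[2] / sv[1] < 1e-9) stop("degenerate sensor geometry: sites are collinear")
  xy <- xy / dmax
  D <- D / dmax
  diag(D) <- Inf
  dmin <- min(D)

  adjacency <- delaunay_adjacency(xy)
  structure(list(coords = xy,
                 channel_coords = xy[array$channel_site, , drop = FALSE],
                 pairwise_min_distance = dmin,
                 adjacency = adjacency,
                 n_sites = array$n_sites),
            class = "layout2d")
}

#' @export
print.layout2d <- function(x, ...) {
  cat(sprintf("2-D sensor layout: %d sites in unit-diameter disk, min pairwise distance %.4f\n",
              x$n_sites, x$pairwise_min_distance))
  invisible(x)
}

## ---- Delaunay triangulation (Bowyer-Watson) -------------------------------
## Used for the neighbourhood structure of local-maxima detection on the
## irregular 2-D sensor layout.  Plain O(n^2) incremental construction:
## adequate for a few hundred sites.

circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  r2 <- (ax - ux)^2 + (ay - uy)^2
  c(ux, uy, r2)
}

delaunay_adjacency <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) {
    adj <- vector("list", n)
    for (i in seq_len(n)) adj[[i]] <- setdiff(seq_len(n), i)
    return(adj)
  }
  ## super-triangle enclosing all points
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  R <- 10 * max(sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2)) + 1
  sp <- rbind(c(cx - 2 * R, cy - R), c(cx + 2 * R, cy - R), c(cx, cy + 2 * R))
  P <- rbind(xy, sp)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- list(c(s1, s2, s3))
  ccs <- list(circumcircle(P[s1, ], P[s2, ], P[s3, ]))
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    bad <- logical(length(tris))
    for (t in seq_along(tris)) {
      cc <- ccs[[t]]
      bad[t] <- (p[1] - cc[1])^2 + (p[2] - cc[2])^2 <= cc[3] * (1 + 1e-12)
    }
    ## boundary polygon = edges of bad triangles not shared by two bad ones
    edges <- list()
    for (t in which(bad)) {
      tri <- tris[[t]]
      for (e in list(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)]))
        edges[[length(edges) + 1L]] <- sort(e)
    }
    if (length(edges)) {
      em <- do.call(rbind, edges)
      keyv <- paste(em[, 1], em[, 2])
      keep <- names(which(table(keyv) == 1L))
      poly <- em[keyv %in% keep & !duplicated(keyv), , drop = FALSE]
    } else poly <- matrix(integer(0), ncol = 2)
    tris <- tris[!bad]; ccs <- ccs[!bad]
    if (nrow(poly)) for (e in seq_len(nrow(poly))) {
      tri <- c(poly[e, ], ip)
      cc <- circumcircle(P[tri[1], ], P[tri[2], ], P[tri[3], ])
      if (!is.null(cc)) {
        tris[[length(tris) + 1L]] <- tri
        ccs[[length(ccs) + 1L]] <- cc
      }
    }
  }
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (tri in tris) {
    tri <- tri[tri <= n]
    if (length(tri) >= 2L)
      for (a in tri) for (b in tri) if (a != b)
        adj[[a]] <- c(adj[[a]], b)
  }
  lapply(adj, function(v) sort(unique(v)))
}

## ---- geometry JSON serialization ------------------------------------------

#' Write or read sensor-array and head-model geometry as JSON
#'
#' Coordinates are stored in metres with full double precision, so a
#' write-read cycle reproduces the objects exactly.
#'
#' @param array a `sensor_array`; `head` a `head_model`; `path` file path.
#' @return `read_geometry_json` returns `list(array = , head = )`.
#' @export
write_geometry_json <- function(array, head, path) {
  stopifnot(inherits(array, "sensor_array"), inherits(head, "head_model"))
  obj <- list(
    head = list(center = head$center, radius = head$radius),
    array = list(site_pos = array$site_pos, site_normal = array$site_normal,
                 ax1 = array$ax1, ax2 = array$ax2, baseline = array$baseline,
                 helmet_radius = array$helmet_radius, center = array$center,
                 channel_names = array$channel_names,
                 channel_site = array$channel_site,
                 channel_axis = array$channel_axis),
    units = "m")
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  head <- head_model(center = obj$head$center, radius = obj$head$radius)
  a <- obj$array
  array <- structure(list(site_pos = as.matrix(a$site_pos),
                          site_normal = as.matrix(a$site_normal),
                          ax1 = as.matrix(a$ax1), ax2 = as.matrix(a$ax2),
                          baseline = a$baseline,
                          helmet_radius = a$helmet_radius,
                          center = as.numeric(a$center),
                          n_sites = nrow(as.matrix(a$site_pos)),
                          channel_names = a$channel_names,
                          channel_site = as.integer(a$channel_site),
                          channel_axis = as.integer(a$channel_axis)),
                     class = "sensor_array")
  list(array = array, head = head)
}
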