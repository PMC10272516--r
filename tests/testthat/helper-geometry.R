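# Shared geometry fixtures, built once per test run.
#
# `tg_full()` is the default study configuration (102 sites / 204 planar
# gradiometers on a 0.12 m shell, 0.09 m head sphere, 8 mm grid) used by the
# localization and laterality tests; `tg_small()` is a reduced configuration
# for the linear-algebra-heavy inverse/beamformer tests.

.tg_cache <- new.env(parent = emptyenv())

tg_full <- function() {
  if (is.null(.tg_cache$full)) {
    head <- head_model()
    array <- build_sensor_array(n_sites = 102, seed = 1)
    grid <- source_grid(head)
    layout <- project_layout(array)
    lf <- leadfield_matrix(head, array, grid)
    atlas <- make_fixture_atlas(grid, n_rois_per_hemisphere = 20,
                                language_fraction = 0.4, seed = 3)
    .tg_cache$full <- list(head = head, array = array, grid = grid,
                           layout = layout, lf = lf, atlas = atlas)
  }
  .tg_cache$full
}

tg_small <- function() {
  if (is.null(.tg_cache$small)) {
    head <- head_model()
    array <- build_sensor_array(n_sites = 40, seed = 2)
    grid <- source_grid(head, spacing = 0.02)
    layout <- project_layout(array)
    lf <- leadfield_matrix(head, array, grid)
    atlas <- make_fixture_atlas(grid, n_rois_per_hemisphere = 6,
                                language_fraction = 0.5, seed = 4)
    .tg_cache$small <- list(head = head, array = array, grid = grid,
                            layout = layout, lf = lf, atlas = atlas)
  }
  .tg_cache$small
}

# an interior grid point away from the centre and inside the helmet-covered
# upper region (tangential lead field well defined), chosen deterministically
pick_source <- function(tg, depth_frac = 0.3) {
  pts <- tg$grid$points
  d <- sqrt(rowSums(sweep(pts, 2, tg$head$center)^2))
  target <- (1 - depth_frac) * tg$head$radius
  score <- abs(d - target) + 0.001 * (pts[, 1] > 0) +
    1e3 * (pts[, 3] < 0.2 * tg$head$radius)
  which.min(score)
}
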