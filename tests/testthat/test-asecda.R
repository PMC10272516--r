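test_that("layout smoothing matches the brute-force kernel formula", {
  tg <- tg_full()
  lay <- tg$layout
  set.seed(13)
  v <- abs(rnorm(102))
  sm <- smooth_layout(v, lay)
  # O(n^2) double-loop oracle
  sd <- lay$pairwise_min_distance
  oracle <- vapply(1:102, function(i) {
    w <- exp(-rowSums(sweep(lay$coords, 2, lay$coords[i, ])^2) / (2 * sd^2))
    sum(w * v) / sum(w)
  }, numeric(1))
  expect_equal(sm, oracle, tolerance = 1e-12)
  # uniform field unchanged; single hot site keeps its maximum there
  expect_equal(smooth_layout(rep(2.5, 102), lay), rep(2.5, 102),
               tolerance = 1e-12)
  spike <- numeric(102); spike[40] <- 1
  expect_equal(which.max(smooth_layout(spike, lay)), 40L)
})

test_that("local maxima selection applies the cap, global and hemisphere rules", {
  tg <- tg_full()
  lay <- tg$layout
  # simulated left-hemisphere dipolar pattern -> a single left maximum
  i <- pick_source(tg)
  p <- tg$grid$points[i, ]
  p[1] <- -abs(p[1])
  ori <- c(-p[3], 0, p[1]); ori <- ori / sqrt(sum(ori^2))
  b <- dipole_field(tg$head, tg$array, p, 2e-8 * ori)
  sm <- smooth_layout(combine_planar(b, tg$array)[, 1], lay)
  mx <- find_local_maxima(sm, lay)
  expect_length(mx$left, 1L)
  expect_length(mx$right, 0L)
  # all-zero field -> no maxima
  mx0 <- find_local_maxima(numeric(102), lay)
  expect_length(c(mx0$left, mx0$right), 0L)
  # six equal isolated peaks -> capped at five, lowest indices win
  v <- numeric(102)
  # pick six pairwise non-adjacent sites
  six <- integer(0)
  for (s in seq_len(102)) {
    if (length(six) == 6) break
    if (!any(lay$adjacency[[s]] %in% six)) six <- c(six, s)
  }
  v[six] <- 1
  mx6 <- find_local_maxima(v, lay)
  kept <- sort(c(mx6$left, mx6$right))
  # smoothing is not applied here, so equal peaks tie; cap keeps 5 by index
  expect_length(kept, 5L)
  expect_identical(kept, sort(six)[1:5])
})

test_that("channel-selection radius follows the clamped Gaussian-width rule", {
  tg <- tg_full()
  lay <- tg$layout
  central <- which.min(rowSums(lay$coords^2))
  d <- sqrt(rowSums(sweep(lay$coords, 2, lay$coords[central, ])^2))
  for (sig_true in c(0.05, 0.15, 0.30)) {
    v <- exp(-d^2 / (2 * sig_true^2))
    ss <- select_channel_subset(central, v, lay)
    expect_equal(ss$sigma, sig_true, tolerance = 1e-3)
    expect_equal(ss$rad_cutoff, min(max(sig_true, 0.1), 0.25),
                 tolerance = 1e-3)
    expect_setequal(ss$sites, which(d < ss$rad_cutoff))
    # both gradiometers of each selected site
    expect_length(ss$channels, 2L * length(ss$sites))
  }
  # non-decreasing profile falls back to sigma = min_rad
  ssf <- select_channel_subset(central, d, lay)   # value grows with distance
  expect_true(ssf$fallback)
  expect_equal(ssf$rad_cutoff, 0.1)
})

test_that("single-dipole fit recovers a noiseless source to sub-millimetre", {
  tg <- tg_full()
  lay <- tg$layout
  i <- pick_source(tg)
  p <- tg$grid$points[i, ] + c(0.003, -0.002, 0.001)  # off-grid truth
  ori <- principal_orientations(tg$lf, i)[, 1]
  b <- dipole_field(tg$head, tg$array, p, 2e-8 * ori)
  sm <- smooth_layout(combine_planar(b, tg$array)[, 1], lay)
  mx <- find_local_maxima(sm, lay)
  ss <- select_channel_subset(c(mx$left, mx$right)[1], sm, lay)
  fit <- fit_single_dipole(b[ss$channels], tg$head, tg$array, tg$grid,
                           ss$channels, tg$lf)
  expect_lt(sqrt(sum((fit$location - p)^2)), 1e-3)
  expect_lt(fit$rv, 1e-6)
  expect_gt(fit$gof, 1 - 1e-6)
  expect_equal(fit$moment, 2e-8 * ori, tolerance = 1e-3)
  # a fit against its own prediction is exact by construction
  pred <- dipole_field(tg$head, tg$array, fit$location, fit$moment)
  fit2 <- fit_single_dipole(pred[ss$channels], tg$head, tg$array, tg$grid,
                            ss$channels, tg$lf)
  expect_equal(fit2$gof, 1, tolerance = 1e-9)
  expect_lt(fit2$rv, 1e-9)
  # under-determined subsets are refused
  expect_null(fit_single_dipole(b[1:4], tg$head, tg$array, tg$grid, 1:4,
                                tg$lf))
})

test_that("non-dipolar fields are rejected by the residual-variance criterion", {
  tg <- tg_full()
  lay <- tg$layout
  # alternating-sign checkerboard over one site neighbourhood
  central <- which.min(rowSums(lay$coords^2))
  d <- sqrt(rowSums(sweep(lay$coords, 2, lay$coords[central, ])^2))
  sites <- which(d < 0.25)
  channels <- which(rep(seq_len(102), each = 2) %in% sites)
  b <- numeric(204)
  b[channels] <- rep_len(c(1, -1), length(channels)) * 1e-12
  fit <- fit_single_dipole(b[channels], tg$head, tg$array, tg$grid,
                           channels, tg$lf)
  expect_gt(fit$rv, 0.5)
  expect_false(fit$gof >= 0.90 && fit$rv < 0.20)
})

test_that("spatiotemporal ranking follows the double-Gaussian kernel", {
  par <- ecd_params()
  two <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0.05, 0.05),
                    latency = c(0.3, 0.3))
  r <- rank_and_prune(two, par)
  expect_equal(r$rank, c(1, 1))              # coincident pair: Gs = Gt = 1
  expect_true(all(r$retained))
  # 10 mm apart and 50 ms apart: one sigma each -> rank = e^-1
  pair <- data.frame(x = c(0, 0.010), y = 0, z = 0.05,
                     latency = c(0.3, 0.35))
  r2 <- rank_and_prune(pair, par)
  expect_equal(r2$rank, rep(exp(-1), 2), tolerance = 1e-12)
  # 10 coincident dipoles + 1 isolated (100 mm, 500 ms away): isolated pruned
  clus <- data.frame(x = c(rep(0, 10), 0.1), y = 0,
                     z = c(rep(0.05, 10), 0.05),
                     latency = c(rep(0.3, 10), 0.8))
  r3 <- rank_and_prune(clus, par)
  expect_true(all(r3$retained[1:10]))
  expect_false(r3$retained[11])
  # single dipole: rank zero, retained by convention
  one <- rank_and_prune(data.frame(x = 0, y = 0, z = 0.05, latency = 0.3), par)
  expect_equal(one$rank, 0)
  expect_true(one$retained)
})

test_that("pure-noise snapshots are rarely accepted and never build rank clusters", {
  tg <- tg_full()
  lay <- tg$layout
  lay$smooth_w <- meglat:::layout_smoother(lay)
  set.seed(17)
  nfit <- 0; nacc <- 0; acc_rows <- list()
  for (r in 1:12) {
    b <- rnorm(204)
    df <- fit_dipole_snapshot(b, tg$head, tg$array, tg$grid, lay, tg$lf)
    nfit <- nfit + nrow(df)
    nacc <- nacc + sum(df$accepted)
    if (any(df$accepted)) {
      d2 <- df[df$accepted, ]
      d2$latency <- r * 0.01
      acc_rows[[length(acc_rows) + 1L]] <- d2
    }
  }
  expect_gt(nfit, 20)
  expect_lt(nacc / nfit, 0.05)
  # whatever survives is spatiotemporally isolated: ranks near zero
  if (length(acc_rows) > 1) {
    rk <- rank_and_prune(do.call(rbind, acc_rows))
    expect_lt(max(rk$rank), 0.5)
  }
})

test_that("full pipeline lateralizes a left language source and logs structure", {
  tg <- tg_full()
  lang_left <- tg$atlas$rois[tg$atlas$rois$is_language &
                               tg$atlas$rois$hemisphere == "L", ][1, ]
  loc <- as.numeric(lang_left[c("cx", "cy", "cz")])
  nn <- meglat:::nearest_grid_point(tg$grid, matrix(loc, 1))
  ori <- principal_orientations(tg$lf, nn)[, 1]
  ev <- simulate_evoked(tg$head, tg$array, loc, ori, snr = 10, seed = 5,
                        fs = 250)
  fit <- auto_ecd(ev, tg$head, tg$array, tg$grid, tg$atlas,
                  leadfield = tg$lf, layout = tg$layout)
  expect_s3_class(fit, "ecd_fit")
  expect_gt(nrow(fit$retained), 5)
  expect_identical(fit$li$category, "left")
  expect_equal(fit$li$li, 1)
  # retained dipoles cluster at the source
  med <- apply(fit$retained[, c("x", "y", "z")], 2, median)
  expect_lt(sqrt(sum((med - loc)^2)), 0.01)
  # bitwise reproducibility under identical seeds
  ev2 <- simulate_evoked(tg$head, tg$array, loc, ori, snr = 10, seed = 5,
                         fs = 250)
  fit2 <- auto_ecd(ev2, tg$head, tg$array, tg$grid, tg$atlas,
                   leadfield = tg$lf, layout = tg$layout)
  expect_identical(fit$retained$x, fit2$retained$x)
  expect_identical(coef(fit), fit$retained)
})
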