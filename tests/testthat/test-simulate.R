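test_that("add_noise honours the RMS/SNR convention", {
  set.seed(5)
  x <- matrix(rnorm(200, sd = 3), 2, 100)
  expect_identical(unclass(add_noise(x, Inf))[1:200], x[1:200])
  # snr = 1: noise SD equals the signal RMS, checked on 1e5 samples
  big <- matrix(rnorm(1e5, sd = 2), 100, 1000)
  noisy <- add_noise(big, 1, seed = 7)
  noise <- noisy - big
  expect_equal(sd(noise), sqrt(mean(big^2)), tolerance = 0.01)
  expect_lt(abs(mean(noise)), 3 * sd(noise) / sqrt(length(noise)))
  expect_error(add_noise(matrix(0, 2, 2), 5), "all-zero")
  expect_error(add_noise(x, 0), "positive")
  expect_error(add_noise(x, -2), "positive")
})

test_that("simulate_evoked: no-noise limit, determinism, and empirical SNR", {
  tg <- tg_full()
  i <- pick_source(tg)
  p <- tg$grid$points[i, ]
  ori <- principal_orientations(tg$lf, i)[, 1]
  clean <- simulate_evoked(tg$head, tg$array, p, ori, snr = Inf)
  # noiseless record equals lead field times waveform exactly
  pk <- which.min(abs(clean$times - 0.3))
  expect_equal(clean$data[, pk],
               dipole_field(tg$head, tg$array, p, 20e-9 * ori),
               tolerance = 1e-12)
  expect_equal(clean$truth$peak_latency, 0.3)
  a <- simulate_evoked(tg$head, tg$array, p, ori, snr = 5, seed = 42)
  b <- simulate_evoked(tg$head, tg$array, p, ori, snr = 5, seed = 42)
  expect_identical(a$data, b$data)
  # empirical SNR (RMS clean / SD of realized noise) within 2% of requested
  noise <- a$data - clean$data
  emp <- sqrt(mean(clean$data^2)) / sd(noise)
  expect_equal(emp, 5, tolerance = 0.02)
  expect_error(simulate_evoked(tg$head, tg$array, p, ori, snr = -1), "positive")
})

test_that("ERD epochs carry the requested band-limited power change", {
  tg <- tg_small()
  i <- pick_source(tg)
  p <- tg$grid$points[i, ]
  ori <- principal_orientations(tg$lf, i)[, 1]
  ep <- simulate_erd_epochs(tg$head, tg$array, p, ori, band = c(8, 12),
                            power_change = -0.5, n_trials = 12, snr = 10,
                            seed = 8)
  expect_equal(dim(ep$data)[1], 12L)
  expect_identical(ep$truth$direction, "ERD")
  # sensor band power in the active window below baseline, per construction
  bsel <- ep$times >= -0.5 & ep$times <= -0.1
  asel <- ep$times >= 0.25 & ep$times <= 0.65
  pw <- function(sel) mean(ep$data[, , sel]^2)
  expect_lt(pw(asel), pw(bsel))
  # determinism and trial-to-trial phase randomization (average kills the
  # oscillation: evoked RMS far below single-trial RMS)
  ep2 <- simulate_erd_epochs(tg$head, tg$array, p, ori, band = c(8, 12),
                             power_change = -0.5, n_trials = 12, snr = 10,
                             seed = 8)
  expect_identical(ep$data, ep2$data)
  avg <- average_epochs(ep)
  expect_lt(sqrt(mean(avg$data^2)), 0.5 * sqrt(mean(ep$data[1, , ]^2)))
  expect_error(simulate_erd_epochs(tg$head, tg$array, p, ori,
                                   n_trials = 0), "n_trials")
  expect_error(simulate_erd_epochs(tg$head, tg$array, p, ori,
                                   band = c(100, 400)), "Nyquist")
})

test_that("empty-room record has white covariance at the stated level", {
  tg <- tg_small()
  rec <- simulate_empty_room(tg$array, 1e5, noise_sd = 3e-12, seed = 12)
  C <- cov(t(rec$data))
  expect_equal(mean(diag(C)), 9e-24, tolerance = 0.02)
  Cc <- cov2cor(C)
  expect_lt(max(abs(Cc[upper.tri(Cc)])), 0.05)
  rec2 <- simulate_empty_room(tg$array, 1e5, noise_sd = 3e-12, seed = 12)
  expect_identical(rec$data, rec2$data)
  expect_warning(simulate_empty_room(tg$array, 10, seed = 1), "rank deficient")
})

test_that("fixture atlas partitions the grid symmetrically", {
  tg <- tg_full()
  atlas <- tg$atlas
  # every point labelled, hemisphere = sign of x
  expect_equal(nrow(atlas$table), nrow(tg$grid$points))
  expect_false(anyNA(atlas$table$roi))
  expect_identical(atlas$table$hemisphere,
                   ifelse(tg$grid$points[, 1] < 0, "L", "R"))
  # equal ROI counts and language flags per hemisphere
  expect_equal(sum(atlas$rois$hemisphere == "L"), 20L)
  expect_equal(sum(atlas$rois$hemisphere == "R"), 20L)
  expect_equal(sum(atlas$rois$is_language & atlas$rois$hemisphere == "L"),
               sum(atlas$rois$is_language & atlas$rois$hemisphere == "R"))
  # centroids inside the sphere and in their own hemisphere
  cen <- as.matrix(atlas$rois[, c("cx", "cy", "cz")])
  expect_true(all(sqrt(rowSums(cen^2)) < tg$head$radius))
  expect_true(all(sign(cen[, 1]) == ifelse(atlas$rois$hemisphere == "L", -1, 1)))
  # mirrored ROI geometry: left centroids are the x-mirror of right ones
  left <- cen[atlas$rois$hemisphere == "L", ]
  right <- cen[atlas$rois$hemisphere == "R", ]
  expect_equal(left[, 1], -right[, 1], tolerance = 1e-12)
  expect_equal(left[, 2:3], right[, 2:3], tolerance = 1e-12)
  expect_error(make_fixture_atlas(tg$grid, n_rois_per_hemisphere = 1e6),
               "between")
})

test_that("atlas TSV round-trips labels and centroids", {
  tg <- tg_small()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_atlas_tsv(tg$atlas, path)
  back <- read_atlas_tsv(path, tg$grid)
  expect_identical(back$table$roi, tg$atlas$table$roi)
  expect_identical(back$table$is_language, tg$atlas$table$is_language)
  expect_equal(back$rois$cx[match(tg$atlas$rois$roi, back$rois$roi)],
               tg$atlas$rois$cx, tolerance = 1e-12)
})
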