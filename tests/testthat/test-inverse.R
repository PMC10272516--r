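test_that("noise covariance of a white record is a scaled identity", {
  tg <- tg_small()
  rec <- simulate_empty_room(tg$array, 5e4, noise_sd = 2e-12, seed = 19)
  nc <- estimate_noise_cov(rec)
  expect_equal(mean(diag(nc$C)), 4e-24, tolerance = 0.02)
  Cc <- cov2cor(nc$C)
  expect_lt(max(abs(Cc[upper.tri(Cc)])), 0.05)
  expect_identical(nc$n_samples, 50000L)
  # symmetric positive definite after loading
  expect_equal(nc$C, t(nc$C), tolerance = 1e-12)
  expect_gt(min(eigen(nc$C, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(estimate_noise_cov(matrix(0, 4, 100)), "zero")
})

test_that("inverse operator satisfies the source-scaling and inverse-limit identities", {
  tg <- tg_small()
  rec <- simulate_empty_room(tg$array, 2e4, noise_sd = 2e-12, seed = 20)
  nc <- estimate_noise_cov(rec)
  op <- inverse_operator(tg$lf, nc, lambda2 = 3)
  A <- tg$lf$matrix
  # trace(A R A^T) / trace(C) = 1
  expect_equal(op$source_scale * sum(A^2) / sum(diag(nc$C)), 1,
               tolerance = 1e-9)
  # lambda^2 -> 0 with a square full-rank whitened system: W A -> I
  set.seed(21)
  nch <- 12
  Asq <- matrix(rnorm(nch * nch), nch, nch)
  lf_sq <- structure(list(matrix = Asq,
                          grid = list(points = matrix(rnorm(12), 4, 3))),
                     class = "leadfield")
  nc_sq <- structure(list(C = diag(0.5, nch), n_samples = 1000L),
                     class = "noise_cov")
  op_sq <- inverse_operator(lf_sq, nc_sq, lambda2 = 1e-12)
  expect_lt(max(abs(op_sq$W %*% Asq - diag(nch))), 1e-6)
})

test_that("inverse operator matches the dense unwhitened textbook formula", {
  # brute-force oracle on a small random instance: W = R A^T (A R A^T +
  # lambda^2 C)^-1 computed directly in the unwhitened basis
  set.seed(22)
  nch <- 50; nsrc <- 60
  A <- matrix(rnorm(nch * nsrc), nch, nsrc) * 1e-7
  X <- matrix(rnorm(nch * 400), nch, 400) * 1e-13
  C <- tcrossprod(X) / 400 + diag(1e-27, nch)
  lambda2 <- 3
  cscale <- sum(diag(C)) / sum(A^2)
  W_dense <- cscale * t(A) %*% solve(cscale * tcrossprod(A) + lambda2 * C)
  lf <- structure(list(matrix = A,
                       grid = list(points = matrix(rnorm(nsrc), nsrc / 3, 3))),
                  class = "leadfield")
  nc <- structure(list(C = C, n_samples = 400L), class = "noise_cov")
  op <- inverse_operator(lf, nc, lambda2 = lambda2)
  expect_equal(op$W, W_dense, tolerance = 1e-8)
})

test_that("MNE estimate is linear and peaks near a simulated source", {
  tg <- tg_small()
  rec <- simulate_empty_room(tg$array, 2e4, noise_sd = 1e-13, seed = 23)
  nc <- estimate_noise_cov(rec)
  op <- inverse_operator(tg$lf, nc)
  i <- pick_source(tg, depth_frac = 0.25)
  p <- tg$grid$points[i, ]
  ori <- principal_orientations(tg$lf, i)[, 1]
  ev <- simulate_evoked(tg$head, tg$array, p, ori, snr = Inf)
  fit <- apply_mne(op, ev)
  # zero in, zero out; additivity
  ev0 <- ev; ev0$data <- ev$data * 0
  expect_equal(max(abs(apply_mne(op, ev0)$sol)), 0)
  ev2 <- ev; ev2$data <- 2 * ev$data
  expect_equal(apply_mne(op, ev2)$sol, 2 * fit$sol, tolerance = 1e-12)
  # peak of the window power within 2 grid spacings of the truth
  pw <- rowMeans(meglat:::point_power(fit$sol)[,
                   ev$times >= 0.25 & ev$times <= 0.35])
  best <- which.max(pw)
  expect_lt(sqrt(sum((tg$grid$points[best, ] - p)^2)), 2 * tg$grid$spacing)
  expect_error(apply_mne(op, evoked(matrix(0, 3, 2), 1000, c(0, 1e-3),
                                    c("a", "b", "c"))), "channel")
})

test_that("dSPM is unit-mean under the null and quadratic in the data", {
  tg <- tg_small()
  rec <- simulate_empty_room(tg$array, 2e4, noise_sd = 3e-13, seed = 24)
  nc <- estimate_noise_cov(rec)
  op <- inverse_operator(tg$lf, nc)
  # x ~ N(0, C): mean q over points and 1e4 samples ~= 1
  set.seed(25)
  ch <- chol(nc$C)
  x <- t(ch) %*% matrix(rnorm(nrow(nc$C) * 1e4), nrow(nc$C))
  evn <- evoked(x, 1000, seq(0, by = 1e-3, length.out = ncol(x)),
                tg$array$channel_names)
  q <- apply_dspm(op, evn)
  expect_true(all(q$q >= 0))
  expect_equal(mean(q$q), 1, tolerance = 3 / sqrt(length(q$q) / 50))
  # scaling the data by 2 scales q by 4
  evn2 <- evn; evn2$data <- 2 * evn$data
  q2 <- apply_dspm(op, evn2)
  expect_equal(q2$q, 4 * q$q, tolerance = 1e-12)
})

test_that("Bonferroni dSPM threshold separates signal from null", {
  tg <- tg_small()
  rec <- simulate_empty_room(tg$array, 2e4, noise_sd = 3e-13, seed = 26)
  nc <- estimate_noise_cov(rec)
  op <- inverse_operator(tg$lf, nc)
  # null: noise drawn from C itself
  set.seed(27)
  ch <- chol(nc$C)
  x <- t(ch) %*% matrix(rnorm(nrow(nc$C) * 500), nrow(nc$C))
  evn <- evoked(x, 1000, seq(0.15, by = 1e-3, length.out = 500),
                tg$array$channel_names)
  thn <- dspm_threshold(apply_dspm(op, evn), window = c(0.15, 0.65))
  expect_lte(sum(thn$significant), 1)      # ~0 false positives expected
  expect_true(all(dspm_threshold(apply_dspm(op, evn), window = c(0.15, 0.65),
                                 alpha = 1)$significant))
  # strong source: its neighbourhood is masked in
  i <- pick_source(tg, depth_frac = 0.25)
  p <- tg$grid$points[i, ]
  ori <- principal_orientations(tg$lf, i)[, 1]
  ev <- simulate_evoked(tg$head, tg$array, p, ori, snr = 20, seed = 28,
                        waveform = list(amplitude = 50e-9))
  th <- dspm_threshold(apply_dspm(op, ev), window = c(0.25, 0.35))
  expect_gt(sum(th$significant), 0)
  sigpts <- tg$grid$points[th$significant, , drop = FALSE]
  dmin <- min(sqrt(rowSums(sweep(sigpts, 2, p)^2)))
  expect_lt(dmin, 2 * tg$grid$spacing)
})

test_that("distributed-inverse laterality recovers side and symmetry", {
  tg <- tg_small()
  rec <- simulate_empty_room(tg$array, 2e4, noise_sd = 1e-13, seed = 29)
  nc <- estimate_noise_cov(rec)
  op <- inverse_operator(tg$lf, nc)
  lang <- tg$atlas$rois[tg$atlas$rois$is_language &
                          tg$atlas$rois$hemisphere == "L", ][1, ]
  locL <- as.numeric(lang[c("cx", "cy", "cz")])
  nn <- meglat:::nearest_grid_point(tg$grid, matrix(locL, 1))
  ori <- principal_orientations(tg$lf, nn)[, 1]
  evL <- simulate_evoked(tg$head, tg$array, locL, ori, snr = 20, seed = 30)
  liL <- laterality(apply_mne(op, evL), tg$atlas, window = c(0.25, 0.35))
  expect_gt(liL$li, 0)
  # mirrored bilateral pair: LI ~= 0
  locR <- locL * c(-1, 1, 1)
  oriR <- ori * c(1, -1, -1)
  evB <- simulate_evoked(tg$head, tg$array, rbind(locL, locR),
                         rbind(ori, oriR), snr = 20, seed = 31)
  liB <- laterality(apply_mne(op, evB), tg$atlas, window = c(0.25, 0.35))
  expect_lt(abs(liB$li), 0.2)
  # dSPM laterality modes run and agree on the side
  liD <- laterality(apply_dspm(op, evL), tg$atlas, window = c(0.25, 0.35))
  if (!liD$no_source) expect_gte(liD$li, 0)
  liC <- laterality(apply_dspm(op, evL), tg$atlas, window = c(0.25, 0.35),
                    mode = "count")
  expect_s3_class(liC, "laterality_result")
})
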