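# mini fixtures for the algebra-level DICS checks: a hand-built 8-point
# source "grid" (two mirrored chains of 4) with its own atlas, on the small
# sensor array

mini_grid <- function(tg) {
  pts <- rbind(cbind(-0.045, c(-0.02, 0, 0.02, 0.04), 0.04),
               cbind(0.045, c(-0.02, 0, 0.02, 0.04), 0.04))
  adjacency <- list(2L, c(1L, 3L), c(2L, 4L), 3L,
                    6L, c(5L, 7L), c(6L, 8L), 7L)
  adjacency[5:8] <- lapply(adjacency[1:4], function(v) v + 4L)
  structure(list(points = pts, spacing = 0.02, margin = 0,
                 adjacency = adjacency, head = tg$head),
            class = "source_grid")
}

mini_atlas <- function() {
  tab <- data.frame(point = 1:8,
                    roi = rep(c("L01", "R01"), each = 4),
                    hemisphere = rep(c("L", "R"), each = 4),
                    is_language = TRUE, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 rois = data.frame(roi = c("L01", "R01"),
                                   hemisphere = c("L", "R"),
                                   is_language = TRUE,
                                   cx = c(-0.045, 0.045), cy = 0.01,
                                   cz = 0.04, stringsAsFactors = FALSE),
                 n_points = 8L), class = "atlas")
}

test_that("CSD concentrates a sinusoid at its bin and is Hermitian", {
  fs <- 250
  times <- seq(-0.5, 0.7, by = 1 / fs)
  ntr <- 8
  s <- sin(2 * pi * 10 * times)
  data <- array(0, c(ntr, 2, length(times)))
  for (tr in 1:ntr) { data[tr, 1, ] <- s; data[tr, 2, ] <- s }
  ep <- epochs(data, fs, times, c("A", "B"))
  cs <- compute_csd(ep, window = c(0.0999, 0.4999), band = c(8, 12))
  expect_equal(cs$freqs, 10)
  Q <- cs$Q[[1]]
  expect_equal(Q, Conj(t(Q)), tolerance = 1e-10)
  expect_true(all(Re(diag(Q)) >= 0))
  expect_lt(max(abs(Im(diag(Q)))), 1e-12)
  # identical channels: perfect coherence, |off-diagonal| = diagonal
  expect_equal(Mod(Q[1, 2]), Re(Q[1, 1]), tolerance = 1e-10)
  # off-band bin carries (almost) no power
  cs2 <- compute_csd(ep, window = c(0.0999, 0.4999), band = c(18, 22))
  expect_gt(Re(Q[1, 1]), 100 * Re(cs2$Q[[1]][1, 1]))
  expect_error(compute_csd(ep, window = c(0.0999, 0.4999), band = c(10.7, 11.2)),
               "bin")
})

test_that("DICS filter has unit gain on the tangential subspace and matches oracles", {
  tg <- tg_small()
  i <- pick_source(tg)
  A <- meglat:::lf_block(tg$lf, i)
  nch <- nrow(A)
  set.seed(51)
  X <- (matrix(rnorm(nch * 300), nch) + 1i * matrix(rnorm(nch * 300), nch)) * 1e-13
  Q <- X %*% Conj(t(X)) / 300
  Wt <- build_dics_filter(Q, A, reg = 0.10)
  # W^T A equals the projector onto the tangential (non-silent) subspace
  V <- svd(A)$v[, 1:2]
  expect_equal(Wt %*% A, V %*% t(V), tolerance = 1e-6)
  # white-CSD limit: filter equals the pseudo-inverse of A
  Wt_white <- build_dics_filter(diag(1e-26, nch), A, reg = 0.10)
  s <- svd(A)
  pinvA <- s$v[, 1:2] %*% (t(s$u[, 1:2]) / s$d[1:2])
  expect_equal(Wt_white, pinvA, tolerance = 1e-6)
  # dense brute-force formula at 50 channels with a full-rank lead field
  set.seed(52)
  A50 <- matrix(rnorm(150), 50, 3)
  X50 <- matrix(rnorm(50 * 200), 50) + 1i * matrix(rnorm(50 * 200), 50)
  Q50 <- X50 %*% Conj(t(X50)) / 200
  Qr <- Re(Q50) + diag(0.10 * mean(eigen(Re(Q50), only.values = TRUE)$values), 50)
  Qi <- solve(Qr)
  W_dense <- solve(t(A50) %*% Qi %*% A50) %*% t(A50) %*% Qi
  expect_equal(build_dics_filter(Q50, A50, reg = 0.10), W_dense,
               tolerance = 1e-8)
})

test_that("source power is the dominant-orientation eigenvalue and scales quadratically", {
  set.seed(53)
  Wt <- matrix(rnorm(30), 3, 10)
  X <- matrix(rnorm(10 * 50), 10) + 1i * matrix(rnorm(10 * 50), 10)
  Q <- X %*% Conj(t(X)) / 50
  p <- dics_source_power(Wt, Q)
  expect_gte(p, 0)
  expect_equal(dics_source_power(Wt, 4 * Q), 4 * p, tolerance = 1e-12)
  # eigen projection beats any fixed orientation (Rayleigh maximality)
  S <- Re(Wt %*% Q %*% t(Wt))
  for (k in 1:5) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    expect_gte(p + 1e-12, as.numeric(t(u) %*% S %*% u))
  }
})

test_that("identical baseline and active content yields zero t everywhere", {
  tg <- tg_small()
  g <- mini_grid(tg)
  lf <- leadfield_matrix(tg$head, tg$array, g)
  fs <- 250
  times <- seq(-0.7, 0.8, by = 1 / fs)
  set.seed(54)
  ntr <- 12
  nch <- 80
  data <- array(rnorm(ntr * nch * length(times)), c(ntr, nch, length(times)))
  bsel <- which(times >= -0.5 & times <= -0.1)
  asel <- which(times >= 0.25 & times <= 0.65)
  for (tr in 1:ntr) data[tr, , asel[seq_along(bsel)]] <- data[tr, , bsel]
  ep <- epochs(data, fs, times, tg$array$channel_names)
  fit <- dics_fit(ep, tg$head, tg$array, g, band = c(8, 12),
                  active_win = c(0.25, 0.65 - 1e-9), n_perm = 200,
                  leadfield = lf, seed = 1)
  expect_lt(max(abs(fit$map$t)), 1e-6)
  expect_false(any(fit$map$significant))
})

test_that("label swap flips the t statistic exactly", {
  tg <- tg_small()
  g <- mini_grid(tg)
  lf <- leadfield_matrix(tg$head, tg$array, g)
  i <- 2
  ori <- svd(meglat:::lf_block(lf, i))$v[, 1]
  ep <- simulate_erd_epochs(tg$head, tg$array, g$points[i, ], ori,
                            band = c(8, 12), power_change = -0.6,
                            n_trials = 14, snr = 3, fs = 250, seed = 55)
  f1 <- dics_fit(ep, tg$head, tg$array, g, band = c(8, 12),
                 baseline_win = c(-0.5, -0.1), active_win = c(0.25, 0.65),
                 n_perm = 200, leadfield = lf, seed = 2)
  f2 <- dics_fit(ep, tg$head, tg$array, g, band = c(8, 12),
                 baseline_win = c(0.25, 0.65), active_win = c(-0.5, -0.1),
                 n_perm = 200, leadfield = lf, seed = 2)
  expect_equal(f2$map$t, -f1$map$t, tolerance = 1e-9)
})

test_that("a strong oscillatory ERD source is localized and lateralized", {
  tg <- tg_small()
  i <- pick_source(tg, depth_frac = 0.25)
  p <- tg$grid$points[i, ]
  ori <- principal_orientations(tg$lf, i)[, 1]
  ep <- simulate_erd_epochs(tg$head, tg$array, p, ori, band = c(8, 12),
                            power_change = -0.7, n_trials = 20, snr = 5,
                            fs = 250, seed = 56)
  fit <- dics_fit(ep, tg$head, tg$array, tg$grid, tg$atlas, band = c(8, 12),
                  n_perm = 500, leadfield = tg$lf, seed = 3)
  map <- fit$map
  # strongest power drop near the source
  ratio <- map$pow_act / map$pow_base
  best <- which.min(ratio)
  expect_lt(sqrt(sum((tg$grid$points[best, ] - p)^2)), 2 * tg$grid$spacing)
  # significant ERD points exist and include the source neighbourhood
  sig_erd <- map$significant & map$direction == "ERD"
  expect_gt(sum(sig_erd), 0)
  dmin <- min(sqrt(rowSums(sweep(tg$grid$points[sig_erd, , drop = FALSE],
                                 2, p)^2)))
  expect_lt(dmin, 2 * tg$grid$spacing)
  # regularization sweep does not change the ERD laterality side
  side <- sign(fit$li$ERD$li)
  for (reg in c(0.01, 0.15)) {
    fr <- dics_fit(ep, tg$head, tg$array, tg$grid, tg$atlas, band = c(8, 12),
                   n_perm = 200, reg = reg, leadfield = tg$lf, seed = 3)
    expect_identical(sign(fr$li$ERD$li), side)
  }
})

test_that("DICS laterality bookkeeping partitions counts and flags no-source", {
  atlas <- mini_atlas()
  map <- data.frame(point = 1:8,
                    pow_base = 1, pow_act = c(rep(0.5, 4), rep(1.5, 4)),
                    t = c(rep(-3, 4), rep(0.1, 4)),
                    p = c(rep(0.01, 4), rep(0.9, 4)),
                    significant = c(rep(TRUE, 4), rep(FALSE, 4)),
                    direction = c(rep("ERD", 4), rep("ERS", 4)))
  lat <- dics_laterality(map, atlas)
  expect_equal(lat$li$ERD$li, 1)                       # all ERD sources left
  expect_true(lat$li$ERS$no_source)
  expect_equal(lat$detail$n_sig_language +
                 lat$detail$n_sig_nonlanguage, lat$detail$n_sig_all)
  expect_false(lat$detail$no_language_source)
  map$significant <- FALSE
  lat0 <- dics_laterality(map, atlas)
  expect_true(lat0$detail$no_language_source)
  expect_true(lat0$li$ERD$no_source)
})
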