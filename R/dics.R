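## DICS: dynamic imaging of coherent sources.  A frequency-domain vector
## beamformer built from the sensor cross-spectral density (CSD), used here
## to contrast oscillatory source power between a pre-stimulus baseline and
## a post-stimulus active window (event-related desynchronization /
## synchronization) with a common filter and nonparametric paired
## statistics.

#' Canonical frequency bands
#'
#' alpha 8-12, low beta 12-20, high beta 20-30, low gamma 30-50 and high
#' gamma 50-110 Hz; shared edges belong to the lower band (the FFT
#' bin-centre rule makes exact-edge bins the only overlap).
#' @export
dics_bands <- function() {
  list(alpha = c(8, 12), low_beta = c(12, 20), high_beta = c(20, 30),
       low_gamma = c(30, 50), high_gamma = c(50, 110))
}

#' Cross-spectral density of epoched data
#'
#' Hanning-windowed FFT of the analysis window of every epoch;
#' `Q(f) = mean over epochs of X(f) X^H(f)` at every FFT bin whose centre
#' frequency falls inside `band` (inclusive).
#'
#' @param ep an [epochs()] object.
#' @param window analysis window in seconds (e.g. baseline or active).
#' @param band `c(f_lo, f_hi)` Hz.
#' @param keep_spectra keep the per-epoch spectra (needed for per-epoch
#'   source power and the paired permutation test).
#' @return Object of class `csd`: `freqs`, `Q` (list of channels x channels
#'   complex Hermitian matrices), `X` (list of channels x epochs complex,
#'   or `NULL`), `n_epochs`.
#' @export
compute_csd <- function(ep, window, band, keep_spectra = FALSE) {
  stopifnot(inherits(ep, "epochs"))
  sel <- which(ep$times >= window[1] & ep$times <= window[2])
  if (length(sel) < 4) stop("analysis window contains too few samples")
  n <- length(sel)
  fs <- ep$fs
  freqs <- (seq_len(n) - 1) * fs / n
  bins <- which(freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2)
  if (!length(bins))
    stop(sprintf("no FFT bin centre inside [%g, %g] Hz (bin spacing %.3g Hz); widen the band or the window",
                 band[1], band[2], fs / n))
  han <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  ntr <- dim(ep$data)[1]; nch <- dim(ep$data)[2]
  X <- lapply(bins, function(b) matrix(0i, nch, ntr))
  for (tr in seq_len(ntr)) {
    seg <- matrix(ep$data[tr, , sel], nch, n)
    Ft <- stats::mvfft(t(seg * rep(han, each = nch)))   # n x nch
    for (k in seq_along(bins)) X[[k]][, tr] <- Ft[bins[k], ]
  }
  Q <- lapply(X, function(x) tcrossprod(x, Conj(x)) / ntr)
  structure(list(freqs = freqs[bins], Q = Q,
                 X = if (keep_spectra) X else NULL,
                 n_epochs = ntr, window = window, band = band),
            class = "csd")
}

#' @export
print.csd <- function(x, ...) {
  cat(sprintf("CSD: %d bins at [%s] Hz, %d epochs, window [%g, %g] s\n",
              length(x$freqs), paste(signif(x$freqs, 4), collapse = ", "),
              x$n_epochs, x$window[1], x$window[2]))
  invisible(x)
}

## regularized real CSD inverse: Re(Q) + reg * mean(eig(Re Q)) * I
csd_inverse <- function(Q, reg = 0.10) {
  Qr <- Re(Q)
  mu <- mean(eigen(Qr, symmetric = TRUE, only.values = TRUE)$values)
  solve(Qr + diag(reg * mu, nrow(Qr)))
}

## 3x3 symmetric pseudo-inverse on the leading (tangential) subspace; the
## radial lead-field direction is silent in a spherical conductor, so the
## bracket A^T Qi A is rank 2 by construction.
pinv3 <- function(B, tol = 1e-9) {
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

#' DICS spatial filter at one source point
#'
#' `W^T = [A^T Qi A]^+ A^T Qi` with `Qi` the regularized inverse of the
#' real part of the (combined-condition) CSD; the 3x3 bracket is inverted
#' on its tangential subspace (the radial direction is silent in a
#' spherical head).
#'
#' @param Q channels x channels complex CSD (combined conditions).
#' @param A channels x 3 lead field of the point.
#' @param reg regularization as a fraction of the mean eigenvalue of
#'   `Re(Q)`, default 0.10.
#' @return 3 x channels real filter matrix `Wt`.
#' @export
build_dics_filter <- function(Q, A, reg = 0.10) {
  if (all(A == 0)) stop("zero lead field at this point")
  Qi <- csd_inverse(Q, reg)
  M <- Qi %*% A
  pinv3(crossprod(A, M)) %*% t(M)
}

#' Source power of a condition CSD through a DICS filter
#'
#' Largest eigenvalue of the real part of `W^T Q W` (projection along the
#' dominant source orientation).
#'
#' @param Wt 3 x channels filter from [build_dics_filter()].
#' @param Q condition CSD at the same frequency.
#' @return scalar power (>= 0).
#' @export
dics_source_power <- function(Wt, Q) {
  S <- Re(Wt %*% Q %*% t(Wt))
  p <- max(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (!is.finite(p)) stop("non-finite source power")
  p
}

#' DICS beamformer ERD/ERS analysis
#'
#' Computes baseline-, active- and combined-condition CSDs in `band`, builds
#' a common filter per grid point from the combined CSD, passes the
#' per-epoch spectra of both conditions through it (per-epoch source power =
#' squared norm of the filtered spectrum, averaged over the FFT bins of the
#' band), and tests the paired baseline/active difference per point with a
#' dependent-sample t statistic whose null distribution is obtained by
#' randomly permuting the two condition labels within epochs.  Cluster-based
#' correction (clusters of |t| above the paired-t critical value on the grid
#' adjacency, cluster mass = sum |t|, max-mass null) is available as an
#' alternative to uncorrected p < alpha.
#'
#' @param ep an [epochs()] object (broad-band filtered).
#' @param head,array,grid geometry; `atlas` optional, enables laterality.
#' @param band frequency band `c(f_lo, f_hi)` Hz (see [dics_bands()]).
#' @param baseline_win,active_win analysis windows (s); must have equal
#'   length for a common bin grid.
#' @param reg CSD regularization fraction, default 0.10.
#' @param n_perm number of label permutations, default 10000.
#' @param alpha significance level, default 0.05.
#' @param correction `"none"` (uncorrected point-wise p) or `"cluster"`.
#' @param leadfield optional precomputed [leadfield_matrix()].
#' @param seed integer seed for the permutations.
#' @return Object of class `dics_fit`: `map` (data.frame per point:
#'   pow_base, pow_act, t, p, significant, direction), `band`, `li`
#'   (list of [laterality_result()] per direction, when `atlas` given),
#'   `detail` volume percentages.
#' @export
dics_fit <- function(ep, head, array, grid, atlas = NULL,
                     band = c(8, 12), baseline_win = c(-0.5, -0.1),
                     active_win = c(0.25, 0.65), reg = 0.10,
                     n_perm = 10000, alpha = 0.05,
                     correction = c("none", "cluster"),
                     leadfield = NULL, seed = NULL) {
  correction <- match.arg(correction)
  if (n_perm < 100) warning("n_perm < 100 gives unstable p values")
  if (dim(ep$data)[1] < 10) stop("need at least 10 epochs for the paired test")
  if (is.null(leadfield)) leadfield <- leadfield_matrix(head, array, grid)
  cb <- compute_csd(ep, baseline_win, band, keep_spectra = TRUE)
  ca <- compute_csd(ep, active_win, band, keep_spectra = TRUE)
  if (length(cb$freqs) != length(ca$freqs) ||
      max(abs(cb$freqs - ca$freqs)) > 1e-9)
    stop("baseline and active windows must produce the same FFT bins (equal window lengths)")
  N <- nrow(grid$points)
  E <- cb$n_epochs
  pow_b <- matrix(0, N, E); pow_a <- matrix(0, N, E)
  cond_b <- numeric(N); cond_a <- numeric(N)
  g <- rep(seq_len(N), each = 3L)
  for (k in seq_along(cb$freqs)) {
    Qc <- (cb$Q[[k]] * cb$n_epochs + ca$Q[[k]] * ca$n_epochs) /
      (cb$n_epochs + ca$n_epochs)
    Qi <- csd_inverse(Qc, reg)
    M <- Qi %*% leadfield$matrix                  # channels x 3N
    Wall <- matrix(0, 3L * N, ncol(Qi))
    for (i in seq_len(N)) {
      cols <- 3L * (i - 1L) + 1:3
      A <- leadfield$matrix[, cols, drop = FALSE]
      Wall[cols, ] <- pinv3(crossprod(A, M[, cols, drop = FALSE])) %*%
        t(M[, cols, drop = FALSE])
    }
    Yb <- Wall %*% cb$X[[k]]; Ya <- Wall %*% ca$X[[k]]
    pow_b <- pow_b + rowsum(Mod(Yb)^2, g)
    pow_a <- pow_a + rowsum(Mod(Ya)^2, g)
    ## condition-level power: dominant orientation of Re(W^T Q W)
    for (i in seq_len(N)) {
      cols <- 3L * (i - 1L) + 1:3
      Wt <- Wall[cols, , drop = FALSE]
      cond_b[i] <- cond_b[i] + dics_source_power(Wt, cb$Q[[k]])
      cond_a[i] <- cond_a[i] + dics_source_power(Wt, ca$Q[[k]])
    }
  }
  nb <- length(cb$freqs)
  pow_b <- pow_b / nb; pow_a <- pow_a / nb       # band power: mean over bins
  cond_b <- cond_b / nb; cond_a <- cond_a / nb

  D <- pow_a - pow_b                              # N x E paired differences
  md <- rowMeans(D)
  ss <- rowSums(D^2)
  sd_d <- sqrt(pmax(0, (ss - E * md^2) / (E - 1)))
  tval <- md / (sd_d / sqrt(E))
  tval[sd_d == 0] <- 0

  if (!is.null(seed)) set.seed(as.integer(seed))
  S <- matrix(sample(c(-1, 1), E * n_perm, replace = TRUE), E, n_perm)
  MD <- (D %*% S) / E                             # N x n_perm permuted means
  TS <- MD / (sqrt(pmax(0, (ss - E * MD^2) / (E - 1))) / sqrt(E))
  TS[!is.finite(TS)] <- 0

  if (correction == "none") {
    p <- (1 + rowSums(abs(TS) >= abs(tval))) / (n_perm + 1)
    signif <- p < alpha
  } else {
    tcrit <- stats::qt(1 - alpha / 2, E - 1)
    obs <- cluster_masses(tval, grid$adjacency, tcrit)
    nullmax <- apply(TS, 2, function(tv)
      max(c(0, cluster_masses(tv, grid$adjacency, tcrit)$mass)))
    p <- rep(1, N)
    signif <- rep(FALSE, N)
    if (length(obs$mass)) {
      pc <- vapply(obs$mass, function(m)
        (1 + sum(nullmax >= m)) / (n_perm + 1), numeric(1))
      for (ci in seq_along(obs$mass)) {
        p[obs$members[[ci]]] <- pc[ci]
        if (pc[ci] < alpha) signif[obs$members[[ci]]] <- TRUE
      }
    }
  }

  map <- data.frame(point = seq_len(N), pow_base = cond_b, pow_act = cond_a,
                    t = tval, p = p, significant = signif,
                    direction = ifelse(cond_a < cond_b, "ERD", "ERS"))
  li <- detail <- NULL
  if (!is.null(atlas)) {
    lat <- dics_laterality(map, atlas)
    li <- lat$li; detail <- lat$detail
  }
  structure(list(map = map, band = band, reg = reg, n_perm = n_perm,
                 alpha = alpha, correction = correction, li = li,
                 detail = detail, n_epochs = E, grid = grid),
            class = "dics_fit")
}

## connected clusters of |t| > tcrit (same-sign components) on the grid
## adjacency; returns per-cluster mass (sum |t|) and members
cluster_masses <- function(tval, adjacency, tcrit) {
  supra <- which(abs(tval) > tcrit)
  mass <- numeric(0); members <- list()
  if (!length(supra)) return(list(mass = mass, members = members))
  in_supra <- logical(length(tval)); in_supra[supra] <- TRUE
  seen <- logical(length(tval))
  for (s in supra) {
    if (seen[s]) next
    comp <- integer(0); queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adjacency[[v]])
        if (in_supra[w] && !seen[w] && sign(tval[w]) == sign(tval[v])) {
          seen[w] <- TRUE; queue <- c(queue, w)
        }
    }
    mass <- c(mass, sum(abs(tval[comp])))
    members[[length(members) + 1L]] <- comp
  }
  list(mass = mass, members = members)
}

#' @export
print.dics_fit <- function(x, ...) {
  cat(sprintf("DICS ERD/ERS analysis: band [%g, %g] Hz, %d points, %d epochs, %s correction\n",
              x$band[1], x$band[2], nrow(x$map), x$n_epochs, x$correction))
  cat(sprintf("  %d significant points (alpha = %g, %d permutations)\n",
              sum(x$map$significant), x$alpha, x$n_perm))
  if (!is.null(x$li)) { print(x$li$ERD); print(x$li$ERS) }
  invisible(x)
}

#' Laterality and volume percentages of a DICS map
#'
#' Counts statistically significant sources inside the language-flagged
#' atlas ROIs, split by hemisphere and by direction (ERD: active power
#' below baseline; ERS: above), and reports the volume percentages of
#' significant points in the language area, the non-language area and the
#' whole grid.
#'
#' @param map the `$map` data.frame of a [dics_fit()] (or the fit itself).
#' @param atlas the atlas labelling the grid points.
#' @return list with `li` (list of [laterality_result()] for ERD and ERS)
#'   and `detail` (percentages and the no-source flag).
#' @export
dics_laterality <- function(map, atlas) {
  if (inherits(map, "dics_fit")) map <- map$map
  lang <- atlas$table$is_language
  hemi <- atlas$table$hemisphere
  li <- list()
  for (dirn in c("ERD", "ERS")) {
    sig <- map$significant & map$direction == dirn
    L <- sum(sig & lang & hemi == "L")
    R <- sum(sig & lang & hemi == "R")
    li[[dirn]] <- laterality_result(L, R, method = paste0("dics-", dirn))
  }
  sig <- map$significant
  detail <- list(
    pct_language = 100 * sum(sig & lang) / max(1, sum(lang)),
    pct_nonlanguage = 100 * sum(sig & !lang) / max(1, sum(!lang)),
    pct_all = 100 * sum(sig) / nrow(map),
    n_sig_language = sum(sig & lang),
    n_sig_nonlanguage = sum(sig & !lang),
    n_sig_all = sum(sig),
    no_language_source = sum(sig & lang) == 0)
  list(li = li, detail = detail)
}

#' @export
laterality.dics_fit <- function(object, direction = c("ERD", "ERS"), ...) {
  direction <- match.arg(direction)
  if (is.null(object$li)) stop("fit was run without an atlas")
  object$li[[direction]]
}
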