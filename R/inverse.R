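## Minimum-norm and noise-normalized (dSPM) distributed inverse solutions.
##
## The inverse operator is W = R A^T (A R A^T + lambda^2 C)^-1 with source
## covariance R = c I scaled so that trace(A R A^T) = trace(C), computed in
## the pre-whitened sensor basis for conditioning (identical in exact
## arithmetic).  The dSPM map divides the per-location MNE power by its
## projected noise variance and is F(3, dof)-distributed under the null,
## with the denominator dof given by the number of noise samples behind C.

#' Estimate the sensor noise covariance from an empty-room recording
#'
#' Sample covariance over samples (channel means removed) with a small
#' diagonal loading (`1e-10` of the mean diagonal) for invertibility.
#'
#' @param x channels x samples matrix or a [simulate_empty_room()] record.
#' @return Object of class `noise_cov`: `C`, `n_samples`, `loading`.
#' @export
estimate_noise_cov <- function(x) {
  if (inherits(x, "raw_noise")) x <- x$data
  stopifnot(is.matrix(x))
  if (all(x == 0)) stop("noise record is identically zero")
  ns <- ncol(x)
  if (ns < nrow(x))
    warning("fewer samples than channels: covariance is rank deficient (diagonal loading applied)")
  xc <- x - rowMeans(x)
  C <- tcrossprod(xc) / ns
  load <- 1e-10 * mean(diag(C))
  C <- C + diag(load, nrow(C))
  structure(list(C = C, n_samples = ns, loading = load),
            class = "noise_cov")
}

#' Minimum-norm inverse operator
#'
#' Builds the linear inverse weights for a free-orientation (3 components
#' per point) volumetric source space.  The source covariance is a scaled
#' identity with the scale solving `trace(A R A^T) = trace(C)`; the lead
#' field is pre-whitened with the noise covariance; the regularization
#' parameter `lambda2` defaults to 3.
#'
#' @param leadfield a [leadfield_matrix()].
#' @param noise_cov an [estimate_noise_cov()] result.
#' @param lambda2 regularization parameter (unitless, whitened basis).
#' @return Object of class `inverse_operator`: `W` ((3 points) x channels),
#'   `C`, `lambda2`, `source_scale`, `dof` (noise samples), `grid`.
#' @export
inverse_operator <- function(leadfield, noise_cov, lambda2 = 3) {
  stopifnot(inherits(leadfield, "leadfield"), inherits(noise_cov, "noise_cov"))
  A <- leadfield$matrix
  C <- noise_cov$C
  if (nrow(A) != nrow(C)) stop("lead field and covariance disagree on channels")
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("noise covariance is not positive definite; increase diagonal loading")
  whitener <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  cscale <- sum(diag(C)) / sum(A^2)     # trace(A R A^T) = trace(C), R = c I
  At <- whitener %*% A
  G <- cscale * tcrossprod(At) + diag(lambda2, nrow(At))
  W <- cscale * t(At) %*% solve(G) %*% whitener
  structure(list(W = W, C = C, lambda2 = lambda2, source_scale = cscale,
                 dof = noise_cov$n_samples, grid = leadfield$grid),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("Minimum-norm inverse operator: %d sources x %d channels, lambda^2 = %g, dof = %d\n",
              nrow(x$W) / 3, ncol(x$W), x$lambda2, x$dof))
  invisible(x)
}

#' Apply the minimum-norm inverse to an evoked field
#'
#' `s(t) = W x(t)`: linear in the data, three moment components per source
#' point.
#'
#' @param op an [inverse_operator()]; `evoked` an [evoked()] object.
#' @return Object of class `mne_fit`: `sol` ((3 points) x samples),
#'   `times`, `grid`.
#' @export
apply_mne <- function(op, evoked) {
  stopifnot(inherits(op, "inverse_operator"), inherits(evoked, "evoked"))
  if (ncol(op$W) != nrow(evoked$data))
    stop("channel count of evoked does not match the operator")
  structure(list(sol = op$W %*% evoked$data, times = evoked$times,
                 grid = op$grid, method = "mne"),
            class = "mne_fit")
}

#' @export
print.mne_fit <- function(x, ...) {
  cat(sprintf("MNE source estimate: %d points x %d samples\n",
              nrow(x$sol) / 3, ncol(x$sol)))
  invisible(x)
}

## per-point power time course: ||s_i(t)||^2 over the 3 components
point_power <- function(sol) {
  N <- nrow(sol) / 3L
  g <- rep(seq_len(N), each = 3L)
  out <- rowsum(sol^2, g)
  rownames(out) <- NULL
  out
}

#' Noise-normalized (dSPM) source estimate
#'
#' `q_i(t) = sum_j (w_j x(t))^2 / sum_j w_j C w_j^T` over the three moment
#' components j of point i: the MNE power normalized by its projected noise
#' variance.  Under the null (sensor data = noise with covariance C) each
#' `q_i` has mean 1 and is F(3, dof) distributed.
#'
#' @param op an [inverse_operator()]; `evoked` an [evoked()] object.
#' @return Object of class `dspm_fit`: `q` (points x samples), `times`,
#'   `dof`, `grid`.
#' @export
apply_dspm <- function(op, evoked) {
  stopifnot(inherits(op, "inverse_operator"), inherits(evoked, "evoked"))
  N <- nrow(op$W) / 3L
  g <- rep(seq_len(N), each = 3L)
  M <- op$W %*% op$C
  denom <- as.numeric(rowsum(rowSums(M * op$W), g))
  num <- point_power(op$W %*% evoked$data)
  zero <- denom <= 0
  denom[zero] <- 1
  q <- num / denom
  q[zero, ] <- 0
  structure(list(q = q, times = evoked$times, dof = op$dof,
                 flagged_points = which(zero), grid = op$grid,
                 method = "dspm"),
            class = "dspm_fit")
}

#' @export
print.dspm_fit <- function(x, ...) {
  cat(sprintf("dSPM source estimate: %d points x %d samples (F(3, %d) null)\n",
              nrow(x$q), ncol(x$q), x$dof))
  invisible(x)
}

#' Window-mean dSPM power with Bonferroni threshold
#'
#' Averages the noise-normalized power over the analysis window and masks
#' points whose mean exceeds the F(3, dof) critical value at
#' `alpha / n_points` (Bonferroni over source locations).
#'
#' @param fit an [apply_dspm()] result.
#' @param window time window in seconds, default `c(0.15, 0.6)`.
#' @param alpha family-wise error level, default 0.05.
#' @return list with `power` (per point), `significant` (logical),
#'   `critical` (threshold used).
#' @export
dspm_threshold <- function(fit, window = c(0.15, 0.6), alpha = 0.05) {
  stopifnot(inherits(fit, "dspm_fit"))
  sel <- fit$times >= window[1] & fit$times <= window[2]
  if (!any(sel)) stop("`window` contains no samples")
  if (alpha >= 1) {
    pw <- rowMeans(fit$q[, sel, drop = FALSE])
    return(list(power = pw, significant = rep(TRUE, length(pw)),
                critical = -Inf))
  }
  pw <- rowMeans(fit$q[, sel, drop = FALSE])
  crit <- stats::qf(1 - alpha / nrow(fit$q), 3, fit$dof)
  list(power = pw, significant = pw > crit, critical = crit)
}

#' Laterality from distributed source estimates
#'
#' For MNE, L and R are the mean window power over the left/right
#' language-flagged atlas points.  For dSPM the map is Bonferroni
#' thresholded first and L/R are computed over the surviving language
#' points; with `mode = "count"` the numbers of significant language points
#' are used instead, and `mode = "amplitude"` uses the window-mean amplitude
#' `sqrt(power)`.
#'
#' @param object an `mne_fit` or `dspm_fit`.
#' @param atlas the atlas labelling the grid points.
#' @param window analysis window (s).
#' @param mode `"mean_power"` (default), `"count"` or `"amplitude"`.
#' @param alpha threshold level for dSPM.
#' @param ... unused.
#' @return A [laterality_result()].
#' @export
laterality.mne_fit <- function(object, atlas, window = c(0.15, 0.6),
                               mode = c("mean_power", "count", "amplitude"),
                               ...) {
  mode <- match.arg(mode)
  sel <- object$times >= window[1] & object$times <= window[2]
  pw <- rowMeans(point_power(object$sol)[, sel, drop = FALSE])
  lat_from_power(pw, rep(TRUE, length(pw)), atlas, mode, "mne")
}

#' @rdname laterality.mne_fit
#' @export
laterality.dspm_fit <- function(object, atlas, window = c(0.15, 0.6),
                                mode = c("mean_power", "count", "amplitude"),
                                alpha = 0.05, ...) {
  mode <- match.arg(mode)
  th <- dspm_threshold(object, window, alpha)
  lat_from_power(th$power, th$significant, atlas, mode, "dspm")
}

lat_from_power <- function(power, significant, atlas, mode, method) {
  lang <- atlas$table$is_language
  hemi <- atlas$table$hemisphere
  left <- lang & hemi == "L" & significant
  right <- lang & hemi == "R" & significant
  agg <- switch(mode,
    mean_power = function(i) if (any(i)) mean(power[i]) else 0,
    amplitude = function(i) if (any(i)) mean(sqrt(power[i])) else 0,
    count = function(i) sum(i))
  laterality_result(agg(left), agg(right), method = method)
}

#' Export a source map as TSV
#' @param grid the source grid; `value` per-point values;
#'   `significant` optional logical; `path` output file.
#' @export
write_source_map_tsv <- function(grid, value, path, significant = NULL) {
  out <- data.frame(point_index = seq_len(nrow(grid$points)),
                    x = grid$points[, 1], y = grid$points[, 2],
                    z = grid$points[, 3], value = value)
  if (!is.null(significant)) out$significant <- significant
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
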