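## Hemispheric laterality index and session-level reliability metrics,
## shared by the dipole, MNE, dSPM and DICS analysis paths.

#' Laterality index
#'
#' `LI = (L - R) / (L + R)` for non-negative left/right quantities (dipole
#' counts, significant-source counts, or mean source power).  +1 is fully
#' left-lateralized, -1 fully right.  `L + R = 0` means no language source
#' was found and yields `NA`.
#'
#' @param L,R non-negative scalars.
#' @return The LI in `[-1, 1]`, or `NA_real_` when `L + R = 0`.
#' @export
compute_li <- function(L, R) {
  if (L < 0 || R < 0) stop("`L` and `R` must be non-negative")
  if (L + R == 0) return(NA_real_)
  (L - R) / (L + R)
}

#' Categorical lateralization call
#'
#' `li > threshold` is "left", `li < -threshold` is "right", everything in
#' the closed interval `[-threshold, threshold]` (including the boundary) is
#' "bilateral"; `NA` maps to "no-source".  The default threshold of 0.1 is a
#' package convention (commonly used in laterality studies) and is fully
#' configurable: published category counts may be based on a different,
#' unpublished cut-off.
#'
#' @param li laterality index in `[-1, 1]` or `NA`.
#' @param threshold bilateral half-width, default 0.1.
#' @return One of "left", "right", "bilateral", "no-source".
#' @export
classify_laterality <- function(li, threshold = 0.1) {
  if (is.na(li)) return("no-source")
  if (li > threshold) "left" else if (li < -threshold) "right" else "bilateral"
}

#' Bundle a left/right pair into a laterality result
#'
#' @param L,R non-negative counts or powers; `method` label;
#'   `threshold` see [classify_laterality()]; `session` optional label;
#'   `detail` optional list of extras (e.g. volume percentages).
#' @return Object of class `laterality_result` with fields `L`, `R`, `li`,
#'   `category`, `no_source`.
#' @export
laterality_result <- function(L, R, method = "unknown", threshold = 0.1,
                              session = NA_character_, detail = NULL) {
  li <- compute_li(L, R)
  structure(list(L = L, R = R, li = li,
                 category = classify_laterality(li, threshold),
                 no_source = is.na(li), method = method,
                 threshold = threshold, session = session, detail = detail),
            class = "laterality_result")
}

#' @export
print.laterality_result <- function(x, ...) {
  if (x$no_source) {
    cat(sprintf("Laterality [%s]: no language source (L = R = 0)\n", x$method))
  } else {
    cat(sprintf("Laterality [%s]: LI = %+.3f (L = %.4g, R = %.4g) -> %s\n",
                x$method, x$li, x$L, x$R, x$category))
  }
  invisible(x)
}

#' Laterality of a fitted analysis object
#'
#' Generic accessor returning the [laterality_result()] of an `ecd_fit`,
#' `mne_fit`, `dspm_fit` or `dics_fit`.
#' @param object a fitted object; `...` passed on.
#' @export
laterality <- function(object, ...) UseMethod("laterality")

#' @export
laterality.ecd_fit <- function(object, ...) object$li

#' @export
laterality.default <- function(object, ...)
  stop("no laterality method for this object")

#' Test-retest reliability of laterality indices
#'
#' Pearson correlation (with the two-sided t-based p value) between paired
#' LI vectors from two sessions.
#'
#' @param li_session1,li_session2 numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `n`, and `flag` ("zero-variance" when the
#'   correlation is undefined).
#' @export
session_reliability <- function(li_session1, li_session2) {
  if (length(li_session1) != length(li_session2))
    stop("sessions must be paired (equal length)")
  ok <- stats::complete.cases(li_session1, li_session2)
  x <- li_session1[ok]; y <- li_session2[ok]
  if (length(x) < 3) stop("need at least 3 paired sessions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                flag = "zero-variance"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), flag = "ok")
}

#' Between-method agreement of laterality indices
#'
#' Full symmetric Pearson correlation matrix (with p values) across the
#' columns of a sessions x methods LI matrix; missing entries are handled
#' pairwise-complete and flagged.
#'
#' @param li_by_method numeric matrix, rows = sessions (>= 3),
#'   columns = methods.
#' @return list with matrices `r` and `p`, and `incomplete` flag.
#' @export
method_agreement <- function(li_by_method) {
  m <- as.matrix(li_by_method)
  if (nrow(m) < 3) stop("need at least 3 sessions")
  k <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- sprintf("m%d", seq_len(k))
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(colnames(m), colnames(m))
  diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(m[, i], m[, j])
    if (sum(ok) >= 3 && stats::sd(m[ok, i]) > 0 && stats::sd(m[ok, j]) > 0) {
      ct <- stats::cor.test(m[ok, i], m[ok, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, incomplete = anyNA(m))
}
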