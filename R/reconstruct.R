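#' Reduced-rank reconstruction of gene expression
#'
#' Projects the expression matrix back from the spatially smoothed
#' low-rank basis, producing a de-noised, spatially smoothed version of
#' every gene. When the fit carries covariate-integrated outputs, the
#' smoothed PCs are first reconstructed from the second-stage scores
#' (`Pc %*% t(Wc)`, restricted to the PC block, plus the column means of
#' `Ps`), so the covariate signal shapes the result. Each gene is then
#' thresholded ALRA-style at the `q`-quantile of its reconstructed values:
#' entries whose absolute reconstruction reaches `|xq|` are kept, entries
#' below it revert to the original value when that was positive and to
#' zero otherwise — so genuine zeros stay exactly zero. With
#' `scale = TRUE` each kept gene is rescaled so the standard deviation of
#' its nonzero reconstructed values matches that of the nonzero originals.
#'
#' Reconstruction is intended primarily for visualization: smoothing
#' borrows signal across neighbouring locations and can blur expression
#' across real tissue boundaries at large neighbourhood sizes.
#'
#' @param X the normalized expression matrix given to [rasp()] (a
#'   `rasp_expr` or matrix).
#' @param fit a `rasp_fit`.
#' @param q quantile probability in `[0, 1]` for thresholding. The
#'   quantile is taken over the signed reconstructed values (type-7
#'   sample quantile); set `absolute = TRUE` for an ALRA-style quantile of
#'   absolute values.
#' @param scale match per-gene nonzero variance to the original data.
#' @param absolute take the threshold quantile over `|Xr|` instead of the
#'   signed values.
#' @return A `rasp_reconstruction`: dense `Xr`, per-gene thresholds `xq`,
#'   and scale factors `s` (`NA` where scaling was skipped).
#' @export
reduced_rank_reconstruct <- function(X, fit, q = 0.5, scale = FALSE,
                                     absolute = FALSE) {
  stopifnot(inherits(fit, "rasp_fit"))
  if (length(q) != 1L || !is.finite(q) || q < 0 || q > 1) {
    stop_invalid("q must lie in [0, 1]")
  }
  Xm <- if (inherits(X, "rasp_expr")) X$X else X
  n <- nrow(Xm)
  if (n != nrow(fit$Ps)) stop_invalid("X rows must align with the fit")
  p <- ncol(fit$Ps)

  if (!is.null(fit$Pc)) {
    ## second-stage scores reconstruct the centered [Ps, Ys] block;
    ## keep the PC columns and restore the Ps column means
    rec <- fit$Pc %*% t(fit$Wc)
    Ps_r <- rec[, seq_len(p), drop = FALSE] +
      tcrossprod(rep(1, n), fit$second_stage_means[seq_len(p)])
    Xr <- Ps_r %*% t(fit$W)
  } else {
    Xr <- fit$Ps %*% t(fit$W)
  }
  ## undo the implicit scaling/centering of the PCA stage
  Xr <- sweep(Xr, 2, fit$column_scales, "*")
  Xr <- Xr + tcrossprod(rep(1, n), fit$column_means)

  xq <- numeric(ncol(Xr))
  sfac <- rep(NA_real_, ncol(Xr))
  for (i in seq_len(ncol(Xr))) {
    orig <- Xm[, i]
    thr <- threshold_gene(Xr[, i], orig, q, absolute = absolute)
    col <- thr$column
    xq[i] <- thr$xq
    if (scale) {
      sc <- rescale_gene(col, orig)
      col <- sc$column
      sfac[i] <- sc$s
    }
    Xr[, i] <- col
  }
  dimnames(Xr) <- dimnames(Xm)
  structure(list(Xr = Xr, xq = xq, s = sfac, q = q, scale = scale),
            class = "rasp_reconstruction")
}

#' Threshold one reconstructed gene column
#'
#' `xq` is the `q`-quantile (type 7) of the reconstructed values (of their
#' absolute values when `absolute = TRUE`). Entry-wise rule: keep the
#' reconstructed value when `|Xr[j]| >= |xq|`; otherwise fall back to the
#' original value when it is positive, else 0.
#'
#' @param reconstructed,original aligned numeric vectors.
#' @param q quantile probability.
#' @param absolute quantile over absolute values.
#' @return List with the thresholded `column` and the threshold `xq`.
#' @export
threshold_gene <- function(reconstructed, original, q, absolute = FALSE) {
  xq <- if (absolute) {
    stats::quantile(abs(reconstructed), q, names = FALSE, type = 7)
  } else {
    stats::quantile(reconstructed, q, names = FALSE, type = 7)
  }
  keep <- abs(reconstructed) >= abs(xq)
  original <- as.numeric(original)
  out <- ifelse(keep, reconstructed, ifelse(original > 0, original, 0))
  list(column = out, xq = xq)
}

#' Rescale one thresholded gene column to the original nonzero variance
#'
#' `s = sd(original[original != 0]) / max(sd(column[column != 0]), 1e-10)`
#' with sample (n-1) standard deviations. Scaling is skipped (`s = NA`,
#' column returned unchanged) when the original column has fewer than two
#' nonzero values.
#'
#' @param column thresholded reconstructed values.
#' @param original original expression values.
#' @return List with the scaled `column` and the factor `s`.
#' @export
rescale_gene <- function(column, original) {
  original <- as.numeric(original)
  nz_orig <- original[original != 0]
  if (length(nz_orig) < 2L) {
    return(list(column = column, s = NA_real_))
  }
  nz_rec <- column[column != 0]
  sd_rec <- if (length(nz_rec) < 2L) 0 else stats::sd(nz_rec)
  s <- stats::sd(nz_orig) / max(sd_rec, 1e-10)
  list(column = column * s, s = s)
}
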