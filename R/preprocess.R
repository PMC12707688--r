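#' Quality-control thresholds
#'
#' Locations are removed when (i) their combined mitochondrial/ribosomal
#' read fraction exceeds `max_mito_ribo_fraction`, (ii) their total read
#' count falls below `min_reads`, or (iii) their total exceeds
#' `median + mad_multiplier * MAD` of the per-location totals. The MAD is
#' the unscaled median absolute deviation (no 1.4826 consistency constant),
#' and the rule is one-sided (upper tail), targeting doublet-like outliers.
#'
#' @param max_mito_ribo_fraction maximum tolerated mito+ribo fraction.
#' @param min_reads minimum total reads per location.
#' @param mad_multiplier multiplier on the MAD for the upper bound.
#' @return A `rasp_qc_thresholds` list.
#' @export
qc_thresholds <- function(max_mito_ribo_fraction = 0.10, min_reads = 100,
                          mad_multiplier = 5) {
  if (max_mito_ribo_fraction < 0 || max_mito_ribo_fraction > 1) {
    stop_invalid("max_mito_ribo_fraction must lie in [0, 1]")
  }
  if (min_reads <= 0 || mad_multiplier <= 0) {
    stop_invalid("min_reads and mad_multiplier must be positive")
  }
  structure(list(max_mito_ribo_fraction = max_mito_ribo_fraction,
                 min_reads = min_reads, mad_multiplier = mad_multiplier),
            class = "rasp_qc_thresholds")
}

#' Filter low-quality locations
#'
#' All three rules are evaluated on the unfiltered matrix, so the retained
#' set does not depend on the order in which rules are applied.
#'
#' @param counts a `rasp_counts` (or location-by-gene matrix).
#' @param mito_ribo_gene_ids character vector of mitochondrial/ribosomal
#'   gene IDs; may be empty, making the fraction rule a no-op. Prefix
#'   conventions differ across species and panels, so the caller supplies
#'   the set explicitly.
#' @param thresholds a [qc_thresholds()] object.
#' @return List with the filtered `counts` and a `report` giving per-rule
#'   removal counts and the retained index.
#' @export
qc_filter <- function(counts, mito_ribo_gene_ids = character(),
                      thresholds = qc_thresholds()) {
  obj <- if (inherits(counts, "rasp_counts")) counts else NULL
  mat <- if (is.null(obj)) counts else obj$counts
  totals <- Matrix::rowSums(mat)
  mr_cols <- which(colnames(mat) %in% mito_ribo_gene_ids)
  mr_frac <- if (length(mr_cols)) {
    Matrix::rowSums(mat[, mr_cols, drop = FALSE]) / pmax(totals, 1)
  } else {
    rep(0, nrow(mat))
  }
  med <- stats::median(totals)
  mad0 <- stats::median(abs(totals - med))      # unscaled MAD
  upper <- med + thresholds$mad_multiplier * mad0

  fail_mr <- mr_frac > thresholds$max_mito_ribo_fraction
  fail_low <- totals < thresholds$min_reads
  fail_high <- totals > upper
  keep <- !(fail_mr | fail_low | fail_high)
  if (!any(keep)) {
    stop_invalid("QC removed every location; relax the thresholds")
  }
  report <- list(
    n_input = nrow(mat),
    n_removed_mito_ribo = sum(fail_mr),
    n_removed_low_reads = sum(fail_low),
    n_removed_high_reads = sum(fail_high),
    n_retained = sum(keep),
    upper_bound = upper,
    retained = which(keep)
  )
  out <- if (is.null(obj)) {
    mat[keep, , drop = FALSE]
  } else {
    obj$counts <- mat[keep, , drop = FALSE]
    obj$location_ids <- obj$location_ids[keep]
    if (!is.null(obj$layout)) {
      obj$layout$coords <- obj$layout$coords[keep, , drop = FALSE]
      obj$layout$domain <- obj$layout$domain[keep]
    }
    obj
  }
  list(counts = out, report = report)
}

#' Library-size normalize and log-transform counts
#'
#' Each location is scaled to `target_sum` total counts (default: the
#' median of the per-location totals), then `log(1 + x)` is applied when
#' `log_transform` is `TRUE`. With `scale_genes = TRUE` every gene is
#' additionally divided by its standard deviation (unit variance, no
#' centering, preserving sparsity). The raw per-location totals are kept as
#' a candidate covariate for the two-stage PCA.
#'
#' @param counts a `rasp_counts` or matrix.
#' @param target_sum target library size; `NULL` uses the median total.
#' @param log_transform apply `log1p` after size normalization.
#' @param scale_genes divide genes by their standard deviation.
#' @return A `rasp_expr`: sparse `X`, `location_ids`, `gene_ids`,
#'   `total_counts`, `coords` (when known), `target_sum`.
#' @export
normalize_expression <- function(counts, target_sum = NULL,
                                 log_transform = TRUE, scale_genes = FALSE) {
  obj <- if (inherits(counts, "rasp_counts")) counts else NULL
  mat <- if (is.null(obj)) {
    as(as(counts, "generalMatrix"), "CsparseMatrix")
  } else {
    obj$counts
  }
  totals <- Matrix::rowSums(mat)
  if (any(totals == 0)) {
    stop_invalid("locations with zero total counts must be removed by QC first")
  }
  if (is.null(target_sum)) target_sum <- stats::median(totals)
  X <- Matrix::Diagonal(x = target_sum / totals) %*% mat
  if (log_transform) X@x <- log1p(X@x)
  if (scale_genes) {
    sds <- col_sds_sparse(X)
    sds[sds == 0] <- 1
    X <- X %*% Matrix::Diagonal(x = 1 / sds)
  }
  X <- as(X, "CsparseMatrix")
  dimnames(X) <- dimnames(mat)
  structure(
    list(X = X,
         location_ids = rownames(mat),
         gene_ids = colnames(mat),
         total_counts = totals,
         coords = if (!is.null(obj) && !is.null(obj$layout)) obj$layout$coords,
         domain = if (!is.null(obj) && !is.null(obj$layout)) obj$layout$domain,
         target_sum = target_sum),
    class = "rasp_expr"
  )
}

#' @export
print.rasp_expr <- function(x, ...) {
  cat(sprintf("rasp_expr: %d locations x %d genes (target sum %.1f)\n",
              nrow(x$X), ncol(x$X), x$target_sum))
  invisible(x)
}

## Column standard deviations of a sparse matrix without densifying.
col_sds_sparse <- function(X) {
  n <- nrow(X)
  mns <- Matrix::colSums(X) / n
  sq <- Matrix::colSums(X^2)
  v <- (sq - n * mns^2) / (n - 1)
  v[v < 0] <- 0
  sqrt(v)
}
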