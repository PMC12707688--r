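#' Configuration for the spatial smoothing pipeline
#'
#' @param p number of principal components (default 20).
#' @param threshold number of spatial nearest neighbours retained per
#'   location when sparsifying the distance matrix.
#' @param beta power for inverse-distance weighting; `beta = 0` collapses
#'   to a rectangular (uniform) kernel over the neighbourhood, larger
#'   values concentrate weight on the closest neighbours. Default 2.
#' @param alpha_mode diagonal (self-distance) rule: `"row_min"` uses each
#'   row's minimum off-diagonal distance, `"half_row_min"` half of it
#'   (recommended for regular spot grids such as Visium), or a fixed
#'   positive number.
#' @param distance_metric metric on the spatial coordinates.
#' @param kernel weighting kernel applied to the sparsified distances.
#'   `"inverse_distance"` (default) uses `1/d^beta`; `"gaussian"` and
#'   `"quadratic"` require `bandwidth`.
#' @param bandwidth kernel bandwidth, in coordinate units (gaussian /
#'   quadratic kernels only).
#' @param center,scale centering/scaling of the expression matrix before
#'   PCA; by default centered but not scaled.
#' @param n_oversamples,n_power_iterations randomized SVD accuracy knobs.
#' @param seed integer seed for the randomized projection.
#' @return A `rasp_config` list.
#' @export
rasp_config <- function(p = 20L, threshold = 10L, beta = 2,
                        alpha_mode = "row_min",
                        distance_metric = c("euclidean", "manhattan", "chebyshev"),
                        kernel = c("inverse_distance", "gaussian", "quadratic"),
                        bandwidth = NULL,
                        center = TRUE, scale = FALSE,
                        n_oversamples = 10L, n_power_iterations = 4L,
                        seed = 1L) {
  p <- check_count(p, "p")
  threshold <- check_count(threshold, "threshold")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop_invalid("beta must be a single number >= 0")
  }
  if (is.numeric(alpha_mode)) {
    if (alpha_mode <= 0) stop_invalid("fixed alpha must be positive")
  } else if (!alpha_mode %in% c("row_min", "half_row_min")) {
    stop_invalid("alpha_mode must be 'row_min', 'half_row_min' or a number")
  }
  structure(
    list(p = p, threshold = threshold, beta = beta, alpha_mode = alpha_mode,
         distance_metric = match.arg(distance_metric),
         kernel = match.arg(kernel), bandwidth = bandwidth,
         center = check_flag(center, "center"),
         scale = check_flag(scale, "scale"),
         n_oversamples = check_count(n_oversamples, "n_oversamples", 0L),
         n_power_iterations = check_count(n_power_iterations,
                                          "n_power_iterations", 0L),
         seed = seed),
    class = "rasp_config"
  )
}

## ---------------------------------------------------------------------------
## Randomized truncated PCA
## ---------------------------------------------------------------------------

## Call counter: lets callers verify that a parameter sweep computes the
## embedding only once (the expensive stage is never inside the sweep loop).
.rasp_state <- new.env(parent = emptyenv())
.rasp_state$pca_calls <- 0L

#' Number of randomized PCA calls made so far
#' @return Integer count (resettable with [reset_pca_call_count()]).
#' @export
pca_call_count <- function() .rasp_state$pca_calls

#' @rdname pca_call_count
#' @export
reset_pca_call_count <- function() {
  .rasp_state$pca_calls <- 0L
  invisible(NULL)
}

## Products with the implicitly centered/scaled matrix
## A = (X - 1 mu') diag(1/s), never densifying X.
.a_mult <- function(X, mu, s, M) {
  M <- M / s
  as.matrix(X %*% M) - tcrossprod(rep(1, nrow(X)), as.vector(crossprod(mu, M)))
}
.at_mult <- function(X, mu, s, U) {
  (as.matrix(Matrix::crossprod(X, U)) - tcrossprod(mu, colSums(U))) / s
}

#' Randomized truncated PCA of a (sparse) expression matrix
#'
#' Computes the top-`p` principal components of `X` via a randomized range
#' finder with Gaussian test vectors, `n_oversamples` extra columns and
#' `n_power_iterations` subspace iterations (re-orthonormalized by QR at
#' every half-step). Centering (and optional unit-variance scaling) is
#' applied implicitly, so sparse input is never densified.
#'
#' @param X location-by-gene matrix (`rasp_expr`, sparse or dense matrix).
#' @param p number of components; must satisfy `p <= min(n, m)`.
#' @param center,scale center columns / scale columns to unit variance.
#' @param seed seed for the Gaussian test matrix.
#' @param n_oversamples,n_power_iterations accuracy parameters; the
#'   defaults (10, 4) are a standard accuracy/cost tradeoff for sparse
#'   expression matrices.
#' @return List with `W` (m x p loadings, orthonormal columns), `P`
#'   (n x p scores, `P = X_centered %*% W`), `d` (singular values),
#'   `column_means`, `column_scales`.
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' fit <- randomized_pca(X, p = 3, seed = 1)
#' crossprod(fit$W)[1:3, 1:3]   # ~ identity
#' @export
randomized_pca <- function(X, p, center = TRUE, scale = FALSE, seed = 1L,
                           n_oversamples = 10L, n_power_iterations = 4L) {
  if (inherits(X, "rasp_expr")) X <- X$X
  n <- nrow(X)
  m <- ncol(X)
  p <- check_count(p, "p")
  if (p > min(n, m)) stop_invalid("p must be <= min(n, m)")
  .rasp_state$pca_calls <- .rasp_state$pca_calls + 1L

  mu <- if (center) as.vector(Matrix::colSums(X)) / n else rep(0, m)
  s <- if (scale) {
    sds <- if (is(X, "sparseMatrix")) col_sds_sparse(X) else apply(X, 2, sd)
    sds[sds == 0] <- 1
    sds
  } else {
    rep(1, m)
  }

  l <- min(p + n_oversamples, min(n, m))
  Omega <- with_seed(seed, matrix(rnorm(m * l), m, l))
  Y <- .a_mult(X, mu, s, Omega)
  for (i in seq_len(n_power_iterations)) {
    Y <- qr.Q(qr(Y))
    Z <- .at_mult(X, mu, s, Y)
    Z <- qr.Q(qr(Z))
    Y <- .a_mult(X, mu, s, Z)
  }
  Q <- qr.Q(qr(Y))
  B <- .at_mult(X, mu, s, Q)        # m x l = t(A) Q
  sv <- svd(B, nu = p, nv = p)
  W <- sv$u[, seq_len(p), drop = FALSE]          # right singular vectors of A
  d <- sv$d[seq_len(p)]
  P <- .a_mult(X, mu, s, W)
  rownames(W) <- colnames(X)
  colnames(W) <- colnames(P) <- paste0("PC", seq_len(p))
  rownames(P) <- rownames(X)
  list(W = W, P = P, d = d, column_means = mu, column_scales = s)
}

## ---------------------------------------------------------------------------
## Sparse spatial distances and kernel weights
## ---------------------------------------------------------------------------

#' Sparse kNN distance structure over spatial coordinates
#'
#' Row `i` stores the exact distances from location `i` to its `threshold`
#' nearest neighbours (self excluded); ties at the boundary are broken by
#' location index. Coincident points (off-diagonal distance 0) have their
#' stored distance replaced by the row's smallest positive distance so the
#' subsequent inversion stays finite while preserving "nearest" status;
#' when a row has no positive distance at all the replacement falls back
#' to the diagonal value set later by [apply_diagonal()].
#'
#' @param coords n x 2 (or n x d) coordinate matrix.
#' @param threshold neighbours retained per row (>= 1). Values larger than
#'   `n - 1` are clamped.
#' @param metric distance metric.
#' @return A `rasp_sparse_dist`: triplet representation (`i`, `j`, `d`)
#'   plus per-row diagonal slot (unset until [apply_diagonal()]).
#' @export
build_sparse_distance <- function(coords, threshold,
                                  metric = c("euclidean", "manhattan", "chebyshev")) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop_invalid("need at least two locations")
  threshold <- min(check_count(threshold, "threshold"), n - 1L)
  nn <- knn_exact(coords, threshold, metric)
  d <- nn$dist
  ## repair coincident points row-wise
  zero_rows <- which(rowSums(d == 0) > 0)
  for (i in zero_rows) {
    pos <- d[i, d[i, ] > 0]
    d[i, d[i, ] == 0] <- if (length(pos)) min(pos) else NA_real_
  }
  structure(
    list(i = rep(seq_len(n), each = threshold),
         j = as.vector(t(nn$index)),
         d = as.vector(t(d)),
         diag = NULL, n = n, threshold = threshold, metric = metric),
    class = "rasp_sparse_dist"
  )
}

#' Set the diagonal (self-distance) of a sparse distance structure
#'
#' The diagonal value substitutes the zero self-distance before inversion.
#' `"row_min"` uses the row's minimum stored off-diagonal distance,
#' `"half_row_min"` half of it, and a number fixes the same value for all
#' rows.
#'
#' @param D a `rasp_sparse_dist`.
#' @param alpha_mode `"row_min"`, `"half_row_min"`, or a positive number.
#' @return `D` with its `diag` slot filled.
#' @export
apply_diagonal <- function(D, alpha_mode = "row_min") {
  stopifnot(inherits(D, "rasp_sparse_dist"))
  row_min <- suppressWarnings(tapply(D$d, D$i, min, na.rm = TRUE))
  row_min <- as.numeric(row_min[as.character(seq_len(D$n))])
  if (!is.numeric(alpha_mode) && any(!is.finite(row_min))) {
    stop_invalid("a row has no positive off-diagonal distance; ",
                 "use a fixed alpha")
  }
  D$diag <- if (is.numeric(alpha_mode)) {
    rep(alpha_mode, D$n)
  } else if (alpha_mode == "row_min") {
    row_min
  } else if (alpha_mode == "half_row_min") {
    row_min / 2
  } else {
    stop_invalid("unknown alpha_mode: ", alpha_mode)
  }
  ## rows whose stored distances were all zero fall back to alpha
  D$d[is.na(D$d)] <- D$diag[D$i[is.na(D$d)]]
  D
}

#' Turn sparsified distances into standardized smoothing weights
#'
#' Applies the kernel to every stored distance (off-diagonal neighbours
#' plus the diagonal), leaves non-stored entries at zero, and then divides
#' each column of the resulting sparse matrix by its maximum, so every
#' stored weight lies in `(0, 1]` and each non-empty column attains 1.
#' Kernels: `inverse_distance` `w = 1/d^beta`; `gaussian`
#' `w = exp(-d^2 / (2 bw^2))`; `quadratic` `w = max(0, 1 - (d/bw)^2)`
#' (entries reaching 0 are dropped).
#'
#' @param D a `rasp_sparse_dist` with its diagonal set.
#' @param beta inverse-distance power (>= 0).
#' @param kernel kernel name.
#' @param bandwidth bandwidth for the gaussian/quadratic kernels.
#' @return A `rasp_weights`: sparse `dgCMatrix` `W` plus provenance fields.
#' @export
weight_kernel <- function(D, beta = 2,
                          kernel = c("inverse_distance", "gaussian", "quadratic"),
                          bandwidth = NULL) {
  stopifnot(inherits(D, "rasp_sparse_dist"))
  kernel <- match.arg(kernel)
  if (is.null(D$diag)) stop_invalid("apply_diagonal() must be called first")
  if (beta < 0) stop_invalid("beta must be >= 0")
  if (kernel != "inverse_distance" && is.null(bandwidth)) {
    stop_invalid("kernel '", kernel, "' requires a bandwidth")
  }
  i <- c(D$i, seq_len(D$n))
  j <- c(D$j, seq_len(D$n))
  d <- c(D$d, D$diag)
  w <- switch(kernel,
    inverse_distance = 1 / d^beta,
    gaussian = exp(-d^2 / (2 * bandwidth^2)),
    quadratic = pmax(0, 1 - (d / bandwidth)^2)
  )
  keep <- w > 0
  W <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = w[keep],
                            dims = c(D$n, D$n))
  W <- standardize_columns_max(W)
  structure(
    list(W = W, threshold = D$threshold, beta = beta, metric = D$metric,
         kernel = kernel, bandwidth = bandwidth),
    class = "rasp_weights"
  )
}

## Divide each column of a sparse nonnegative matrix by its maximum stored
## value; empty columns are left untouched.
standardize_columns_max <- function(W) {
  W <- as(W, "CsparseMatrix")
  p <- W@p
  nz <- diff(p)
  if (any(nz > 0)) {
    colmax <- vapply(seq_len(ncol(W)), function(jj) {
      if (nz[jj] == 0) 1 else max(W@x[(p[jj] + 1):p[jj + 1]])
    }, numeric(1))
    W@x <- W@x / rep.int(colmax, nz)
  }
  W
}

#' @export
print.rasp_weights <- function(x, ...) {
  cat(sprintf("rasp_weights: %d x %d, kNN=%d, beta=%g, %s/%s\n",
              nrow(x$W), ncol(x$W), x$threshold, x$beta, x$metric, x$kernel))
  invisible(x)
}

#' Spatially smooth a matrix of per-location values
#'
#' Returns `W %*% M`, the weight-matrix product that averages each row's
#' neighbourhood (columns contribute according to the column-max
#' standardized weights).
#'
#' @param weights a `rasp_weights`.
#' @param M n x k matrix aligned with the weight rows.
#' @return Dense n x k matrix.
#' @export
spatial_smooth <- function(weights, M) {
  stopifnot(inherits(weights, "rasp_weights"))
  M <- as.matrix(M)
  if (nrow(M) != nrow(weights$W)) {
    stop_invalid("weights and matrix row counts differ")
  }
  out <- as.matrix(weights$W %*% M)
  dimnames(out) <- dimnames(M)
  out
}

## ---------------------------------------------------------------------------
## Full pipeline
## ---------------------------------------------------------------------------

#' Covariate specification for two-stage PCA
#'
#' @param Y n x b matrix (or data frame) of location-level covariates,
#'   e.g. local cell density (cells per unit area), library size (counts),
#'   or cell volume. Rows must align with the expression matrix.
#' @param smooth logical vector (recycled over columns): whether each
#'   covariate is spatially smoothed before the second-stage PCA.
#'   Covariates that already encode spatial structure (local density) are
#'   typically left unsmoothed.
#' @return A `rasp_covariates` list.
#' @export
covariate_spec <- function(Y, smooth = TRUE) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("cov", seq_len(ncol(Y)))
  smooth <- rep_len(as.logical(smooth), ncol(Y))
  structure(list(Y = Y, smooth = smooth), class = "rasp_covariates")
}

#' Randomized spatial PCA
#'
#' Runs the full pipeline: randomized truncated PCA of the expression
#' matrix, construction of the kNN-sparsified inverse-distance weight
#' matrix over the spatial coordinates, and smoothing of the PC scores.
#' When covariates are supplied, flagged columns are smoothed with the same
#' weights, the covariate block is standardized to zero mean / unit
#' variance (so a handful of covariates is not swamped by the `p` PC
#' columns), and a second-stage randomized PCA of `[Ps, Ys]` yields the
#' covariate-integrated scores `Pc`.
#'
#' @param X a `rasp_expr`, or a location-by-gene matrix of normalized
#'   expression.
#' @param coords n x 2 spatial coordinates aligned with the rows of `X`;
#'   taken from `X` when it is a `rasp_expr` carrying coordinates.
#' @param config a [rasp_config()].
#' @param covariates optional [covariate_spec()].
#' @return A `rasp_fit`: smoothed scores `Ps`, loadings `W`, raw scores
#'   `P`, singular values `d`, `column_means`/`column_scales`, the weight
#'   matrix provenance, and (with covariates) `Ys`, `Pc`, `Wc`,
#'   `cov_center`, `cov_scale`.
#' @examples
#' lay <- make_stripes_layout(150, 4, seed = 1)
#' gm <- zinb_gene_model(fold_changes = default_fold_changes(4, 10, 10),
#'                       n_low_signal = 10, n_high_signal = 10, n_noise = 10)
#' expr <- normalize_expression(simulate_counts(lay, gm, seed = 1))
#' fit <- rasp(expr, config = rasp_config(p = 5, threshold = 10, beta = 0))
#' dim(fit$Ps)
#' @export
rasp <- function(X, coords = NULL, config = rasp_config(),
                 covariates = NULL) {
  if (inherits(X, "rasp_expr")) {
    if (is.null(coords)) coords <- X$coords
    Xm <- X$X
  } else {
    Xm <- X
  }
  if (is.null(coords)) stop_invalid("spatial coordinates are required")
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(Xm)) {
    stop_invalid("coordinate rows must align with expression rows")
  }
  pca <- randomized_pca(Xm, p = config$p, center = config$center,
                        scale = config$scale, seed = config$seed,
                        n_oversamples = config$n_oversamples,
                        n_power_iterations = config$n_power_iterations)
  D <- build_sparse_distance(coords, config$threshold, config$distance_metric)
  D <- apply_diagonal(D, config$alpha_mode)
  weights <- weight_kernel(D, beta = config$beta, kernel = config$kernel,
                           bandwidth = config$bandwidth)
  fit <- rasp_smooth_stage(pca, weights, covariates, config)
  fit$coords <- coords
  fit
}

## Smoothing + optional second stage, shared by rasp() and parameter_sweep()
## (the sweep reuses one PCA across many weight matrices).
rasp_smooth_stage <- function(pca, weights, covariates, config) {
  Ps <- spatial_smooth(weights, pca$P)
  fit <- list(Ps = Ps, W = pca$W, P = pca$P, d = pca$d,
              column_means = pca$column_means,
              column_scales = pca$column_scales,
              weights = weights, config = config)
  if (!is.null(covariates)) {
    stopifnot(inherits(covariates, "rasp_covariates"))
    Y <- covariates$Y
    if (nrow(Y) != nrow(Ps)) {
      stop_invalid("covariate rows must align with expression rows")
    }
    Ys <- Y
    if (any(covariates$smooth)) {
      sm <- which(covariates$smooth)
      Ys[, sm] <- spatial_smooth(weights, Y[, sm, drop = FALSE])
    }
    ## standardize the covariate block so its scale is commensurate with
    ## the PC columns in the second-stage PCA
    cov_center <- colMeans(Ys)
    cov_scale <- apply(Ys, 2, sd)
    cov_scale[cov_scale == 0] <- 1
    Ys_std <- sweep(sweep(Ys, 2, cov_center), 2, cov_scale, "/")
    M <- cbind(Ps, Ys_std)
    pca2 <- randomized_pca(M, p = config$p, center = config$center,
                           scale = FALSE, seed = config$seed,
                           n_oversamples = config$n_oversamples,
                           n_power_iterations = config$n_power_iterations)
    fit$Ys <- Ys
    fit$Ys_std <- Ys_std
    fit$cov_center <- cov_center
    fit$cov_scale <- cov_scale
    fit$Wc <- pca2$W
    fit$Pc <- pca2$P
    fit$second_stage_means <- pca2$column_means
  }
  class(fit) <- "rasp_fit"
  fit
}

#' @export
print.rasp_fit <- function(x, ...) {
  cat(sprintf("rasp_fit: %d locations, %d PCs, kNN=%d, beta=%g%s\n",
              nrow(x$Ps), ncol(x$Ps), x$weights$threshold, x$weights$beta,
              if (!is.null(x$Pc)) ", covariate-integrated" else ""))
  invisible(x)
}
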