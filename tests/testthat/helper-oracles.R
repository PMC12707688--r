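# Independent oracles and small fixture builders shared across tests.

# Brute-force pair-counting ARI: iterate over all C(n,2) pairs.
brute_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  total <- choose(n, 2)
  index <- s11
  exp_index <- (s11 + s10) * (s11 + s01) / total
  max_index <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_index == exp_index) return(1)
  (index - exp_index) / (max_index - exp_index)
}

# All partitions of n elements into at most max_blocks blocks
# (restricted growth strings).
enumerate_partitions <- function(n, max_blocks) {
  out <- list()
  recurse <- function(prefix, m) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(min(m + 1L, max_blocks))) {
      recurse(c(prefix, v), max(m, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Dense reference for the whole smoothing pipeline: exact truncated SVD of
# the centered matrix, dense kNN inverse-distance kernel with column-max
# standardization, dense matrix product.
dense_pipeline_oracle <- function(X, coords, p, knn, beta,
                                  alpha_mode = "row_min") {
  X <- as.matrix(X)
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = p, nv = p)
  P <- Xc %*% sv$v[, seq_len(p), drop = FALSE]
  Dm <- as.matrix(dist(coords))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(Dm[i, -i], seq_len(n)[-i])[seq_len(knn)]
    nb <- (seq_len(n)[-i])[ord]
    d <- Dm[i, nb]
    alpha <- switch(as.character(alpha_mode),
                    row_min = min(d), half_row_min = min(d) / 2,
                    as.numeric(alpha_mode))
    W[i, nb] <- 1 / d^beta
    W[i, i] <- 1 / alpha^beta
  }
  for (j in seq_len(n)) {
    mx <- max(W[, j])
    if (mx > 0) W[, j] <- W[, j] / mx
  }
  list(Ps = W %*% P, P = P, V = sv$v[, seq_len(p), drop = FALSE],
       d = sv$d[seq_len(p)], W = W)
}

# Align the columns of A to B up to sign flips.
align_signs <- function(A, B) {
  for (j in seq_len(ncol(A))) {
    if (sum(abs(A[, j] - B[, j])) > sum(abs(A[, j] + B[, j]))) {
      A[, j] <- -A[, j]
    }
  }
  A
}

# Sparse test matrix with a planted, geometrically decaying spectrum so
# truncated-SVD factors are well conditioned (clear singular-value gaps).
planted_sparse_matrix <- function(n, m, rank = 30, seed = 1) {
  set.seed(seed)
  U <- Matrix::rsparsematrix(n, rank, density = 0.3)
  V <- Matrix::rsparsematrix(m, rank, density = 0.3)
  d <- 10 * (0.7^(seq_len(rank) - 1))
  L <- U %*% Matrix::Diagonal(x = d) %*% Matrix::t(V)
  E <- Matrix::rsparsematrix(n, m, density = 0.05) * 1e-4
  methods::as(L + E, "CsparseMatrix")
}

# Small ZINB expression fixture on a striped tissue.
stripes_fixture <- function(n_cells = 400, n_domains = 4, seed = 1,
                            genes_per_class = 10) {
  lay <- make_stripes_layout(n_cells, n_domains, seed = seed)
  fc <- default_fold_changes(n_domains, genes_per_class, genes_per_class)
  gm <- zinb_gene_model(fold_changes = fc,
                        n_low_signal = genes_per_class,
                        n_high_signal = genes_per_class,
                        n_noise = genes_per_class)
  cm <- simulate_counts(lay, gm, seed = seed)
  list(layout = lay, genes = gm, counts = cm,
       expr = normalize_expression(cm))
}

# Two well-separated Gaussian blobs in PC-like space.
blob_fixture <- function(n_per = 20, d = 3, sep = 50, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep), n_per, d))
  list(X = X, truth = rep(1:2, each = n_per))
}
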