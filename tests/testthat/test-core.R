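test_that("rank-1 matrices are recovered exactly", {
  set.seed(1)
  u <- rnorm(30)
  v <- rnorm(10)
  X <- tcrossprod(u, v)
  fit <- randomized_pca(X, p = 1, seed = 2)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_lt(max(abs(tcrossprod(fit$P, fit$W) - Xc)), 1e-10)
})

test_that("randomized scores match a dense SVD oracle", {
  X <- planted_sparse_matrix(200, 50, rank = 30, seed = 3)
  fit <- randomized_pca(X, p = 20, seed = 4)
  oracle <- svd(scale(as.matrix(X), center = TRUE, scale = FALSE))
  Po <- scale(as.matrix(X), center = TRUE, scale = FALSE) %*% oracle$v[, 1:20]
  P <- align_signs(fit$P, Po)
  expect_lt(max(abs(fit$d - oracle$d[1:20]) / oracle$d[1:20]), 1e-6)
  for (j in 1:20) {
    expect_lt(max(abs(P[, j] - Po[, j])) / max(abs(Po[, j])), 1e-6)
  }
  # loadings are orthonormal
  expect_lt(max(abs(crossprod(fit$W) - diag(20))), 1e-8)
})

test_that("PCA defaults center but do not scale", {
  set.seed(5)
  X <- matrix(rnorm(40 * 8, mean = 3, sd = c(1, 5)), 40, 8)
  fit <- randomized_pca(X, p = 3, seed = 1)
  expect_equal(fit$column_means, colMeans(X))
  expect_identical(fit$column_scales, rep(1, 8))
  expect_lt(max(abs(colMeans(fit$P))), 1e-10)
  fit2 <- randomized_pca(X, p = 3, scale = TRUE, seed = 1)
  expect_equal(fit2$column_scales, apply(X, 2, sd))
  expect_error(randomized_pca(X, p = 9), class = "rasp_invalid_argument")
})

test_that("sparse distances store exact kNN rows", {
  # collinear points with unit spacing
  coords <- cbind(c(0, 1, 2), 0)
  D <- build_sparse_distance(coords, 1)
  expect_identical(D$d, rep(1, 3))
  expect_identical(D$j[1], 2L)          # 0 -> 1
  expect_identical(D$j[3], 2L)          # 2 -> 1
  # threshold >= n-1 gives the full pairwise matrix
  set.seed(6)
  pts <- matrix(runif(20), 10, 2)
  Df <- build_sparse_distance(pts, 9)
  M <- matrix(0, 10, 10)
  M[cbind(Df$i, Df$j)] <- Df$d
  expect_equal(M + diag(NA, 10),
               unname(as.matrix(dist(pts))) + diag(NA, 10),
               tolerance = 1e-12)
})

test_that("kNN sparsity pattern matches a dense argsort oracle", {
  set.seed(7)
  pts <- matrix(runif(200), 100, 2)
  D <- build_sparse_distance(pts, 5)
  Dm <- as.matrix(dist(pts))
  for (i in c(1, 17, 50, 100)) {
    others <- setdiff(1:100, i)
    expected <- others[order(Dm[i, others], others)][1:5]
    expect_setequal(D$j[D$i == i], expected)
  }
})

test_that("supported metrics agree with direct formulas", {
  set.seed(8)
  pts <- matrix(runif(60), 30, 2)
  for (metric in c("euclidean", "manhattan", "chebyshev")) {
    D <- build_sparse_distance(pts, 3, metric)
    ref <- switch(metric,
      euclidean = as.matrix(dist(pts, method = "euclidean")),
      manhattan = as.matrix(dist(pts, method = "manhattan")),
      chebyshev = as.matrix(dist(pts, method = "maximum"))
    )
    expect_equal(D$d, ref[cbind(D$i, D$j)], tolerance = 1e-12)
  }
})

test_that("diagonal rules follow the row minimum", {
  coords <- rbind(c(0, 0), c(2, 0), c(3, 0), c(5, 0))
  D <- build_sparse_distance(coords, 3)
  # row 1 off-diagonal distances are {2, 3, 5}
  expect_equal(apply_diagonal(D, "row_min")$diag[1], 2)
  expect_equal(apply_diagonal(D, "half_row_min")$diag[1], 1)
  expect_equal(apply_diagonal(D, 0.5)$diag, rep(0.5, 4))
})

test_that("coincident points keep finite positive weights", {
  coords <- rbind(c(0, 0), c(0, 0), c(1, 0), c(4, 0))
  D <- apply_diagonal(build_sparse_distance(coords, 2), "row_min")
  w <- weight_kernel(D, beta = 2)
  expect_true(all(is.finite(w$W@x)))
  expect_true(all(w$W@x > 0))
})

test_that("a zero power gives the rectangular kernel", {
  set.seed(9)
  pts <- matrix(runif(80), 40, 2)
  for (thr in c(1, 5, 20)) {
    for (alpha in list("row_min", "half_row_min", 0.3)) {
      D <- apply_diagonal(build_sparse_distance(pts, thr), alpha)
      w <- weight_kernel(D, beta = 0)
      expect_true(all(w$W@x == 1))
    }
  }
})

test_that("column standardization leaves an attained maximum of one", {
  coords <- rbind(c(0, 0), c(1, 0), c(3, 0))
  D <- apply_diagonal(build_sparse_distance(coords, 2), "row_min")
  w <- weight_kernel(D, beta = 2)
  M <- as.matrix(w$W)
  for (j in 1:3) expect_equal(max(M[, j]), 1)
  expect_true(all(M[M > 0] <= 1))
})

test_that("sparse weights equal the dense kernel oracle", {
  set.seed(10)
  pts <- matrix(runif(100), 50, 2)
  D <- apply_diagonal(build_sparse_distance(pts, 5), "row_min")
  w <- weight_kernel(D, beta = 2)
  oracle <- dense_pipeline_oracle(matrix(rnorm(50 * 4), 50, 4), pts,
                                  p = 2, knn = 5, beta = 2)
  expect_lt(max(abs(as.matrix(w$W) - oracle$W)), 1e-12)
})

test_that("alternative kernels require a bandwidth and match formulas", {
  coords <- rbind(c(0, 0), c(1, 0), c(2, 0))
  D <- apply_diagonal(build_sparse_distance(coords, 2), "row_min")
  expect_error(weight_kernel(D, kernel = "gaussian"),
               class = "rasp_invalid_argument")
  expect_error(weight_kernel(D, beta = -1), class = "rasp_invalid_argument")
  wg <- weight_kernel(D, kernel = "gaussian", bandwidth = 1.5)
  raw <- exp(-c(1, 1)^2 / (2 * 1.5^2))   # row 1: d=1 to point 2; diag d=1
  expect_true(all(wg$W@x <= 1))
  wq <- weight_kernel(D, kernel = "quadratic", bandwidth = 1.5)
  expect_true(all(wq$W@x > 0))            # d=2 entries dropped (1-(2/1.5)^2<0)
  expect_true(all(as.matrix(wq$W)[cbind(c(1, 3), c(3, 1))] == 0))
})

test_that("smoothing is the sparse weight product", {
  set.seed(11)
  pts <- matrix(runif(200), 100, 2)
  D <- apply_diagonal(build_sparse_distance(pts, 6), "row_min")
  w <- weight_kernel(D, beta = 1)
  M <- matrix(rnorm(500), 100, 5)
  expect_lt(max(abs(spatial_smooth(w, M) - as.matrix(w$W) %*% M)), 1e-10)
  # identity weights pass the matrix through
  wI <- w
  wI$W <- Matrix::Diagonal(100)
  expect_equal(spatial_smooth(wI, M), M, ignore_attr = TRUE)
  expect_error(spatial_smooth(w, M[1:10, ]), class = "rasp_invalid_argument")
})

test_that("the sparse pipeline matches the dense oracle end to end", {
  # expression with a planted decaying spectrum so the truncated factors
  # are well conditioned, scattered over random 2-D positions
  X <- planted_sparse_matrix(200, 60, rank = 30, seed = 12)
  set.seed(12)
  coords <- matrix(runif(400, 0, 100), 200, 2)
  cfg <- rasp_config(p = 10, threshold = 8, beta = 1.5, seed = 3)
  fit <- rasp(X, coords, config = cfg)
  oracle <- dense_pipeline_oracle(as.matrix(X), coords,
                                  p = 10, knn = 8, beta = 1.5)
  Ps <- align_signs(fit$Ps, oracle$Ps)
  expect_lt(max(abs(Ps - oracle$Ps)), 1e-6)
})

test_that("increasing beta concentrates weight on near neighbours", {
  set.seed(13)
  pts <- matrix(runif(60), 30, 2)
  D <- apply_diagonal(build_sparse_distance(pts, 5), "row_min")
  d_row <- D$d[D$i == 1]                 # fixed neighbour distances of row 1
  ratios <- sapply(c(0.5, 1, 1.5, 2), function(b) {
    w_raw <- 1 / d_row^b
    max(w_raw) / min(w_raw)              # nearest over farthest weight
  })
  expect_true(all(diff(ratios) > 0))
  # and the standardized matrix preserves the within-column ordering
  w1 <- weight_kernel(D, beta = 0.5)
  w2 <- weight_kernel(D, beta = 2)
  M1 <- as.matrix(w1$W)
  M2 <- as.matrix(w2$W)
  j <- 1
  nb <- which(M1[, j] > 0 & M2[, j] > 0)
  expect_identical(order(M1[nb, j]), order(M2[nb, j]))
})

test_that("rasp runs deterministically and reuses nothing across seeds", {
  fx <- stripes_fixture(n_cells = 150, n_domains = 4, seed = 14)
  cfg <- rasp_config(p = 5, threshold = 10, beta = 2, seed = 99)
  f1 <- rasp(fx$expr, config = cfg)
  f2 <- rasp(fx$expr, config = cfg)
  expect_identical(f1$Ps, f2$Ps)
  expect_null(f1$Pc)
  cfg2 <- rasp_config(p = 5, threshold = 10, beta = 2, seed = 100)
  f3 <- rasp(fx$expr, config = cfg2)
  expect_false(identical(f1$Ps, f3$Ps))   # different random projection
})

test_that("covariates produce second-stage outputs of the right shape", {
  fx <- stripes_fixture(n_cells = 150, n_domains = 4, seed = 15)
  Y <- cbind(density = runif(150), libsize = fx$expr$total_counts)
  cfg <- rasp_config(p = 5, threshold = 10, beta = 2, seed = 1)
  fit <- rasp(fx$expr, config = cfg,
              covariates = covariate_spec(Y, smooth = c(FALSE, TRUE)))
  expect_equal(dim(fit$Pc), c(150, 5))
  expect_equal(dim(fit$Wc), c(7, 5))
  expect_equal(dim(fit$Ys), c(150, 2))
  # unsmoothed covariate passes through untouched
  expect_identical(fit$Ys[, 1], Y[, 1])
  expect_false(identical(fit$Ys[, 2], Y[, 2]))
  expect_error(rasp(fx$expr, config = cfg,
                    covariates = covariate_spec(Y[1:10, ])),
               class = "rasp_invalid_argument")
})

test_that("a redundant covariate leaves the second-stage subspace intact", {
  fx <- stripes_fixture(n_cells = 120, n_domains = 4, seed = 16)
  cfg <- rasp_config(p = 4, threshold = 8, beta = 1, seed = 2)
  base <- rasp(fx$expr, config = cfg)
  # covariate identical to the first smoothed PC, not smoothed again
  fit <- rasp(fx$expr, config = cfg,
              covariates = covariate_spec(base$Ps[, 1, drop = FALSE],
                                          smooth = FALSE))
  # span(Pc) must equal the span of the centered Ps (principal angles ~ 0)
  Q1 <- qr.Q(qr(scale(base$Ps, center = TRUE, scale = FALSE)))
  Q2 <- qr.Q(qr(scale(fit$Pc, center = TRUE, scale = FALSE)))
  angles <- svd(crossprod(Q1, Q2))$d
  expect_lt(max(abs(angles - 1)), 1e-8)
})

test_that("the sweep computes the embedding exactly once", {
  fx <- stripes_fixture(n_cells = 150, n_domains = 4, seed = 17)
  reset_pca_call_count()
  tab <- parameter_sweep(fx$expr, fx$layout$coords, knn_grid = c(5, 10),
                         beta_grid = c(0, 2), methods = "louvain",
                         config = rasp_config(p = 4), seed = 1)
  expect_equal(pca_call_count(), 1L)
  expect_equal(nrow(tab), 4)
})
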