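#' @importFrom Matrix sparseMatrix colSums rowSums t crossprod Diagonal
#' @importFrom methods as is
#' @importFrom stats rnorm rbinom rnbinom runif quantile sd median mad
#' @importFrom mclust Mclust mclustBIC
NULL

## Evaluate an expression under a fixed RNG seed, restoring the caller's
## RNG state afterwards so library calls do not perturb user-level streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("rasp_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop_invalid(name, " must be a single integer >= ", min)
  }
  as.integer(x)
}

check_flag <- function(x, name) {
  if (length(x) != 1L || !is.logical(x) || is.na(x)) {
    stop_invalid(name, " must be TRUE or FALSE")
  }
  x
}

## Pairwise distances between rows of `query` (b x d) and rows of `ref`
## (n x d) under the supported Minkowski-family metrics. Dense result,
## used block-wise so memory stays O(block * n).
dist_block <- function(query, ref, metric = c("euclidean", "manhattan", "chebyshev")) {
  metric <- match.arg(metric)
  b <- nrow(query)
  n <- nrow(ref)
  if (metric == "euclidean") {
    qn <- rowSums(query^2)
    rn <- rowSums(ref^2)
    d2 <- outer(qn, rn, "+") - 2 * tcrossprod(query, ref)
    d2[d2 < 0] <- 0
    return(sqrt(d2))
  }
  acc <- matrix(0, b, n)
  for (j in seq_len(ncol(ref))) {
    dj <- abs(outer(query[, j], ref[, j], "-"))
    acc <- if (metric == "manhattan") acc + dj else pmax(acc, dj)
  }
  acc
}

## Exact k-nearest neighbours of every row of `x` among all rows of `x`,
## self excluded. Ties at the neighbourhood boundary are broken by row
## index (stable), so results are reproducible across platforms.
## Returns k-column matrices `index` and `dist` (row i = neighbours of i).
knn_exact <- function(x, k, metric = "euclidean", block = 512L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop_invalid("k must be smaller than the number of points")
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    rows <- s:min(s + block - 1L, n)
    d <- dist_block(x[rows, , drop = FALSE], x, metric)
    for (r in seq_along(rows)) {
      i <- rows[r]
      di <- d[r, ]
      di[i] <- Inf                       # exclude self
      ord <- order(di, seq_len(n))[seq_len(k)]
      idx[i, ] <- ord
      dst[i, ] <- di[ord]
    }
  }
  list(index = idx, dist = dst)
}
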