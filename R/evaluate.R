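#' Nearest-neighbour graph over smoothed principal components
#'
#' Builds a weighted undirected graph on the locations where distances are
#' measured in PC space (transcriptomic similarity), not on the spatial
#' coordinates. Edge weights follow the UMAP fuzzy-connectivity
#' construction: per point, distances to its `n_neighbors` nearest
#' neighbours are turned into membership strengths
#' `exp(-(d - rho_i) / sigma_i)` with `rho_i` the distance to the nearest
#' neighbour and `sigma_i` calibrated so the strengths sum to
#' `log2(n_neighbors)`; directed memberships are combined by the fuzzy
#' union `a + b - ab`.
#'
#' @param Ps n x p matrix of (smoothed) PC scores.
#' @param n_neighbors neighbourhood size; 10 is adequate for most data
#'   (5-10 for cell-type-scale structure, 20+ for broad domains).
#' @return An `igraph` weighted undirected graph with `n` vertices.
#' @export
build_expression_graph <- function(Ps, n_neighbors = 10L) {
  Ps <- as.matrix(Ps)
  n <- nrow(Ps)
  n_neighbors <- check_count(n_neighbors, "n_neighbors")
  if (n_neighbors >= n) stop_invalid("n_neighbors must be < number of rows")
  nn <- knn_exact(Ps, n_neighbors, "euclidean")
  memb <- umap_memberships(nn$dist, n_neighbors)
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = n_neighbors),
    j = as.vector(t(nn$index)),
    x = as.vector(t(memb)), dims = c(n, n)
  )
  ## fuzzy union of the directed memberships: A + A' - A o A'
  S <- A + Matrix::t(A) - A * Matrix::t(A)
  igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

## Smooth-kNN membership strengths (binary search for sigma per point).
umap_memberships <- function(dist, k, n_iter = 64L) {
  target <- log2(k)
  t(apply(dist, 1, function(d) {
    rho <- if (any(d > 0)) min(d[d > 0]) else 0
    dd <- pmax(d - rho, 0)
    if (all(dd == 0)) return(rep(1, k))
    lo <- 1e-12
    hi <- max(dd) * k
    for (it in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      val <- sum(exp(-dd / mid))
      if (val > target) hi <- mid else lo <- mid
    }
    exp(-dd / ((lo + hi) / 2))
  }))
}

#' Cluster locations on their smoothed principal components
#'
#' Graph methods (`leiden`, `louvain`, `walktrap`) operate on the
#' [build_expression_graph()] neighbourhood graph; `mclust` (alias `gmm`)
#' fits a Gaussian mixture directly to the PC scores for a requested
#' number of components. Labels are relabelled to contiguous integers in
#' decreasing cluster-size order, and results are deterministic given
#' `seed`.
#'
#' @param Ps n x p matrix of (smoothed) PC scores.
#' @param method clustering algorithm.
#' @param n_neighbors neighbourhood size for the expression graph.
#' @param resolution resolution parameter for leiden/louvain.
#' @param k number of mixture components for `mclust`; for `walktrap`,
#'   an optional cluster count at which the merge dendrogram is cut
#'   (otherwise the modularity-optimal cut is used).
#' @param steps random-walk length for `walktrap`.
#' @param seed integer seed.
#' @param graph optionally, a prebuilt expression graph to reuse.
#' @return A `rasp_clusters`: integer `labels` (1-based, contiguous),
#'   `n_clusters`, and provenance fields.
#' @export
cluster_locations <- function(Ps, method = c("leiden", "louvain", "walktrap",
                                             "mclust", "gmm"),
                              n_neighbors = 10L, resolution = 1,
                              k = NULL, steps = 4L, seed = 1L,
                              graph = NULL) {
  method <- match.arg(method)
  if (method == "gmm") method <- "mclust"
  Ps <- as.matrix(Ps)
  if (method == "mclust") {
    if (is.null(k)) stop_invalid("mclust requires a component count k")
    labels <- with_seed(seed, {
      fit <- mclust::Mclust(Ps, G = k, verbose = FALSE)
      fit$classification
    })
  } else {
    if (is.null(graph)) graph <- build_expression_graph(Ps, n_neighbors)
    labels <- with_seed(seed, switch(method,
      leiden = igraph::membership(igraph::cluster_leiden(
        graph, objective_function = "modularity",
        resolution = resolution, n_iterations = 5L,
        weights = igraph::E(graph)$weight)),
      louvain = igraph::membership(igraph::cluster_louvain(
        graph, resolution = resolution,
        weights = igraph::E(graph)$weight)),
      walktrap = {
        wt <- igraph::cluster_walktrap(graph, steps = steps,
                                       weights = igraph::E(graph)$weight)
        if (is.null(k)) igraph::membership(wt) else igraph::cut_at(wt, no = k)
      }
    ))
  }
  labels <- relabel_by_size(as.integer(labels))
  structure(
    list(labels = labels, n_clusters = max(labels), method = method,
         n_neighbors = n_neighbors,
         resolution_or_k = if (method == "mclust") k else resolution,
         seed = seed),
    class = "rasp_clusters"
  )
}

relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab), names(tab))
  as.integer(map[as.character(labels)])
}

#' @export
print.rasp_clusters <- function(x, ...) {
  cat(sprintf("rasp_clusters: %d locations in %d clusters (%s)\n",
              length(x$labels), x$n_clusters, x$method))
  invisible(x)
}

#' Search the resolution parameter for a target cluster count
#'
#' Bisects the resolution of a graph clustering method until the partition
#' has `target_k` clusters or the bracket is exhausted; the achieved
#' number of clusters is non-decreasing in resolution, which the search
#' exploits. Returns the closest partition found, with `matched`
#' indicating whether `target_k` was hit exactly and the search `trace`.
#'
#' @param Ps n x p matrix of (smoothed) PC scores.
#' @param method `"leiden"` or `"louvain"`.
#' @param target_k desired number of clusters.
#' @param resolution_bounds length-2 numeric search bracket.
#' @param n_neighbors,seed as in [cluster_locations()].
#' @param max_iter bisection steps after the initial bracket evaluation.
#' @param graph optionally, a prebuilt expression graph to reuse.
#' @return A `rasp_clusters` with extra fields `matched` and `trace`.
#' @export
match_cluster_count <- function(Ps, method = c("leiden", "louvain"),
                                target_k, resolution_bounds = c(1e-3, 20),
                                n_neighbors = 10L, seed = 1L,
                                max_iter = 25L, graph = NULL) {
  method <- match.arg(method)
  target_k <- check_count(target_k, "target_k")
  if (is.null(graph)) graph <- build_expression_graph(Ps, n_neighbors)
  run <- function(res) {
    cluster_locations(Ps, method, n_neighbors = n_neighbors,
                      resolution = res, seed = seed, graph = graph)
  }
  lo <- resolution_bounds[1]
  hi <- resolution_bounds[2]
  trace <- data.frame(resolution = numeric(), k = integer())
  best <- NULL
  note <- function(res, cl) {
    trace[nrow(trace) + 1L, ] <<- list(res, cl$n_clusters)
    if (is.null(best) ||
        abs(cl$n_clusters - target_k) < abs(best$n_clusters - target_k)) {
      best <<- cl
    }
    cl$n_clusters
  }
  k_lo <- note(lo, run(lo))
  if (k_lo < target_k) {
    k_hi <- note(hi, run(hi))
    if (k_hi >= target_k) {
      for (i in seq_len(max_iter)) {
        if (best$n_clusters == target_k) break
        mid <- (lo + hi) / 2
        k_mid <- note(mid, run(mid))
        if (k_mid < target_k) lo <- mid else hi <- mid
      }
    }
  }
  best$matched <- best$n_clusters == target_k
  best$resolution_or_k <- trace$resolution[which.min(abs(trace$k - target_k))]
  best$trace <- trace
  best
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model:
#' 1 for identical partitions (up to relabelling), about 0 for independent
#' ones, negative for less-than-chance agreement.
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type).
#' @return A number in `[-1, 1]`.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_invalid("label vectors must have equal length")
  }
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  index <- sum_comb(tab)
  exp_a <- sum_comb(rowSums(tab))
  exp_b <- sum_comb(colSums(tab))
  expected <- exp_a * exp_b / choose(n, 2)
  max_index <- (exp_a + exp_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (index - expected) / (max_index - expected)
}

## Row-standardized kNN spatial weight matrix used by Moran's I.
spatial_weight_graph <- function(coords, w_neighbors = 6L) {
  n <- nrow(coords)
  k <- min(w_neighbors, n - 1L)
  nn <- knn_exact(as.matrix(coords), k, "euclidean")
  Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                       j = as.vector(t(nn$index)),
                       x = rep(1 / k, n * k), dims = c(n, n))
}

#' Moran's I spatial autocorrelation
#'
#' For a numeric input, the standard Moran's I on a row-standardized
#' k-nearest-neighbour spatial weight graph. For a label (factor/integer
#' partition) input, Moran's I is computed on each cluster's one-hot
#' indicator and the cluster-size-weighted mean is returned, with the
#' per-cluster values attached as `attr(, "per_cluster")`.
#'
#' @param values numeric vector, or a partition (factor / integer labels /
#'   `rasp_clusters`).
#' @param coords n x 2 spatial coordinates.
#' @param w_neighbors spatial neighbours per location for the weight graph.
#' @return Moran's I (near 1: spatially contiguous; negative:
#'   alternating). `NaN` with a warning for constant input.
#' @export
morans_i <- function(values, coords, w_neighbors = 6L) {
  if (inherits(values, "rasp_clusters")) values <- values$labels
  coords <- as.matrix(coords)
  W <- spatial_weight_graph(coords, w_neighbors)
  if (is.factor(values) || is.integer(values) || is.character(values)) {
    f <- factor(values)
    if (nlevels(f) < 2L) {
      warning("constant labels: Moran's I undefined")
      return(NaN)
    }
    sizes <- as.numeric(table(f))
    per <- vapply(levels(f), function(lv) {
      morans_i_numeric(as.numeric(f == lv), W)
    }, numeric(1))
    out <- sum(per * sizes) / sum(sizes)
    attr(out, "per_cluster") <- per
    return(out)
  }
  if (stats::var(values) == 0) {
    warning("constant values: Moran's I undefined")
    return(NaN)
  }
  morans_i_numeric(as.numeric(values), W)
}

morans_i_numeric <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- sum(W@x)
  (n / s0) * as.numeric(crossprod(z, W %*% z)) / sum(z^2)
}

#' CHAOS score of a spatial partition
#'
#' Coordinates are scaled to unit range per axis; within each cluster of
#' two or more locations, every location contributes the distance to its
#' nearest neighbour in the same cluster, and CHAOS is the mean of those
#' within-cluster 1-NN edge lengths over all contributing locations.
#' Lower values indicate spatially compact, continuous clusters.
#' Singleton clusters are skipped with a warning.
#'
#' @param labels partition (vector or `rasp_clusters`).
#' @param coords n x 2 spatial coordinates.
#' @return Nonnegative number.
#' @export
chaos <- function(labels, coords) {
  if (inherits(labels, "rasp_clusters")) labels <- labels$labels
  coords <- as.matrix(coords)
  rng <- apply(coords, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  sc <- sweep(sweep(coords, 2, apply(coords, 2, min)), 2, rng, "/")
  dists <- numeric(0)
  skipped <- 0L
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < 2L) {
      skipped <- skipped + 1L
      next
    }
    nn <- knn_exact(sc[idx, , drop = FALSE], 1L, "euclidean")
    dists <- c(dists, nn$dist[, 1])
  }
  if (skipped > 0L) warning(skipped, " singleton cluster(s) skipped")
  if (!length(dists)) {
    stop_invalid("all clusters are singletons; CHAOS undefined")
  }
  mean(dists)
}

#' Sweep the spatial-smoothing parameters
#'
#' Computes the randomized PCA embedding once, then for each
#' `(knn, beta)` grid cell rebuilds only the sparse weight matrix, smooths
#' the fixed PC scores, clusters with each requested method, and records
#' ARI (when truth labels are given), Moran's I and CHAOS. With
#' `target_k` set, graph methods are resolution-matched to that cluster
#' count via [match_cluster_count()].
#'
#' @param X expression (`rasp_expr` or matrix).
#' @param coords n x 2 spatial coordinates.
#' @param knn_grid,beta_grid numeric grids; the default beta grid is
#'   `seq(0, 2, by = 0.25)`.
#' @param methods clustering methods to apply per cell.
#' @param truth optional ground-truth labels for ARI.
#' @param config base [rasp_config()] (its `threshold`/`beta` are
#'   overridden by the grid).
#' @param n_neighbors expression-graph neighbourhood size.
#' @param target_k desired cluster count (graph methods matched by
#'   resolution search; mclust uses it directly).
#' @param resolution fixed resolution when `target_k` is `NULL`.
#' @param w_neighbors spatial neighbours for Moran's I.
#' @param seed integer seed for embedding and clustering.
#' @return A `rasp_sweep` data frame with one row per
#'   `(knn, beta, method)`: `n_clusters`, `ari` (or `NA`), `morans_i`,
#'   `chaos`, `seed`.
#' @export
parameter_sweep <- function(X, coords, knn_grid = c(10L, 30L, 50L),
                            beta_grid = seq(0, 2, by = 0.25),
                            methods = "leiden", truth = NULL,
                            config = rasp_config(), n_neighbors = 10L,
                            target_k = NULL, resolution = 1,
                            w_neighbors = 6L, seed = 1L) {
  if (!length(knn_grid) || !length(beta_grid)) {
    stop_invalid("parameter grids must be non-empty")
  }
  Xm <- if (inherits(X, "rasp_expr")) X$X else X
  coords <- as.matrix(coords)
  pca <- randomized_pca(Xm, p = config$p, center = config$center,
                        scale = config$scale, seed = seed,
                        n_oversamples = config$n_oversamples,
                        n_power_iterations = config$n_power_iterations)
  rows <- list()
  for (knn in knn_grid) {
    D <- build_sparse_distance(coords, knn, config$distance_metric)
    D <- apply_diagonal(D, config$alpha_mode)
    for (beta in beta_grid) {
      weights <- weight_kernel(D, beta = beta, kernel = config$kernel,
                               bandwidth = config$bandwidth)
      Ps <- spatial_smooth(weights, pca$P)
      graph <- NULL
      for (method in methods) {
        cl <- sweep_cluster_cell(Ps, method, n_neighbors, target_k,
                                 resolution, seed, graph)
        rows[[length(rows) + 1L]] <- data.frame(
          knn = knn, beta = beta, method = method,
          n_clusters = cl$n_clusters,
          ari = if (is.null(truth)) NA_real_ else ari(truth, cl$labels),
          morans_i = suppressWarnings(
            as.numeric(morans_i(cl$labels, coords, w_neighbors))),
          chaos = suppressWarnings(chaos(cl$labels, coords)),
          seed = seed
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rasp_sweep", "data.frame")
  out
}

sweep_cluster_cell <- function(Ps, method, n_neighbors, target_k,
                               resolution, seed, graph = NULL) {
  if (method %in% c("mclust", "gmm")) {
    k <- if (is.null(target_k)) stop_invalid("mclust needs target_k") else target_k
    cluster_locations(Ps, "mclust", k = k, seed = seed)
  } else if (method == "walktrap") {
    cluster_locations(Ps, "walktrap", n_neighbors = n_neighbors,
                      k = target_k, seed = seed, graph = graph)
  } else if (!is.null(target_k) && method %in% c("leiden", "louvain")) {
    match_cluster_count(Ps, method, target_k = target_k,
                        n_neighbors = n_neighbors, seed = seed, graph = graph)
  } else {
    cluster_locations(Ps, method, n_neighbors = n_neighbors,
                      resolution = resolution, seed = seed, graph = graph)
  }
}

#' Select the best sweep row by a quality criterion
#'
#' `max_moran` and `max_ari` take the row maximizing the metric,
#' `min_chaos` the row minimizing CHAOS. Ties are broken by smaller kNN,
#' then smaller beta.
#'
#' @param table a `rasp_sweep` (or compatible data frame).
#' @param criterion selection rule.
#' @return The selected row (single-row data frame).
#' @export
select_parameters <- function(table,
                              criterion = c("max_moran", "min_chaos", "max_ari")) {
  criterion <- match.arg(criterion)
  col <- switch(criterion, max_moran = "morans_i", min_chaos = "chaos",
                max_ari = "ari")
  if (!col %in% names(table)) stop_invalid("column '", col, "' absent")
  v <- table[[col]]
  if (all(is.na(v))) stop_invalid("criterion column '", col, "' is all NA")
  if (criterion == "min_chaos") v <- -v
  ord <- order(-v, table$knn, table$beta, na.last = TRUE)
  table[ord[1L], , drop = FALSE]
}
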