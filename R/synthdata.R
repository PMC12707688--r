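#' Synthetic spatial-transcriptomics tissues
#'
#' The simulator generates labelled tissues with known spatial domains and
#' zero-inflated negative binomial (ZINB) counts so that every stage of the
#' smoothing/clustering pipeline can be tested without external data. Two
#' layouts are provided: a laminar *stripes* tissue (vertical bands of equal
#' width) and a *dots* tissue (circular regions of varying size on a large
#' background domain). Both default to eight annotated domains.
#'
#' @name synthdata
NULL

#' Create a striped (laminar) tissue layout
#'
#' Locations are scattered uniformly on a rectangle and each is labelled by
#' the vertical band its x-coordinate falls into; bands have equal width, so
#' domain k occupies x in `[(k-1), k) * width / n_domains`.
#'
#' @param n_cells number of locations to place.
#' @param n_domains number of vertical bands (domains).
#' @param seed integer seed controlling placement.
#' @param width,height extent of the tissue rectangle, in spatial units
#'   (micron-like by default).
#' @param deterministic if `TRUE`, place points on band centres instead of
#'   uniformly at random (useful for exact, seed-free fixtures).
#' @return A `rasp_layout`: list with `coords` (n x 2 matrix, columns
#'   `x`,`y`), `domain` (integer labels in `1:n_domains`), `model_name`,
#'   `seed`, and the bounding `width`/`height`.
#' @examples
#' lay <- make_stripes_layout(200, 8, seed = 1)
#' table(lay$domain)
#' @export
make_stripes_layout <- function(n_cells, n_domains = 8L, seed = 1L,
                                width = 1000, height = 1000,
                                deterministic = FALSE) {
  n_cells <- check_count(n_cells, "n_cells")
  n_domains <- check_count(n_domains, "n_domains")
  if (n_cells < n_domains) stop_invalid("n_cells must be >= n_domains")
  if (deterministic) {
    band <- rep(seq_len(n_domains), length.out = n_cells)
    x <- (band - 0.5) * width / n_domains
    y <- rep(height / 2, n_cells)
  } else {
    xy <- with_seed(seed, cbind(runif(n_cells, 0, width),
                                runif(n_cells, 0, height)))
    x <- xy[, 1]
    y <- xy[, 2]
  }
  coords <- cbind(x = x, y = y)
  domain <- stripes_domain_of(x, n_domains, width)
  new_layout(coords, domain, "stripes", seed, width, height)
}

## Band index of an x coordinate: floor(K * x / width), clamped to 1..K.
stripes_domain_of <- function(x, n_domains, width) {
  d <- floor(n_domains * x / width) + 1L
  pmin(pmax(as.integer(d), 1L), as.integer(n_domains))
}

#' Default circular-region specification for the dots layout
#'
#' Seven circles of varying radius scattered over a 1000 x 1000 rectangle;
#' together with the background they give eight annotated domains. The
#' geometry is a versioned fixture of this package (centres and radii are
#' arbitrary but fixed), chosen so that region sizes span roughly an order
#' of magnitude and small regions are only resolvable with local smoothing.
#'
#' @param width,height tissue extent used to scale the default geometry.
#' @return A data frame with columns `cx`, `cy`, `radius`, `label`.
#' @export
default_dot_spec <- function(width = 1000, height = 1000) {
  spec <- data.frame(
    cx     = c(200, 700, 450, 150, 850, 300, 650),
    cy     = c(800, 760, 550, 350, 400, 120, 160),
    radius = c(120, 140,  90,  70, 110, 100,  60),
    label  = 1:7
  )
  spec$cx <- spec$cx * width / 1000
  spec$cy <- spec$cy * height / 1000
  spec$radius <- spec$radius * min(width, height) / 1000
  spec
}

#' Create a dotted tissue layout
#'
#' Locations are scattered uniformly on a rectangle; each is labelled by the
#' last circle in `dot_spec` that contains it, or `background_label` if no
#' circle does. Circles may overlap (later rows take precedence).
#'
#' @param n_cells number of locations.
#' @param dot_spec data frame with columns `cx`, `cy`, `radius`, `label`
#'   (see [default_dot_spec()]).
#' @param background_label label assigned outside all circles.
#' @param seed integer seed controlling placement.
#' @param width,height tissue extent in spatial units.
#' @return A `rasp_layout` (see [make_stripes_layout()]).
#' @export
make_dots_layout <- function(n_cells, dot_spec = default_dot_spec(width, height),
                             background_label = 8L, seed = 1L,
                             width = 1000, height = 1000) {
  n_cells <- check_count(n_cells, "n_cells")
  if (nrow(dot_spec) > 0 && any(dot_spec$radius <= 0)) {
    stop_invalid("dot radii must be positive")
  }
  xy <- with_seed(seed, cbind(runif(n_cells, 0, width),
                              runif(n_cells, 0, height)))
  coords <- cbind(x = xy[, 1], y = xy[, 2])
  domain <- dots_domain_of(coords, dot_spec, background_label)
  new_layout(coords, domain, "dots", seed, width, height)
}

dots_domain_of <- function(coords, dot_spec, background_label) {
  domain <- rep(as.integer(background_label), nrow(coords))
  for (r in seq_len(NROW(dot_spec))) {
    inside <- (coords[, 1] - dot_spec$cx[r])^2 +
      (coords[, 2] - dot_spec$cy[r])^2 <= dot_spec$radius[r]^2
    domain[inside] <- as.integer(dot_spec$label[r])
  }
  domain
}

new_layout <- function(coords, domain, model_name, seed, width, height) {
  rownames(coords) <- paste0("loc", seq_len(nrow(coords)))
  structure(
    list(coords = coords, domain = domain, model_name = model_name,
         seed = seed, width = width, height = height),
    class = "rasp_layout"
  )
}

#' @export
print.rasp_layout <- function(x, ...) {
  cat(sprintf("rasp_layout '%s': %d locations, %d domains, %g x %g units\n",
              x$model_name, nrow(x$coords), length(unique(x$domain)),
              x$width, x$height))
  invisible(x)
}

#' Default per-domain fold-change table for signal genes
#'
#' Each signal gene modulates the baseline NB mean by a domain-specific
#' multiplicative fold change; fold changes are shared by blocks of
#' co-regulated genes so that each domain carries a strong, unique
#' multi-gene signature. The genes of each class are split into blocks
#' (low-signal into 3, high-signal into 4 for eight domains) and the
#' block values of a domain follow a row of a Sylvester Hadamard matrix:
#' `+1` entries take the high value of the class's pair, `-1` the low
#' value. This balanced orthogonal code makes every pair of domains
#' differ in half of the blocks, keeps each domain's total expression
#' nearly constant (so library-size normalization is close to neutral),
#' and spreads the between-domain variance evenly over all contrast
#' directions. Default contrasts: low-signal `c(1.5, 3)` (twofold,
#' log2FC 1) and high-signal `c(2, 8)` (fourfold, log2FC 2) — ordinary
#' marker-gene effect sizes. Noise genes have fold change 1 everywhere
#' and are not represented in this table.
#'
#' @param n_domains number of spatial domains (rows).
#' @param n_low_signal,n_high_signal numbers of low/high signal genes.
#' @param low_values,high_values length-2 `c(low, high)` fold-change pairs
#'   per gene class.
#' @return `n_domains x (n_low_signal + n_high_signal)` matrix, low-signal
#'   columns first.
#' @export
default_fold_changes <- function(n_domains = 8L, n_low_signal = 50L,
                                 n_high_signal = 50L,
                                 low_values = c(1.5, 3),
                                 high_values = c(2, 8)) {
  H <- hadamard_matrix(n_domains)        # >= n_domains rows/cols
  n_contrast <- ncol(H) - 1L             # non-constant columns
  n_blocks_low <- max(1L, min(floor(n_contrast / 2), ceiling(log2(n_domains))))
  n_blocks_high <- max(1L, n_contrast - n_blocks_low)
  fc <- cbind(
    coded_fold_changes(H, seq_len(n_blocks_low) + 1L,
                       n_domains, n_low_signal, low_values),
    coded_fold_changes(H, seq_len(n_blocks_high) + 1L + n_blocks_low,
                       n_domains, n_high_signal, high_values)
  )
  colnames(fc) <- c(sprintf("low%02d", seq_len(n_low_signal)),
                    sprintf("high%02d", seq_len(n_high_signal)))
  fc
}

## Smallest Sylvester Hadamard matrix with at least k rows.
hadamard_matrix <- function(k) {
  H <- matrix(1, 1, 1)
  while (nrow(H) < k) H <- rbind(cbind(H, H), cbind(H, -H))
  H[seq_len(k), , drop = FALSE]
}

## Fold changes for one gene class: genes split into equal blocks, block b
## of domain k takes values[2] where H[k, cols[b]] is +1 and values[1]
## where it is -1 (columns recycled if the class has more blocks than
## Hadamard columns available).
coded_fold_changes <- function(H, cols, n_domains, n_genes, values) {
  if (length(values) != 2L) stop_invalid("fold-change value sets are pairs")
  cols <- rep_len(((cols - 2L) %% (ncol(H) - 1L)) + 2L, length(cols))
  block_of <- sort(rep_len(seq_along(cols), n_genes))
  sign <- H[, cols[block_of], drop = FALSE]      # K x n_genes
  matrix(ifelse(sign > 0, values[2], values[1]), n_domains, n_genes)
}

#' Construct a ZINB gene model
#'
#' Counts follow a zero-inflated negative binomial: with probability
#' `zero_fraction` the count is a structural zero, otherwise it is drawn
#' from NB with mean `mu * fold_change` and dispersion `theta`
#' (variance `m + m^2/theta`). Defaults mirror a sparse imaging-based panel:
#' `mu = 2`, `theta = 0.5`, `zero_fraction = 0.5`, and 50 low-signal,
#' 50 high-signal, 50 noise genes.
#'
#' @param mu baseline NB mean (counts).
#' @param theta NB dispersion (`size` in [stats::rnbinom()]).
#' @param zero_fraction structural-zero probability in `[0, 1]`.
#' @param fold_changes `K x G_signal` matrix of per-domain fold changes for
#'   the signal genes (see [default_fold_changes()]).
#' @param n_noise number of noise genes (fold change 1 in every domain).
#' @param n_low_signal,n_high_signal how many leading columns of
#'   `fold_changes` are low- vs high-signal (used only for gene-class tags).
#' @return A `rasp_gene_model` list.
#' @export
zinb_gene_model <- function(mu = 2, theta = 0.5, zero_fraction = 0.5,
                            fold_changes = default_fold_changes(),
                            n_low_signal = 50L, n_high_signal = 50L,
                            n_noise = 50L) {
  if (mu < 0) stop_invalid("mu must be >= 0")
  if (theta <= 0) stop_invalid("theta must be > 0")
  if (zero_fraction < 0 || zero_fraction > 1) {
    stop_invalid("zero_fraction must lie in [0, 1]")
  }
  fold_changes <- as.matrix(fold_changes)
  if (any(fold_changes < 0)) stop_invalid("fold changes must be >= 0")
  if (ncol(fold_changes) != n_low_signal + n_high_signal) {
    stop_invalid("fold_changes must have n_low_signal + n_high_signal columns")
  }
  structure(
    list(mu = mu, theta = theta, zero_fraction = zero_fraction,
         fold_changes = fold_changes,
         n_low_signal = as.integer(n_low_signal),
         n_high_signal = as.integer(n_high_signal),
         n_noise = as.integer(n_noise)),
    class = "rasp_gene_model"
  )
}

#' Simulate a ZINB count matrix over a tissue layout
#'
#' For a location in domain `k` and signal gene `g`, counts are ZINB with
#' NB mean `mu * fold_changes[k, g]`; noise genes use mean `mu` everywhere.
#' Structural zeros are drawn independently with probability
#' `zero_fraction`. Draws are reproducible from `seed`.
#'
#' @param layout a `rasp_layout`.
#' @param genes a `rasp_gene_model`; its fold-change matrix must have one
#'   row per domain present in `layout`.
#' @param seed integer seed for the count draws.
#' @return A `rasp_counts`: sparse `dgCMatrix` `counts` (locations x genes)
#'   plus `location_ids`, `gene_ids`, `gene_class`, `layout`, `seed`.
#' @examples
#' lay <- make_stripes_layout(100, 4, seed = 1)
#' gm <- zinb_gene_model(fold_changes = default_fold_changes(4, 5, 5),
#'                       n_low_signal = 5, n_high_signal = 5, n_noise = 5)
#' cm <- simulate_counts(lay, gm, seed = 1)
#' dim(cm$counts)
#' @export
simulate_counts <- function(layout, genes, seed = 1L) {
  stopifnot(inherits(layout, "rasp_layout"), inherits(genes, "rasp_gene_model"))
  n_domains <- max(layout$domain)
  if (nrow(genes$fold_changes) != n_domains) {
    stop_invalid("fold_changes must have one row per domain (",
                 n_domains, " needed, got ", nrow(genes$fold_changes), ")")
  }
  n <- nrow(layout$coords)
  g_signal <- ncol(genes$fold_changes)
  m <- g_signal + genes$n_noise
  counts <- with_seed(seed, {
    ## NB mean per (location, gene): fold change indexed by the location's
    ## domain for signal genes, 1 for noise genes.
    mu_mat <- cbind(genes$fold_changes[layout$domain, , drop = FALSE],
                    matrix(1, n, genes$n_noise)) * genes$mu
    draws <- rnbinom(n * m, size = genes$theta, mu = as.vector(mu_mat))
    keep <- rbinom(n * m, 1L, 1 - genes$zero_fraction)
    matrix(draws * keep, n, m)
  })
  signal_ids <- colnames(genes$fold_changes)
  if (is.null(signal_ids)) {
    signal_ids <- sprintf("signal%02d", seq_len(g_signal))
  }
  gene_ids <- c(signal_ids, sprintf("noise%02d", seq_len(genes$n_noise)))
  gene_class <- c(rep("low_signal", genes$n_low_signal),
                  rep("high_signal", genes$n_high_signal),
                  rep("noise", genes$n_noise))
  dimnames(counts) <- list(rownames(layout$coords), gene_ids)
  structure(
    list(counts = as(as(counts, "generalMatrix"), "CsparseMatrix"),
         location_ids = rownames(layout$coords),
         gene_ids = gene_ids, gene_class = gene_class,
         layout = layout, seed = seed),
    class = "rasp_counts"
  )
}

#' @export
print.rasp_counts <- function(x, ...) {
  cat(sprintf("rasp_counts: %d locations x %d genes, %.1f%% zeros\n",
              nrow(x$counts), ncol(x$counts),
              100 * (1 - Matrix::nnzero(x$counts) / prod(dim(x$counts)))))
  invisible(x)
}

#' Generate replicate count matrices
#'
#' Replicate `r` (1-based) is simulated with seed `base_seed + r - 1`, so
#' replicates are individually reproducible and mutually distinct.
#'
#' @param layout a `rasp_layout` shared by all replicates.
#' @param genes a `rasp_gene_model`.
#' @param n_replicates number of replicates (>= 1).
#' @param base_seed seed of the first replicate.
#' @return List of `rasp_counts`.
#' @export
replicate_batch <- function(layout, genes, n_replicates, base_seed = 1L) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  lapply(seq_len(n_replicates), function(r) {
    simulate_counts(layout, genes, seed = base_seed + r - 1L)
  })
}

#' Analytic ZINB zero probability
#'
#' `P(count = 0) = zero_fraction + (1 - zero_fraction) * (theta/(theta+mu))^theta`.
#'
#' @param mu,theta,zero_fraction ZINB parameters.
#' @return Probability of observing a zero.
#' @export
zinb_zero_probability <- function(mu, theta, zero_fraction) {
  zero_fraction + (1 - zero_fraction) * (theta / (theta + mu))^theta
}
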