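# rasp — randomized spatial PCA for spatial transcriptomics

Spatial transcriptomics assays (Visium, Visium HD, MERFISH, Xenium,
Stereo-seq, ...) measure gene expression at thousands to hundreds of
thousands of positions in a tissue section. Clustering ordinary principal
components of the expression matrix finds cell types but ignores tissue
geometry; recognizing *spatial domains* — contiguous regions such as
cortical layers — needs spatial information. Most spatially aware
embedding methods are too slow or memory-hungry for modern subcellular
datasets.

`rasp` implements a fast, spatially aware dimensionality reduction for
people analyzing such data: a randomized truncated PCA of the sparse
location-by-gene matrix, followed by smoothing of the component scores
with a k-nearest-neighbour sparsified inverse-distance weight matrix,

```
W, P = rPCA(X, p)                     # p-component randomized PCA, X centered implicitly
D_ij = dist(c_i, c_j)  for j in kNN(i);  D_ii = alpha (row minimum)
W_ij = 1 / D_ij^beta   (columns divided by their maximum)
Ps   = W P                            # spatially smoothed scores
```

`beta = 0` gives a uniform (rectangular) kernel over the neighbourhood —
broad, domain-scale smoothing; `beta = 2` concentrates weight on the
closest neighbours — local, cell-type-scale smoothing. Location-level
covariates (cell density, library size, volume) can be integrated through
a second-stage PCA of the smoothed scores and (optionally smoothed)
covariates. On top of the embedding the package provides:

* graph clustering of the smoothed scores (Leiden / Louvain / Walktrap /
  Gaussian mixtures) on a UMAP-style connectivity graph in PC space;
* label-free cluster quality metrics — Moran's I and the CHAOS score —
  and a `(kNN, beta)` parameter sweep with automatic selection;
* ALRA-style reduced-rank reconstruction of de-noised, spatially smoothed
  per-gene expression (quantile thresholding that preserves biological
  zeros, optional variance rescaling);
* QC filtering (mito/ribo fraction, minimum reads, MAD outliers) and
  library-size + log normalization;
* a zero-inflated negative binomial tissue simulator (striped and dotted
  domain layouts) so everything above is testable without external data;
* a command-line interface (`inst/cli/rasp.R`) with `simulate`,
  `preprocess`, `run`, `reconstruct`, `sweep` and `select` subcommands,
  Matrix Market / CSV IO and JSON run manifests.

## Worked example

Simulate an eight-stripe tissue with ZINB counts, normalize, embed,
smooth, cluster, and score the partition:

```r
library(rasp)

layout <- make_stripes_layout(2000, n_domains = 8, seed = 1)
counts <- simulate_counts(layout, zinb_gene_model(), seed = 1)
qc     <- qc_filter(counts, thresholds = qc_thresholds(min_reads = 50))
expr   <- normalize_expression(qc$counts)

fit <- rasp(expr, config = rasp_config(p = 20, threshold = 10, beta = 0, seed = 1))
cl  <- match_cluster_count(fit$Ps, "leiden", target_k = 8, seed = 1)
cl
#> rasp_clusters: 1979 locations in 8 clusters (leiden)

round(ari(expr$domain, cl$labels), 3)                      # vs ground truth
#> [1] 0.587
round(as.numeric(morans_i(cl, expr$coords)), 3)            # spatial contiguity
#> [1] 0.916
round(chaos(cl, expr$coords), 4)                           # compactness (lower = better)
#> [1] 0.0118

plain <- match_cluster_count(fit$P, "leiden", target_k = 8, seed = 1)
round(ari(expr$domain, plain$labels), 3)                   # unsmoothed PCA baseline
#> [1] 0.039
```

Smoothing lifts domain recovery from an ARI of 0.04 (plain PCA scores
`fit$P`) to 0.59, with a highly contiguous partition (Moran's I 0.92).
`parameter_sweep()` scans a `(kNN, beta)` grid reusing one embedding, and
`select_parameters()` picks the best cell by `max_moran`, `min_chaos` or
`max_ari`. See the vignette in `vignettes/` for the model, parameter
guidance, and the design of the synthetic tissues.

The same pipeline from a shell:

```sh
Rscript inst/cli/rasp.R simulate --model stripes --n-cells 2000 --seed 1 --out sim/
Rscript inst/cli/rasp.R sweep --counts sim/ --knn-grid 5,10,30 --beta-grid 0:2:0.5 \
    --methods leiden --n-pcs 20 --seed 1 --out sweep.csv
Rscript inst/cli/rasp.R select --table sweep.csv --criterion max_moran
```

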