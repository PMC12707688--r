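#' Write a simulated or observed count matrix to disk
#'
#' Writes `counts.mtx` (Matrix Market), `locations.csv`
#' (`id,x,y[,domain]`) and `genes.csv` (`id[,class]`) into `dir`.
#'
#' @param counts a `rasp_counts` or a sparse/dense location-by-gene matrix
#'   with dimnames.
#' @param dir output directory (created if missing).
#' @param coords optional n x 2 coordinate matrix when `counts` is a bare
#'   matrix.
#' @param domain optional integer domain labels.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(counts, dir, coords = NULL, domain = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(counts, "rasp_counts")) {
    mat <- counts$counts
    coords <- counts$layout$coords
    domain <- counts$layout$domain
    gene_class <- counts$gene_class
  } else {
    mat <- as(as(counts, "generalMatrix"), "CsparseMatrix")
    gene_class <- NULL
  }
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(mat, mtx)
  loc <- data.frame(id = rownames(mat))
  if (!is.null(coords)) {
    loc$x <- coords[, 1]
    loc$y <- coords[, 2]
  }
  if (!is.null(domain)) loc$domain <- domain
  utils::write.csv(loc, file.path(dir, "locations.csv"), row.names = FALSE)
  gen <- data.frame(id = colnames(mat))
  if (!is.null(gene_class)) gen$class <- gene_class
  utils::write.csv(gen, file.path(dir, "genes.csv"), row.names = FALSE)
  invisible(file.path(dir, c("counts.mtx", "locations.csv", "genes.csv")))
}

#' Read a count matrix written by [write_counts()]
#'
#' @param dir directory holding `counts.mtx`, `locations.csv`, `genes.csv`.
#' @return A `rasp_counts`; `layout` carries coordinates (and domains when
#'   present in `locations.csv`).
#' @export
read_counts <- function(dir) {
  mat <- as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  loc <- utils::read.csv(file.path(dir, "locations.csv"))
  gen <- utils::read.csv(file.path(dir, "genes.csv"))
  if (nrow(loc) != nrow(mat) || nrow(gen) != ncol(mat)) {
    stop_invalid("locations/genes files do not match matrix dimensions")
  }
  dimnames(mat) <- list(loc$id, gen$id)
  coords <- NULL
  if (all(c("x", "y") %in% names(loc))) {
    coords <- cbind(x = loc$x, y = loc$y)
    rownames(coords) <- loc$id
  }
  domain <- if ("domain" %in% names(loc)) as.integer(loc$domain) else NULL
  layout <- NULL
  if (!is.null(coords)) {
    layout <- structure(
      list(coords = coords,
           domain = if (is.null(domain)) rep(1L, nrow(coords)) else domain,
           model_name = "file", seed = NA_integer_,
           width = diff(range(coords[, 1])),
           height = diff(range(coords[, 2]))),
      class = "rasp_layout"
    )
  }
  structure(
    list(counts = mat, location_ids = loc$id, gene_ids = gen$id,
         gene_class = if ("class" %in% names(gen)) gen$class else NULL,
         layout = layout, seed = NA_integer_),
    class = "rasp_counts"
  )
}

#' Read an n x 2 spatial coordinate table
#'
#' @param path CSV with columns `x` and `y` (an `id` column, if present,
#'   becomes row names).
#' @return Numeric matrix with columns `x`, `y`.
#' @export
read_coords <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) {
    stop_invalid("coordinate file must have columns 'x' and 'y'")
  }
  coords <- cbind(x = df$x, y = df$y)
  if ("id" %in% names(df)) rownames(coords) <- df$id
  coords
}
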