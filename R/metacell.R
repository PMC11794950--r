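#' Group cells into metacells
#'
#' Seeded k-means over the LSI embedding (depth-flagged components excluded)
#' with `k = floor(n_cells / target_size)` clusters. Metacells pool the
#' counts of transcriptionally similar cells to beat sparsity before
#' correlation analyses; the downstream linkage depends on this aggregation
#' granularity rather than on any particular metacell algorithm.
#'
#' @param embedding A `phr_lsi` object or a numeric cell-by-component matrix.
#' @param target_size Target number of cells per metacell.
#' @param seed Integer seed for the k-means initialization.
#' @return Integer vector of metacell ids (1..k), named by barcode.
#' @export
compute_metacells <- function(embedding, target_size = 75, seed = 1L) {
  x <- if (inherits(embedding, "phr_lsi")) {
    embedding$embedding[, !embedding$flagged, drop = FALSE]
  } else {
    as.matrix(embedding)
  }
  n <- nrow(x)
  if (n < 2 * target_size) {
    abort("Need at least 2 * target_size cells.")
  }
  k <- floor(n / target_size)
  if (k < 2) abort("Fewer than 2 metacells; decrease `target_size`.")
  set.seed(seed)
  km <- kmeans(x, centers = k, nstart = 10, iter.max = 100)
  if (any(km$size == 0)) abort("k-means produced an empty metacell.")
  setNames(km$cluster, rownames(x))
}

#' Aggregate a dataset over metacells
#'
#' Sums raw counts per metacell for every modality (totals are conserved
#' exactly), then normalizes the aggregates: CLR for ADT, TF-IDF for ATAC,
#' and depth-scaled log1p for RNA.
#'
#' @param dataset A `phr_dataset`.
#' @param assignment Metacell ids per cell (from [compute_metacells()]).
#' @param scale_factor RNA log-normalization scale factor.
#' @return A list of class `phr_metacells`: `assignment`, `sizes`, `counts`
#'   (summed matrices per modality) and `norm` (normalized aggregates).
#' @export
aggregate_metacells <- function(dataset, assignment, scale_factor = 1e4) {
  cells <- rownames(dataset$atac)
  if (!is.null(names(assignment))) assignment <- assignment[cells]
  if (length(assignment) != length(cells) || anyNA(assignment)) {
    abort("`assignment` must cover every cell of the dataset.")
  }
  ids <- sort(unique(assignment))
  ind <- Matrix::sparseMatrix(i = seq_along(assignment),
                              j = match(assignment, ids), x = 1,
                              dims = c(length(cells), length(ids)))
  agg <- function(m) {
    out <- as.matrix(Matrix::crossprod(ind, m))
    rownames(out) <- paste0("mc", ids)
    out
  }
  counts <- list(atac = agg(dataset$atac), adt = agg(dataset$adt))
  if (!is.null(dataset$rna)) counts$rna <- agg(dataset$rna)
  counts$free_oligo <- drop(agg(matrix(dataset$free_oligo, ncol = 1)))
  norm <- list(
    adt = clr_normalize(counts$adt),
    atac = as.matrix(tfidf(counts$atac))
  )
  if (!is.null(counts$rna)) {
    rs <- rowSums(counts$rna)
    norm$rna <- log1p(scale_factor * counts$rna / rs)
  }
  structure(
    list(assignment = setNames(assignment, cells),
         sizes = as.integer(table(factor(assignment, levels = ids))),
         counts = counts, norm = norm),
    class = "phr_metacells"
  )
}

#' @export
#' @method print phr_metacells
print.phr_metacells <- function(x, ...) {
  cat(sprintf("<phr_metacells> %d metacells (sizes %d-%d) over %d cells\n",
              length(x$sizes), min(x$sizes), max(x$sizes),
              length(x$assignment)))
  invisible(x)
}
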