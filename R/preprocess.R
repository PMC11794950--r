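#' Quality-control filtering of cells
#'
#' Removes cells with total ADT counts strictly above `adt_count_max`
#' (outliers in ADT space), cells with total RNA UMIs outside
#' `rna_umi_bounds` (only when an RNA layer is present), and cells with total
#' peak counts outside `peak_count_bounds`. Bounds are strict inequalities on
#' both sides; set a rule to `NULL` in the config to disable it.
#'
#' @param dataset A `phr_dataset`.
#' @param config A [pipeline_config()].
#' @return A list: `dataset` (filtered) and `report` (tibble of rule,
#'   n_removed), class `phr_qc`.
#' @export
qc_filter <- function(dataset, config = pipeline_config()) {
  n <- nrow(dataset$atac)
  keep <- rep(TRUE, n)
  report <- list()
  flag <- function(bad, rule) {
    report[[length(report) + 1L]] <<- tibble::tibble(
      rule = rule, n_removed = sum(bad & keep))
    keep <<- keep & !bad
  }
  if (!is.null(config$adt_count_max)) {
    flag(rowSums(dataset$adt) > config$adt_count_max, "adt_count_max")
  }
  if (!is.null(dataset$rna) && !is.null(config$rna_umi_bounds)) {
    tot <- Matrix::rowSums(dataset$rna)
    flag(tot < config$rna_umi_bounds[1] | tot > config$rna_umi_bounds[2],
         "rna_umi_bounds")
  }
  if (!is.null(config$peak_count_bounds)) {
    tot <- Matrix::rowSums(dataset$atac)
    flag(tot < config$peak_count_bounds[1] | tot > config$peak_count_bounds[2],
         "peak_count_bounds")
  }
  if (!any(keep)) abort("QC removed every cell.")
  structure(
    list(dataset = subset_cells(dataset, keep),
         report = dplyr::bind_rows(report),
         n_before = n, n_after = sum(keep)),
    class = "phr_qc"
  )
}

#' @export
#' @method print phr_qc
print.phr_qc <- function(x, ...) {
  cat(sprintf("<phr_qc> %d -> %d cells\n", x$n_before, x$n_after))
  print(x$report)
  invisible(x)
}

#' Centered log-ratio normalization of tag counts
#'
#' Per cell (default margin) across tags:
#' `clr_ij = log1p(x_ij) - mean_j log1p(x_ij)`, so rows sum to zero exactly.
#' The alternative margin (per tag across cells) is exposed because tools in
#' the field disagree on which margin they apply.
#'
#' @param counts Cell-by-tag count matrix.
#' @param margin `"cells"` (center within each cell) or `"tags"`.
#' @return A dense numeric matrix of CLR values with the input dimnames.
#' @export
#' @examples
#' clr_normalize(rbind(c(3, 0), c(1, 1)))
clr_normalize <- function(counts, margin = c("cells", "tags")) {
  margin <- match.arg(margin)
  x <- log1p(as.matrix(counts))
  if (min(counts) < 0) abort("`counts` must be non-negative.")
  if (margin == "cells") x - rowMeans(x) else x - rep(colMeans(x), each = nrow(x))
}

#' Regress ADT values on free-oligo counts
#'
#' Per tag, ordinary least squares of the CLR values on `log1p(free_oligo)`
#' with an intercept. The free-oligo count indexes how permeable/sticky each
#' cell is, so the residuals are ADT levels purged of nonspecific background.
#' A constant covariate yields centered CLR values and slope 0 with a warning.
#'
#' @param clr Cell-by-tag matrix of CLR values.
#' @param free_oligo Per-cell free-oligo counts (non-negative).
#' @return A list of class `phr_adt_norm`: `residuals` (cell-by-tag matrix),
#'   `slopes` and `intercepts` (per tag).
#' @export
regress_free_oligo <- function(clr, free_oligo) {
  clr <- as.matrix(clr)
  if (length(free_oligo) != nrow(clr)) {
    abort("`free_oligo` must have one value per cell (row of `clr`).")
  }
  if (any(free_oligo < 0)) abort("`free_oligo` must be non-negative.")
  if (any(!is.finite(clr))) abort("`clr` must be finite.")
  x <- log1p(free_oligo)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx < .Machine$double.eps * length(x)) {
    warn("Constant free-oligo covariate; returning centered CLR, slopes 0.")
    slopes <- setNames(rep(0, ncol(clr)), colnames(clr))
    res <- clr - rep(colMeans(clr), each = nrow(clr))
    return(structure(list(residuals = res, slopes = slopes,
                          intercepts = colMeans(clr)),
                     class = "phr_adt_norm"))
  }
  slopes <- drop(crossprod(xc, clr)) / sxx
  intercepts <- colMeans(clr) - slopes * mean(x)
  res <- clr - outer(x, slopes) - rep(intercepts, each = nrow(clr))
  structure(list(residuals = res, slopes = setNames(slopes, colnames(clr)),
                 intercepts = setNames(intercepts, colnames(clr))),
            class = "phr_adt_norm")
}

#' @export
#' @method print phr_adt_norm
print.phr_adt_norm <- function(x, ...) {
  cat(sprintf("<phr_adt_norm> %d cells x %d tags; slope range [%.3f, %.3f]\n",
              nrow(x$residuals), ncol(x$residuals),
              min(x$slopes), max(x$slopes)))
  invisible(x)
}

#' Normalize the ADT layer of a dataset
#'
#' Convenience wrapper: CLR per cell, then per-tag regression on the
#' free-oligo covariate.
#'
#' @param dataset A `phr_dataset`.
#' @return The residual matrix (cells by tags) with the regression fit as
#'   attribute `"fit"`.
#' @export
adt_normalize <- function(dataset) {
  fit <- regress_free_oligo(clr_normalize(dataset$adt), dataset$free_oligo)
  structure(fit$residuals, fit = fit)
}

#' Population summary for staining-index calculations
#' @param values Numeric vector of per-cell tag levels.
#' @return List with `median` and `sd`.
#' @export
population_summary <- function(values) {
  list(median = median(values), sd = sd(values))
}

#' Staining index
#'
#' Signal-to-background metric for antibody staining:
#' `(median_pos - median_neg) / (2 * sd_neg)`.
#'
#' @param pos,neg Either [population_summary()] lists or raw numeric vectors.
#' @return A single number.
#' @export
#' @examples
#' staining_index(list(median = 10, sd = 2), list(median = 4, sd = 1.5))
staining_index <- function(pos, neg) {
  if (is.numeric(pos)) pos <- population_summary(pos)
  if (is.numeric(neg)) neg <- population_summary(neg)
  if (!is.finite(neg$sd) || neg$sd <= 0) {
    abort("Staining index undefined: negative-population sd must be > 0.")
  }
  (pos$median - neg$median) / (2 * neg$sd)
}

#' TF-IDF weighting of a peak count matrix
#'
#' The log-scaled variant standard in scATAC workflows:
#' `log(1 + 1e4 * (x_ij / rowsum_i) * (n_cells / colcount_j))`, where
#' `colcount_j` is the number of cells in which peak j is detected. Peaks
#' detected in no cell yield all-zero columns.
#'
#' @param counts Cell-by-peak counts (sparse supported); no all-zero cells.
#' @param scale_factor Scale inside the log (default 1e4).
#' @return A `dgCMatrix` of TF-IDF values.
#' @export
tfidf <- function(counts, scale_factor = 1e4) {
  x <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  rs <- Matrix::rowSums(x)
  if (any(rs == 0)) {
    bad <- rownames(x)[which(rs == 0)[1]] %||% as.character(which(rs == 0)[1])
    abort(sprintf("Cell with zero counts: %s", bad))
  }
  colcount <- Matrix::colSums(x > 0)
  idf <- ifelse(colcount > 0, nrow(x) / colcount, 0)
  # operate on nonzero entries only; zeros map to log1p(0) = 0
  row_of <- x@i + 1L
  col_of <- rep.int(seq_len(ncol(x)), diff(x@p))
  x@x <- log1p(scale_factor * (x@x / rs[row_of]) * idf[col_of])
  x
}

#' Latent semantic indexing of a TF-IDF matrix
#'
#' Exact truncated SVD computed from the eigen-decomposition of the
#' cell-by-cell Gram matrix, with a deterministic sign convention (the
#' largest-magnitude loading of each left singular vector is positive).
#' Reports the Pearson correlation of every component with log total counts;
#' components with `|r| > 0.75` are flagged as depth-driven and excluded by
#' downstream metacell clustering.
#'
#' @param x Cell-by-peak TF-IDF matrix.
#' @param n_components Number of components (< min dimension and rank).
#' @param counts_total Optional per-cell raw totals for the depth
#'   correlation; defaults to row sums of `x`.
#' @param depth_cor_cutoff Absolute correlation above which a component is
#'   flagged.
#' @param seed Kept for interface stability; the decomposition is exact and
#'   deterministic.
#' @return A list of class `phr_lsi`: `embedding` (cells by components, U*D),
#'   `d` (singular values), `depth_cor`, `flagged` (logical).
#' @export
lsi <- function(x, n_components = 30, counts_total = NULL,
                depth_cor_cutoff = 0.75, seed = 1L) {
  if (n_components >= min(dim(x))) {
    abort("`n_components` must be smaller than both matrix dimensions.")
  }
  gram <- as.matrix(Matrix::tcrossprod(x))
  eig <- eigen(gram, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-12
  if (n_components > sum(pos)) {
    abort(sprintf("`n_components` (%d) exceeds matrix rank (%d).",
                  n_components, sum(pos)))
  }
  d <- sqrt(pmax(eig$values[seq_len(n_components)], 0))
  u <- eig$vectors[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    if (u[which.max(abs(u[, k])), k] < 0) u[, k] <- -u[, k]
  }
  emb <- u * rep(d, each = nrow(u))
  rownames(emb) <- rownames(x)
  colnames(emb) <- paste0("LSI_", seq_len(n_components))
  tot <- counts_total %||% Matrix::rowSums(x)
  tot <- if (all(tot >= 0)) log1p(tot) else tot
  varying <- apply(emb, 2, sd) > 0
  depth_cor <- rep(0, n_components)
  depth_cor[varying] <- drop(cor(tot, emb[, varying, drop = FALSE]))
  structure(
    list(embedding = emb, d = d, depth_cor = depth_cor,
         flagged = abs(depth_cor) > depth_cor_cutoff),
    class = "phr_lsi"
  )
}

#' @export
#' @method print phr_lsi
print.phr_lsi <- function(x, ...) {
  cat(sprintf("<phr_lsi> %d cells x %d components; %d depth-flagged\n",
              nrow(x$embedding), ncol(x$embedding), sum(x$flagged)))
  invisible(x)
}
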