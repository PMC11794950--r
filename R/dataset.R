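#' Assemble a trimodal single-cell dataset
#'
#' Aligns the accessibility, ADT, and (optional) RNA layers on a shared cell
#' index together with per-cell free-oligo (spiked unconjugated tag) counts,
#' cell metadata, the peak set, and a TSS table.
#'
#' @param atac Cell-by-peak counts (sparse or dense, non-negative).
#' @param adt Cell-by-tag ADT counts.
#' @param free_oligo Per-cell counts of the spiked unconjugated tag.
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `peak_id`, optional
#'   `gc`), one row per `atac` column.
#' @param rna Optional cell-by-gene counts, measured or imputed; the pipeline
#'   treats both identically and records which via `rna_provenance`.
#' @param hto Optional cell-by-hash counts.
#' @param cell_meta Optional tibble of per-cell metadata (`donor`, `genotype`,
#'   `cell_type`, ...); a `barcode` column is added from the cell index.
#' @param tss Optional TSS tibble (`gene`, `chrom`, `tss`, `strand`).
#' @param rna_provenance `"measured"` or `"imputed"`.
#' @return A list of class `phr_dataset`.
#' @export
trimodal_dataset <- function(atac, adt, free_oligo, peaks,
                             rna = NULL, hto = NULL, cell_meta = NULL,
                             tss = NULL,
                             rna_provenance = c("measured", "imputed")) {
  rna_provenance <- match.arg(rna_provenance)
  atac <- methods::as(Matrix::Matrix(atac, sparse = TRUE), "CsparseMatrix")
  adt <- as.matrix(adt)
  cells <- rownames(atac)
  if (is.null(cells)) abort("`atac` must carry cell barcodes as rownames.")
  layers <- list(adt = adt, rna = rna, hto = hto)
  for (nm in names(layers)) {
    x <- layers[[nm]]
    if (is.null(x)) next
    if (nrow(x) != length(cells)) {
      abort(sprintf("`%s` has %d rows; expected %d cells.",
                    nm, nrow(x), length(cells)))
    }
    if (!is.null(rownames(x)) && !identical(rownames(x), cells)) {
      abort(sprintf("`%s` cell index does not match `atac`.", nm))
    }
    if (min(x) < 0) abort(sprintf("`%s` contains negative entries.", nm))
  }
  if (min(atac) < 0) abort("`atac` contains negative entries.")
  if (length(free_oligo) != length(cells) || any(free_oligo < 0)) {
    abort("`free_oligo` must be one non-negative count per cell.")
  }
  if (nrow(peaks) != ncol(atac)) {
    abort(sprintf("%d peaks for %d atac columns.", nrow(peaks), ncol(atac)))
  }
  if (anyDuplicated(peaks$peak_id)) abort("`peaks$peak_id` must be unique.")
  if (any(peaks$start >= peaks$end) || any(peaks$start < 0)) {
    abort("Peak intervals must satisfy 0 <= start < end.")
  }
  if ("gc" %in% names(peaks) && any(peaks$gc < 0 | peaks$gc > 1)) {
    abort("`peaks$gc` must lie in [0, 1].")
  }
  colnames(atac) <- peaks$peak_id
  unlinked <- character()
  if (!is.null(rna) && !is.null(tss)) {
    unlinked <- setdiff(colnames(rna), tss$gene)
  }
  if (is.null(cell_meta)) cell_meta <- tibble::tibble(.rows = length(cells))
  cell_meta <- tibble::as_tibble(cell_meta)
  cell_meta$barcode <- cells
  structure(
    list(atac = atac, adt = adt, rna = rna, hto = hto,
         free_oligo = setNames(as.numeric(free_oligo), cells),
         peaks = tibble::as_tibble(peaks), tss = tss,
         cell_meta = cell_meta,
         rna_provenance = if (is.null(rna)) NULL else rna_provenance,
         unlinked_genes = unlinked),
    class = "phr_dataset"
  )
}

#' @export
#' @method print phr_dataset
print.phr_dataset <- function(x, ...) {
  cat(sprintf("<phr_dataset> %d cells\n", nrow(x$atac)))
  cat(sprintf("  atac: %d peaks (%.1f%% nonzero)\n", ncol(x$atac),
              100 * Matrix::nnzero(x$atac) / prod(dim(x$atac))))
  cat(sprintf("  adt:  %d tags; free-oligo median %.0f\n", ncol(x$adt),
              median(x$free_oligo)))
  if (!is.null(x$rna)) {
    cat(sprintf("  rna:  %d genes (%s)\n", ncol(x$rna), x$rna_provenance))
  }
  if (!is.null(x$hto)) cat(sprintf("  hto:  %d hashes\n", ncol(x$hto)))
  if (ncol(x$cell_meta) > 1) {
    cat("  meta:", paste(setdiff(names(x$cell_meta), "barcode"),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a trimodal dataset to a set of cells
#'
#' @param dataset A `phr_dataset`.
#' @param cells Barcodes or logical/integer index over cells.
#' @return A `phr_dataset` restricted to `cells`.
#' @export
subset_cells <- function(dataset, cells) {
  if (is.character(cells)) cells <- match(cells, rownames(dataset$atac))
  if (is.logical(cells)) cells <- which(cells)
  if (anyNA(cells) || !length(cells)) abort("Unknown or empty cell selection.")
  dataset$atac <- dataset$atac[cells, , drop = FALSE]
  dataset$adt <- dataset$adt[cells, , drop = FALSE]
  if (!is.null(dataset$rna)) {
    dataset$rna <- dataset$rna[cells, , drop = FALSE]
  }
  if (!is.null(dataset$hto)) {
    dataset$hto <- dataset$hto[cells, , drop = FALSE]
  }
  dataset$free_oligo <- dataset$free_oligo[cells]
  dataset$cell_meta <- dataset$cell_meta[cells, , drop = FALSE]
  dataset
}
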