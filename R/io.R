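#' Read a labelled sparse count matrix
#'
#' Reads cell-by-feature counts either from a MatrixMarket file with sidecar
#' label files (`<path>`, `<path>.rows`, `<path>.cols`, one label per line,
#' rows = cells) or from a dense TSV with row names in the first column and
#' feature names in the header.
#'
#' @param path Path to a `.mtx` (MatrixMarket) or `.tsv` file.
#' @param row_labels,col_labels Optional character vectors overriding the
#'   sidecar/TSV labels.
#' @return A `dgCMatrix` with dimnames set (cells in rows).
#' @export
read_counts <- function(path, row_labels = NULL, col_labels = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (grepl("\\.mtx$", path)) {
    m <- tryCatch(
      methods::as(methods::as(Matrix::readMM(path), "generalMatrix"),
                  "CsparseMatrix"),
      error = function(e) abort(sprintf("Malformed MatrixMarket file %s: %s",
                                        path, conditionMessage(e)))
    )
    if (is.null(row_labels) && file.exists(paste0(path, ".rows"))) {
      row_labels <- readLines(paste0(path, ".rows"))
    }
    if (is.null(col_labels) && file.exists(paste0(path, ".cols"))) {
      col_labels <- readLines(paste0(path, ".cols"))
    }
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- Matrix::Matrix(as.matrix(tab[, -1, drop = FALSE]), sparse = TRUE)
    m <- methods::as(m, "CsparseMatrix")
    row_labels <- row_labels %||% as.character(tab[[1]])
    col_labels <- col_labels %||% colnames(tab)[-1]
  }
  if (!is.null(row_labels)) {
    if (length(row_labels) != nrow(m)) {
      abort(sprintf("%d row labels for %d rows.", length(row_labels), nrow(m)))
    }
    dup <- row_labels[duplicated(row_labels)]
    if (length(dup)) {
      abort(sprintf("Duplicate barcode(s): %s",
                    paste(unique(dup), collapse = ", ")))
    }
  }
  if (!is.null(col_labels) && length(col_labels) != ncol(m)) {
    abort(sprintf("%d column labels for %d columns.",
                  length(col_labels), ncol(m)))
  }
  dimnames(m) <- list(row_labels %||% dimnames(m)[[1]],
                      col_labels %||% dimnames(m)[[2]])
  m
}

#' Write a labelled sparse count matrix
#'
#' Inverse of [read_counts()]: writes MatrixMarket plus `.rows`/`.cols` label
#' sidecars. Integer matrices round-trip bit-exactly.
#'
#' @param mat Matrix (sparse or dense) with dimnames.
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(mat, path) {
  # force a general matrix so writeMM never emits the symmetric dialect
  m <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, path)
  if (!is.null(rownames(m))) writeLines(rownames(m), paste0(path, ".rows"))
  if (!is.null(colnames(m))) writeLines(colnames(m), paste0(path, ".cols"))
  invisible(path)
}

#' Read peak intervals from a BED file
#'
#' BED3+ with 0-based half-open coordinates. Column 4, when present, supplies
#' `peak_id`; otherwise ids are auto-assigned as `chrom:start-end`. A `gc`
#' column is carried through when present as column 5 header-less input lacks
#' it; use [peak_gc()] on sequences otherwise.
#'
#' @param path BED file path (optionally gzipped).
#' @return A tibble with columns `chrom`, `start`, `end`, `peak_id` (and `gc`
#'   when present), one row per peak.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tab) < 3) abort("BED input needs at least 3 columns.")
  peaks <- tibble::tibble(
    chrom = as.character(tab[[1]]),
    start = as.numeric(tab[[2]]),
    end = as.numeric(tab[[3]])
  )
  bad <- which(!(peaks$start >= 0 & peaks$start < peaks$end))
  if (length(bad)) {
    abort(sprintf("Invalid interval (start >= end or start < 0) at line %d.",
                  bad[1]))
  }
  peaks$peak_id <- if (ncol(tab) >= 4) {
    as.character(tab[[4]])
  } else {
    sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  }
  if (ncol(tab) >= 5 && is.numeric(tab[[5]]) &&
      all(tab[[5]] >= 0 & tab[[5]] <= 1)) {
    peaks$gc <- as.numeric(tab[[5]])
  }
  dup <- peaks$peak_id[duplicated(peaks$peak_id)]
  if (length(dup)) {
    abort(sprintf("Duplicate peak_id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  peaks
}

#' Write peaks to BED
#'
#' @param peaks Tibble as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  cols <- c("chrom", "start", "end", "peak_id")
  if ("gc" %in% names(peaks)) cols <- c(cols, "gc")
  readr::write_tsv(peaks[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a Tn5 fragment file
#'
#' Standard scATAC fragment dialect: TSV(.gz) with columns chrom, start, end,
#' barcode and an optional duplicate-count column (defaults to 1 when absent).
#' Coordinates are 0-based half-open; each fragment contributes two Tn5
#' insertion events, at `start` and `end - 1`. Records are returned sorted by
#' (chrom, start).
#'
#' @param path Fragment TSV path, optionally gzip-compressed.
#' @return Tibble with columns `chrom`, `start`, `end`, `barcode`, `count`.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tab) < 4) abort("Fragment input needs at least 4 columns.")
  start <- suppressWarnings(as.numeric(tab[[2]]))
  end <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(start) || anyNA(end) || any(start != floor(start)) ||
      any(end != floor(end))) {
    abort("Non-integer fragment coordinates.")
  }
  count <- if (ncol(tab) >= 5) {
    cnt <- suppressWarnings(as.numeric(tab[[5]]))
    if (anyNA(cnt) || any(cnt < 1) || any(cnt != floor(cnt))) {
      abort("Fragment count column must hold positive integers.")
    }
    as.integer(cnt)
  } else {
    1L
  }
  frags <- tibble::tibble(
    chrom = as.character(tab[[1]]), start = start, end = end,
    barcode = as.character(tab[[4]]), count = count
  )
  if (any(frags$start >= frags$end)) abort("Fragment with start >= end.")
  dplyr::arrange(frags, .data$chrom, .data$start)
}

#' Write fragments as a sorted TSV
#'
#' @param fragments Tibble as returned by [read_fragments()].
#' @param path Output path (gzip when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  frags <- dplyr::arrange(fragments, .data$chrom, .data$start)
  readr::write_tsv(frags[, c("chrom", "start", "end", "barcode", "count")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Plain-text JASPAR PFM records: a `>ID name` header followed by four rows of
#' base counts in A, C, G, T order, with or without the `A [ ... ]` bracket
#' decoration.
#'
#' @param path PFM file path.
#' @param background Base frequencies (A, C, G, T) attached to each motif;
#'   must sum to 1.
#' @param pseudocount Positive pseudocount used when scoring.
#' @return A list of motif models (see [motif_model()]), named by motif name.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  headers <- grep("^>", lines)
  if (!length(headers) || headers[1] != 1) {
    abort("JASPAR input must start with a '>' header line.")
  }
  out <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    block <- lines[headers[i]:(bounds[i + 1] - 1L)]
    if (length(block) != 5) {
      abort(sprintf("Motif record %d does not have exactly 4 base rows.", i))
    }
    hdr <- strsplit(sub("^>\\s*", "", block[1]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) hdr[2] else hdr[1]
    rows <- lapply(block[2:5], function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("\\[|\\]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (anyNA(vals)) abort(sprintf("Non-numeric PFM row in motif %s.", id))
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1) {
      abort(sprintf("Motif %s has rows of unequal length (%s).",
                    id, paste(lens, collapse = ", ")))
    }
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    out[[name]] <- motif_model(name = name, pfm = pfm, tf_name = name,
                               background = background,
                               pseudocount = pseudocount, id = id)
  }
  out
}

#' Read a TSS table
#'
#' TSV with columns gene, chrom, tss, strand (header optional; detected from
#' the first line).
#'
#' @param path TSS table path.
#' @return Tibble with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  first <- readLines(path, n = 1)
  has_header <- grepl("gene", first, ignore.case = TRUE)
  tab <- readr::read_tsv(path, col_names = has_header == TRUE, progress = FALSE,
                         show_col_types = FALSE)
  if (!has_header) colnames(tab)[1:4] <- c("gene", "chrom", "tss", "strand")
  tibble::tibble(
    gene = as.character(tab$gene), chrom = as.character(tab$chrom),
    tss = as.numeric(tab$tss), strand = as.character(tab$strand)
  )
}
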