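#' Sample background peaks matched on GC and accessibility
#'
#' Bins peaks on a GC-content by mean-accessibility grid (quantile tiles,
#' default 10 x 10) and, for each peak, samples replacement peaks with
#' replacement from its own bin. Used both by motif deviation z-scores and by
#' peak-gene background models.
#'
#' @param gc Per-peak GC fraction.
#' @param accessibility Per-peak mean accessibility (e.g. column means of the
#'   count matrix).
#' @param n Number of background draws per peak.
#' @param bins Number of quantile tiles per dimension.
#' @param seed Integer seed.
#' @return An integer matrix (peaks by `n`) of peak indices.
#' @export
sample_background_peaks <- function(gc, accessibility, n = 50, bins = 10,
                                    seed = 1L) {
  if (length(gc) != length(accessibility)) {
    abort("`gc` and `accessibility` must have one value per peak.")
  }
  set.seed(seed)
  tile <- function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2) return(rep(1L, length(v)))
    findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  bin <- paste(tile(gc), tile(accessibility))
  out <- matrix(0L, length(gc), n)
  for (b in unique(bin)) {
    idx <- which(bin == b)
    out[idx, ] <- sample(idx, length(idx) * n, replace = TRUE)
  }
  out
}

#' Per-cell motif accessibility deviation z-scores
#'
#' For each motif m and cell i, the raw deviation is
#' `(obs_im - exp_im) / exp_im`, with `exp_im = d_i * sum_{j in m} p_j`,
#' where `p_j` is peak j's share of total counts and `d_i` is cell i's total.
#' Raw deviations are z-scored against `n_background` background peak sets
#' sampled within GC-by-accessibility bins (each motif peak replaced by a
#' binned lookalike), which calibrates out depth and composition effects.
#'
#' @param counts Cell-by-peak counts.
#' @param membership Peak-by-motif logical/binary matrix.
#' @param gc Per-peak GC fraction (defaults to a constant, i.e. accessibility
#'   only matching).
#' @param n_background Number of background sets.
#' @param bins Bins per matching dimension.
#' @param seed Integer seed for background sampling.
#' @param bg_peaks Optional precomputed matrix from
#'   [sample_background_peaks()] (peaks by at least `n_background` columns);
#'   overrides `seed`.
#' @return A list of class `phr_deviations`: `z` and `raw` (cells by motifs),
#'   `missing` (motifs with zero expected counts), `n_background`.
#' @export
chromvar_deviations <- function(counts, membership, gc = NULL,
                                n_background = 50, bins = 10, seed = 1L,
                                bg_peaks = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  membership <- Matrix::Matrix(membership + 0, sparse = TRUE)
  if (nrow(membership) != ncol(counts)) {
    abort("`membership` must have one row per peak (column of `counts`).")
  }
  if (any(Matrix::colSums(membership) == 0)) {
    abort("Every motif needs at least one member peak.")
  }
  total <- sum(counts)
  p <- Matrix::colSums(counts) / total
  d <- Matrix::rowSums(counts)
  if (is.null(bg_peaks)) {
    gc <- gc %||% rep(0.5, ncol(counts))
    bg_peaks <- sample_background_peaks(gc, p, n = n_background, bins = bins,
                                        seed = seed)
  }
  if (ncol(bg_peaks) < n_background) {
    abort("`bg_peaks` has fewer columns than `n_background`.")
  }
  dev_for <- function(memb) {
    expected <- outer(d, drop(Matrix::crossprod(memb, p)))
    obs <- as.matrix(counts %*% memb)
    ok <- colSums(expected) > 0 & apply(expected, 2, min) > 0
    raw <- matrix(NA_real_, nrow(obs), ncol(obs))
    raw[, ok] <- (obs[, ok, drop = FALSE] - expected[, ok, drop = FALSE]) /
      expected[, ok, drop = FALSE]
    raw
  }
  raw <- dev_for(membership)
  trip <- Matrix::summary(membership)
  s1 <- matrix(0, nrow(raw), ncol(raw))
  s2 <- matrix(0, nrow(raw), ncol(raw))
  for (b in seq_len(n_background)) {
    mb <- Matrix::sparseMatrix(i = bg_peaks[trip$i, b], j = trip$j, x = 1,
                               dims = dim(membership), use.last.ij = FALSE)
    rb <- dev_for(mb)
    s1 <- s1 + rb
    s2 <- s2 + rb^2
  }
  mean_b <- s1 / n_background
  sd_b <- sqrt(pmax(s2 / n_background - mean_b^2, 0) *
                 n_background / (n_background - 1))
  z <- (raw - mean_b) / sd_b
  z[!is.finite(z)] <- NA_real_
  missing <- colnames(membership)[colSums(is.na(raw)) == nrow(raw)]
  dimnames(z) <- dimnames(raw) <- list(rownames(counts), colnames(membership))
  structure(list(z = z, raw = raw, missing = missing,
                 n_background = n_background),
            class = "phr_deviations")
}

#' @export
#' @method print phr_deviations
print.phr_deviations <- function(x, ...) {
  cat(sprintf("<phr_deviations> %d cells x %d motifs (%d background sets)\n",
              nrow(x$z), ncol(x$z), x$n_background))
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Rank-correlation of ADT levels with motif deviation scores
#'
#' Pearson correlation of every ADT against every motif deviation z-score
#' across cells, ranked per ADT (descending r, ties broken by motif name).
#' The percentile of the canonical motif (the ADT's own binding motif) asks
#' whether the protein's abundance tracks its own motif's accessibility: high
#' percentiles are the signature of pioneer-like factors.
#'
#' @param adt_norm Cell-by-tag normalized ADT matrix.
#' @param deviations A `phr_deviations` or cell-by-motif z matrix.
#' @param canonical_map Named character vector ADT name -> motif name (may
#'   cover a subset of ADTs).
#' @return A list of class `phr_rankcorr`: `table` (adt, motif, r, rank,
#'   percentile), `canonical` (adt, motif, r, rank, percentile), `flagged`
#'   (zero-variance ADTs).
#' @export
adt_motif_rank_correlation <- function(adt_norm, deviations,
                                       canonical_map = NULL) {
  z <- if (inherits(deviations, "phr_deviations")) deviations$z else deviations
  if (nrow(adt_norm) != nrow(z)) abort("Cell index mismatch.")
  keep <- colSums(is.na(z)) == 0
  if (!all(keep)) {
    warn(sprintf("Dropping %d motif(s) with undefined deviations.",
                 sum(!keep)))
    z <- z[, keep, drop = FALSE]
  }
  sds <- apply(adt_norm, 2, sd)
  flagged <- colnames(adt_norm)[sds == 0]
  ok <- sds > 0
  r <- cor(adt_norm[, ok, drop = FALSE], z)
  tab <- tibble::as_tibble(as.table(r), .name_repair = "minimal")
  names(tab) <- c("adt", "motif", "r")
  n_motifs <- ncol(z)
  tab <- tab |>
    dplyr::group_by(.data$adt) |>
    dplyr::arrange(dplyr::desc(.data$r), .data$motif, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  percentile = 100 * (n_motifs - .data$rank + 1) / n_motifs) |>
    dplyr::ungroup()
  canonical <- NULL
  if (!is.null(canonical_map)) {
    canonical <- tibble::tibble(adt = names(canonical_map),
                                motif = unname(canonical_map)) |>
      dplyr::inner_join(tab, by = c("adt", "motif"))
  }
  structure(list(table = tab, canonical = canonical, flagged = flagged,
                 n_motifs = n_motifs),
            class = "phr_rankcorr")
}

#' @export
#' @method print phr_rankcorr
print.phr_rankcorr <- function(x, ...) {
  cat(sprintf("<phr_rankcorr> %d ADTs x %d motifs\n",
              length(unique(x$table$adt)), x$n_motifs))
  if (!is.null(x$canonical)) print(x$canonical)
  invisible(x)
}
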