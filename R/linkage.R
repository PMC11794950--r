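#' Adaptive ADT-to-peak correlation cutoff
#'
#' Pearson correlation of one ADT's normalized metacell aggregate against
#' every peak's normalized aggregate. The cutoff starts at `corr_start`
#' (0.5) and is decremented by `corr_step` (0.1) until strictly more than
#' `corr_min_frac` (1%) of peaks exceed it; the schedule floors at
#' `corr_step`, returning an empty candidate set with status
#' `"floor_reached"` if the fraction rule is never met.
#'
#' @param metacells A `phr_metacells`.
#' @param adt ADT (tag) name.
#' @param config A [pipeline_config()].
#' @return List of class `phr_adaptive`: `adt`, `cutoff`, `status` (`"ok"` or
#'   `"floor_reached"`), `candidates` (peak ids), `r` (named correlation
#'   vector).
#' @export
adaptive_peak_correlation <- function(metacells, adt,
                                      config = pipeline_config()) {
  if (nrow(metacells$norm$atac) < 3) abort("Need at least 3 metacells.")
  if (!adt %in% colnames(metacells$norm$adt)) {
    abort(sprintf("Unknown ADT: %s", adt))
  }
  r <- drop(cor(metacells$norm$adt[, adt], metacells$norm$atac))
  r[is.na(r)] <- 0
  names(r) <- colnames(metacells$norm$atac)
  sel <- adaptive_cutoff(r, config)
  structure(c(list(adt = adt, r = r), sel), class = "phr_adaptive")
}

# The decrement rule on a plain correlation vector (exposed for testing and
# reuse).
adaptive_cutoff <- function(r, config = pipeline_config()) {
  cutoff <- config$corr_start
  repeat {
    frac <- mean(r > cutoff)
    if (frac > config$corr_min_frac) {
      return(list(cutoff = cutoff, status = "ok",
                  candidates = names(r)[r > cutoff]))
    }
    if (cutoff - config$corr_step < config$corr_step - 1e-9) {
      return(list(cutoff = cutoff, status = "floor_reached",
                  candidates = character()))
    }
    cutoff <- cutoff - config$corr_step
  }
}

#' @export
#' @method print phr_adaptive
print.phr_adaptive <- function(x, ...) {
  cat(sprintf("<phr_adaptive> %s: cutoff %.2f (%s), %d candidate peaks\n",
              x$adt, x$cutoff, x$status, length(x$candidates)))
  invisible(x)
}

#' Filter candidate peaks for the canonical motif
#'
#' Keeps candidate peaks that harbor the ADT's binding motif (relative score
#' strictly above `config$motif_score_cutoff`). ADTs without a mapped motif
#' (e.g. phospho-tags acting through a partner TF) must be given an explicit
#' mapping.
#'
#' @param candidates Character vector of candidate peak ids.
#' @param hits A `phr_hits` from [scan_peaks()].
#' @param adt ADT name.
#' @param adt_map Named character vector ADT -> motif name.
#' @param config A [pipeline_config()].
#' @return Tibble of retained peaks: `peak_id`, `motif`, `motif_score` (best
#'   hit score per peak).
#' @export
motif_filter <- function(candidates, hits, adt, adt_map,
                         config = pipeline_config()) {
  if (!adt %in% names(adt_map) || is.na(adt_map[[adt]])) {
    abort(sprintf("No motif mapped for ADT %s; supply an explicit mapping.",
                  adt))
  }
  motif_name <- adt_map[[adt]]
  cutoff <- config$motif_score_cutoff
  if (hits$cutoff > cutoff) {
    abort("Motif hits were computed at a higher cutoff than requested.")
  }
  kept <- dplyr::filter(hits$hits, .data$motif == motif_name,
                        .data$score > cutoff, .data$peak_id %in% candidates)
  if (!nrow(kept)) {
    return(tibble::tibble(peak_id = character(), motif = character(),
                          motif_score = numeric()))
  }
  kept |>
    dplyr::group_by(.data$peak_id) |>
    dplyr::summarise(motif = motif_name, motif_score = max(.data$score),
                     .groups = "drop")
}

#' Link peaks to genes across metacells
#'
#' For each gene, candidate peaks have midpoints within `link_window` of the
#' TSS. The observed Pearson correlation (across metacells) between peak
#' accessibility and gene expression is z-scored against the correlations of
#' `n_background_peaks` GC/accessibility-matched background peaks with the
#' same gene (correlations are Fisher-transformed before z-scoring, and the
#' background spread is inflated by `sqrt(1 + 1/n)` so the null is
#' calibrated). Links with two-sided p below `link_p_cutoff` and `|r|` above
#' `link_score_cutoff` are retained.
#'
#' @param metacells A `phr_metacells` with an RNA aggregate.
#' @param peaks Peak tibble (`peak_id`, `start`, `end`, optional `gc`).
#' @param tss TSS tibble (`gene`, `chrom`, `tss`).
#' @param config A [pipeline_config()].
#' @param seed Seed for background sampling.
#' @return Tibble: `gene`, `peak_id`, `peak_gene_r`, `z`, `p`, `distance`.
#' @export
link_peaks_to_genes <- function(metacells, peaks, tss,
                                config = pipeline_config(), seed = 1L) {
  if (is.null(metacells$norm$rna)) abort("Metacells lack an RNA aggregate.")
  atac <- metacells$norm$atac
  rna <- metacells$norm$rna
  genes <- intersect(colnames(rna), tss$gene)
  skipped <- setdiff(colnames(rna), tss$gene)
  if (length(skipped)) {
    inform(sprintf("%d gene(s) without TSS skipped.", length(skipped)))
  }
  peaks <- peaks[match(colnames(atac), peaks$peak_id), ]
  mid <- (peaks$start + peaks$end) / 2
  gc <- peaks$gc %||% rep(0.5, nrow(peaks))
  access <- colMeans(atac)
  nbg <- config$n_background_peaks
  bg <- sample_background_peaks(gc, access, n = nbg, seed = seed)
  R <- cor(rna[, genes, drop = FALSE], atac)
  zclip <- function(r) atanh(pmin(pmax(r, -0.999999), 0.999999))
  tss_pos <- setNames(tss$tss, tss$gene)
  tss_chrom <- setNames(tss$chrom, tss$gene)
  out <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    cand <- which(peaks$chrom == tss_chrom[[g]] &
                    abs(mid - tss_pos[[g]]) <= config$link_window)
    if (!length(cand)) next
    rg <- R[gi, ]
    zr <- zclip(rg)
    bg_z <- matrix(zr[bg[cand, , drop = FALSE]], length(cand), nbg)
    mu <- rowMeans(bg_z)
    sdv <- apply(bg_z, 1, sd) * sqrt(1 + 1 / nbg)
    z <- (zr[cand] - mu) / sdv
    # studentized against an estimated background mean/sd: t reference with
    # n_background - 1 df keeps the null retention rate at its nominal level
    p <- 2 * stats::pt(-abs(z), df = nbg - 1)
    keep <- p < config$link_p_cutoff & abs(rg[cand]) > config$link_score_cutoff
    if (!any(keep)) next
    out[[gi]] <- tibble::tibble(
      gene = g, peak_id = peaks$peak_id[cand[keep]],
      peak_gene_r = unname(rg[cand[keep]]), z = unname(z[keep]),
      p = unname(p[keep]),
      distance = abs(mid[cand[keep]] - tss_pos[[g]])
    )
  }
  dplyr::bind_rows(out)
}

#' Classify ADT-peak-gene links as activating or repressive
#'
#' Joins the motif-filtered ADT candidate peaks with the peak-gene links and
#' classifies each row by the sign of the peak-gene correlation at the
#' +/- `gene_link_r` rule (0.2): rows whose correlation falls inside the band
#' are dropped.
#'
#' @param gene_links Tibble from [link_peaks_to_genes()].
#' @param adt_candidates Named list (by ADT) of tibbles from
#'   [motif_filter()], or a single tibble for one ADT.
#' @param adt_r Optional named list (by ADT) of peak correlation vectors from
#'   [adaptive_peak_correlation()] (`$r`), carried into the table.
#' @param cutoffs Optional named numeric vector of the adaptive cutoff used
#'   per ADT.
#' @param config A [pipeline_config()].
#' @return A `phr_links` object whose `table` has one row per
#'   (adt, peak, gene) link.
#' @export
classify_links <- function(gene_links, adt_candidates, adt_r = NULL,
                           cutoffs = NULL, config = pipeline_config()) {
  if (is.data.frame(adt_candidates)) {
    adt_candidates <- list(ADT = adt_candidates)
  }
  rows <- purrr::imap(adt_candidates, function(cand, adt) {
    if (!nrow(cand)) return(NULL)
    joined <- dplyr::inner_join(
      dplyr::mutate(cand, adt = adt), gene_links, by = "peak_id")
    if (!is.null(adt_r) && adt %in% names(adt_r)) {
      joined$peak_adt_r <- unname(adt_r[[adt]][joined$peak_id])
    } else {
      joined$peak_adt_r <- NA_real_
    }
    joined$cutoff_used <- if (!is.null(cutoffs)) cutoffs[[adt]] else NA_real_
    joined
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab)) {
    tab <- tab |>
      dplyr::mutate(class = dplyr::case_when(
        .data$peak_gene_r > config$gene_link_r ~ "activating",
        .data$peak_gene_r < -config$gene_link_r ~ "repressive",
        TRUE ~ NA_character_
      )) |>
      dplyr::filter(!is.na(.data$class)) |>
      dplyr::select("adt", "peak_id", "peak_adt_r", "motif", "motif_score",
                    "gene", "peak_gene_r", "z", "p", "class", "cutoff_used",
                    "distance")
  } else {
    tab <- tibble::tibble(
      adt = character(), peak_id = character(), peak_adt_r = numeric(),
      motif = character(), motif_score = numeric(), gene = character(),
      peak_gene_r = numeric(), z = numeric(), p = numeric(),
      class = character(), cutoff_used = numeric(), distance = numeric())
  }
  structure(list(table = tab, config = config), class = "phr_links")
}

#' @export
#' @method print phr_links
print.phr_links <- function(x, ...) {
  cat(sprintf("<phr_links> %d links, %d ADTs (%d activating, %d repressive)\n",
              nrow(x$table), length(unique(x$table$adt)),
              sum(x$table$class == "activating"),
              sum(x$table$class == "repressive")))
  invisible(x)
}

#' Run the full ADT-to-CRE-to-gene linkage pipeline
#'
#' QC filtering, ADT normalization (CLR + free-oligo regression), TF-IDF/LSI,
#' metacell aggregation, adaptive ADT-peak correlation, canonical-motif
#' filtering, peak-gene linking, and activating/repressive classification.
#'
#' @param dataset A `phr_dataset` with an RNA layer.
#' @param hits A `phr_hits` over the dataset's peaks.
#' @param adt_map Named character vector ADT -> motif name.
#' @param config A [pipeline_config()].
#' @param adts ADTs to process (default: all mapped ADTs present).
#' @return A `phr_links` whose `components` element keeps the intermediate
#'   objects (qc, lsi, metacells, per-ADT adaptive results).
#' @export
run_linkage <- function(dataset, hits, adt_map, config = pipeline_config(),
                        adts = NULL) {
  qc <- qc_filter(dataset, config)
  ds <- qc$dataset
  emb <- lsi(tfidf(ds$atac), n_components = min(30, nrow(ds$atac) - 1),
             counts_total = Matrix::rowSums(ds$atac), seed = config$seed)
  assignment <- compute_metacells(emb, target_size = config$metacell_size,
                                  seed = config$seed)
  mc <- aggregate_metacells(ds, assignment)
  adts <- adts %||% intersect(colnames(ds$adt), names(adt_map))
  adaptive <- purrr::map(setNames(adts, adts), adaptive_peak_correlation,
                         metacells = mc, config = config)
  candidates <- purrr::map(adaptive, function(a) {
    motif_filter(a$candidates, hits, a$adt, adt_map, config)
  })
  gene_links <- link_peaks_to_genes(mc, ds$peaks, ds$tss, config,
                                    seed = config$seed)
  links <- classify_links(
    gene_links, candidates,
    adt_r = purrr::map(adaptive, "r"),
    cutoffs = vapply(adaptive, `[[`, 0, "cutoff"),
    config = config
  )
  links$components <- list(qc = qc, lsi = emb, metacells = mc,
                           adaptive = adaptive, gene_links = gene_links)
  links
}

#' Gene-set module score
#'
#' Mean expression of a gene set minus the mean of control genes drawn from
#' matching average-expression bins (`n_ctrl` controls per gene from
#' `n_bins` bins), per cell. Deterministic given the seed.
#'
#' @param rna Cell-by-gene normalized expression matrix.
#' @param gene_set Character vector of genes; members absent from `rna` are
#'   dropped with a warning.
#' @param n_bins Number of average-expression bins.
#' @param n_ctrl Control genes sampled per gene-set member.
#' @param seed Integer seed.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(rna, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  rna <- as.matrix(rna)
  missing <- setdiff(gene_set, colnames(rna))
  if (length(missing)) {
    warn(sprintf("%d gene(s) not in the expression matrix dropped.",
                 length(missing)))
  }
  gene_set <- unique(intersect(gene_set, colnames(rna)))
  if (!length(gene_set)) abort("Empty gene set after filtering.")
  set.seed(seed)
  avg <- colMeans(rna)
  br <- unique(quantile(avg, seq(0, 1, length.out = n_bins + 1)))
  bin <- findInterval(avg, br, rightmost.closed = TRUE, all.inside = TRUE)
  names(bin) <- colnames(rna)
  ctrl <- unlist(lapply(sort(gene_set), function(g) {
    pool <- names(bin)[bin == bin[[g]]]
    sample(pool, n_ctrl, replace = TRUE)
  }))
  score <- rowMeans(rna[, gene_set, drop = FALSE]) -
    rowMeans(rna[, ctrl, drop = FALSE])
  setNames(score, rownames(rna))
}
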