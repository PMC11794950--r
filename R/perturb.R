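# Vectorized two-sided Wilcoxon rank-sum p-values per column (normal
# approximation with tie correction and continuity correction, as in
# wilcox.test for large samples).
wilcox_by_column <- function(x, group1) {
  n1 <- sum(group1)
  n2 <- nrow(x) - n1
  apply(x, 2, function(v) {
    r <- rank(v)
    w <- sum(r[group1]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) return(1)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  })
}

#' Differential accessibility between genotypes
#'
#' Two-sided Wilcoxon rank-sum test on TF-IDF-normalized accessibility per
#' peak between wild-type and knockout cells, restricted to peaks detected
#' in at least `min_pct` of cells in either group, with Benjamini-Hochberg
#' adjustment. A peak is flagged DAR when its adjusted p is below `alpha`.
#'
#' @param dataset A combined `phr_dataset` whose `cell_meta$genotype` holds
#'   two groups, or a list with `atac` counts and `genotype`.
#' @param peak_universe Optional peak ids to restrict the test to (e.g. a
#'   bound-site universe from CUT&Tag-like data).
#' @param min_pct Minimum detection fraction in either group.
#' @param alpha Adjusted-p level for the DAR flag.
#' @param groups Optional length-2 character giving the genotype order
#'   (first = "case" whose higher accessibility gives positive log2 FC).
#' @return A tibble of class `phr_dar`: `peak_id`, `statistic_p` columns
#'   (`p`, `p_adj`), `log2_fc`, `pct_1`, `pct_2`, `dar`.
#' @export
differential_accessibility <- function(dataset, peak_universe = NULL,
                                       min_pct = 0.05, alpha = 0.05,
                                       groups = NULL) {
  if (inherits(dataset, "phr_dataset")) {
    genotype <- dataset$cell_meta$genotype
    counts <- dataset$atac
  } else {
    genotype <- dataset$genotype
    counts <- dataset$atac
  }
  if (is.null(genotype)) abort("No `genotype` in the cell metadata.")
  groups <- groups %||% sort(unique(genotype), decreasing = TRUE)
  if (length(unique(genotype)) != 2) abort("Need exactly two genotypes.")
  if (min(table(genotype)) < 3) abort("A genotype has fewer than 3 cells.")
  if (!is.null(peak_universe)) {
    counts <- counts[, colnames(counts) %in% peak_universe, drop = FALSE]
  }
  g1 <- genotype == groups[1]
  pct1 <- Matrix::colMeans(counts[g1, , drop = FALSE] > 0)
  pct2 <- Matrix::colMeans(counts[!g1, , drop = FALSE] > 0)
  tested <- pmax(pct1, pct2) >= min_pct
  norm <- as.matrix(tfidf(counts[, tested, drop = FALSE]))
  p <- wilcox_by_column(norm, g1)
  m1 <- colMeans(norm[g1, , drop = FALSE])
  m2 <- colMeans(norm[!g1, , drop = FALSE])
  eps <- 1e-6
  out <- tibble::tibble(
    peak_id = colnames(counts)[tested],
    p = unname(p),
    p_adj = p.adjust(p, method = "BH"),
    log2_fc = log2((m1 + eps) / (m2 + eps)),
    pct_1 = unname(pct1[tested]),
    pct_2 = unname(pct2[tested])
  )
  out$dar <- out$p_adj < alpha
  class(out) <- c("phr_dar", class(out))
  attr(out, "groups") <- groups
  attr(out, "n_excluded") <- sum(!tested)
  out
}

#' Motif enrichment in a peak set against matched background
#'
#' Compares motif membership frequency in a query peak set against a
#' GC/accessibility-matched background sampled from the rest of the
#' universe. Fold enrichment is query frequency over background frequency;
#' the p-value is the hypergeometric upper tail on membership counts among
#' query vs background peaks.
#'
#' @param query Peak ids of interest (e.g. DARs); must lie in `universe`.
#' @param universe Peak ids of the full universe.
#' @param hits A `phr_hits` covering the universe.
#' @param gc,accessibility Optional per-peak matching covariates named by
#'   peak id; when omitted the background is an unmatched uniform sample.
#' @param n_background Background sample size (default `10 * length(query)`,
#'   capped at the available pool).
#' @param seed Integer seed.
#' @return Tibble: `motif`, `freq_query`, `freq_background`,
#'   `fold_enrichment`, `p`.
#' @export
motif_enrichment <- function(query, universe, hits, gc = NULL,
                             accessibility = NULL, n_background = NULL,
                             seed = 1L) {
  if (!length(query)) abort("`query` must not be empty.")
  if (!all(query %in% universe)) abort("`query` must be a subset of `universe`.")
  pool <- setdiff(universe, query)
  if (!length(pool)) abort("No background peaks left in the universe.")
  n_background <- min(n_background %||% (10 * length(query)), length(pool))
  set.seed(seed)
  if (!is.null(gc) || !is.null(accessibility)) {
    gcv <- gc %||% setNames(rep(0.5, length(universe)), universe)
    acv <- accessibility %||% setNames(rep(1, length(universe)), universe)
    tile <- function(v) {
      br <- unique(quantile(v, seq(0, 1, length.out = 11)))
      if (length(br) < 2) return(rep(1L, length(v)))
      findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
    }
    bin <- setNames(paste(tile(gcv[universe]), tile(acv[universe])), universe)
    per <- ceiling(n_background / length(query))
    bg <- unique(unlist(lapply(query, function(q) {
      cand <- pool[bin[pool] == bin[[q]]]
      if (!length(cand)) cand <- pool
      sample(cand, per, replace = TRUE)
    })))
  } else {
    bg <- sample(pool, n_background)
  }
  memb <- hits$membership
  motifs <- colnames(memb)
  qi <- match(query, rownames(memb))
  bi <- match(bg, rownames(memb))
  if (anyNA(qi) || anyNA(bi)) abort("Peaks missing from the hit membership.")
  kq <- Matrix::colSums(memb[qi, , drop = FALSE])
  kb <- Matrix::colSums(memb[bi, , drop = FALSE])
  nq <- length(qi)
  nb <- length(bi)
  fq <- kq / nq
  fb <- kb / nb
  tibble::tibble(
    motif = motifs,
    freq_query = unname(fq),
    freq_background = unname(fb),
    fold_enrichment = unname(fq / fb),
    p = unname(phyper(kq - 1, kq + kb, nq + nb - kq - kb, nq,
                      lower.tail = FALSE))
  )
}

#' Concordance of differential accessibility with ADT correlation
#'
#' Welch two-sided t-test comparing the ADT-peak correlation values of DAR
#' versus non-DAR peaks: if protein-accessibility correlations in the
#' unperturbed data predict which bound sites respond to the knockout, the
#' DAR group mean is higher.
#'
#' @param dar_table A `phr_dar` tibble.
#' @param adt_cor Named numeric vector of per-peak ADT correlations.
#' @return One-row tibble: `statistic`, `p`, `mean_dar`, `mean_nondar`,
#'   `n_dar`, `n_nondar`.
#' @export
dar_concordance <- function(dar_table, adt_cor) {
  r <- adt_cor[dar_table$peak_id]
  a <- r[dar_table$dar]
  b <- r[!dar_table$dar]
  if (length(a) < 2 || length(b) < 2) {
    abort("Both DAR and non-DAR groups need at least 2 peaks.")
  }
  tt <- t.test(a, b)
  tibble::tibble(
    statistic = unname(tt$statistic), p = tt$p.value,
    mean_dar = mean(a), mean_nondar = mean(b),
    n_dar = length(a), n_nondar = length(b)
  )
}
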