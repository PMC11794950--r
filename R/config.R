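#' Pipeline configuration
#'
#' Bundles every tunable threshold of the linkage pipeline with the defaults
#' used throughout: 75 cells per metacell, a 500 kb peak-gene window, the
#' adaptive ADT-peak correlation schedule (start 0.5, step 0.1, stop once more
#' than 1% of peaks pass), a motif relative-score cutoff of 400 (on the 0-1000
#' min-max scale), peak-gene link cutoffs (p < 0.10, |r| > 0.01), the +/-0.2
#' activating/repressive gene-correlation rule, ten ADT quantiles, and the QC
#' bounds (cells with more than 10,000 ADT counts removed; 100-10,000 RNA UMIs;
#' 1,000-100,000 peak counts).
#'
#' @param metacell_size Target number of cells per metacell.
#' @param link_window Maximum TSS-to-peak-midpoint distance (bp) for peak-gene
#'   links.
#' @param corr_start,corr_step Starting value and decrement of the adaptive
#'   ADT-peak correlation cutoff.
#' @param corr_min_frac Fraction of peaks that must exceed the cutoff before
#'   the decrement stops (strict `>`).
#' @param motif_score_cutoff Minimum PWM relative score (0-1000 scale, strict
#'   `>`) for a motif hit.
#' @param link_p_cutoff,link_score_cutoff Peak-gene link retention cutoffs:
#'   background-z p-value (strict `<`) and absolute correlation (strict `>`).
#' @param gene_link_r Absolute peak-gene correlation above which a link is
#'   classified activating (r > gene_link_r) or repressive (r < -gene_link_r).
#' @param n_quantiles Number of ADT quantile bins for footprinting/coverage.
#' @param adt_count_max Cells with total ADT counts strictly above this are
#'   removed by QC.
#' @param rna_umi_bounds Length-2 numeric: cells outside (low, high) total RNA
#'   UMIs are removed when the RNA layer is present.
#' @param peak_count_bounds Length-2 numeric: cells outside (low, high) total
#'   peak counts are removed.
#' @param n_background_peaks Matched background peaks per peak for the
#'   peak-gene background z-score.
#' @param n_background_sets Background peak-set iterations for motif deviation
#'   z-scores.
#' @param seed Integer seed used by seeded pipeline stages.
#'
#' @return A list of class `phr_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$link_window
pipeline_config <- function(metacell_size = 75,
                            link_window = 500000,
                            corr_start = 0.5,
                            corr_step = 0.1,
                            corr_min_frac = 0.01,
                            motif_score_cutoff = 400,
                            link_p_cutoff = 0.10,
                            link_score_cutoff = 0.01,
                            gene_link_r = 0.2,
                            n_quantiles = 10,
                            adt_count_max = 10000,
                            rna_umi_bounds = c(100, 10000),
                            peak_count_bounds = c(1000, 100000),
                            n_background_peaks = 200,
                            n_background_sets = 50,
                            seed = 1L) {
  cfg <- list(
    metacell_size = metacell_size, link_window = link_window,
    corr_start = corr_start, corr_step = corr_step,
    corr_min_frac = corr_min_frac, motif_score_cutoff = motif_score_cutoff,
    link_p_cutoff = link_p_cutoff, link_score_cutoff = link_score_cutoff,
    gene_link_r = gene_link_r, n_quantiles = n_quantiles,
    adt_count_max = adt_count_max, rna_umi_bounds = rna_umi_bounds,
    peak_count_bounds = peak_count_bounds,
    n_background_peaks = n_background_peaks,
    n_background_sets = n_background_sets,
    seed = as.integer(seed)
  )
  scalars <- c(
    "metacell_size", "link_window", "corr_start", "corr_step",
    "corr_min_frac", "motif_score_cutoff", "link_p_cutoff",
    "link_score_cutoff", "gene_link_r", "n_quantiles", "adt_count_max",
    "n_background_peaks", "n_background_sets"
  )
  for (nm in scalars) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm))
    }
  }
  if (cfg$corr_start < cfg$corr_step) {
    abort("`corr_start` must be >= `corr_step`.")
  }
  for (nm in c("rna_umi_bounds", "peak_count_bounds")) {
    b <- cfg[[nm]]
    if (length(b) != 2 || any(b <= 0) || b[1] >= b[2]) {
      abort(sprintf("`%s` must be an increasing positive pair.", nm))
    }
  }
  structure(cfg, class = "phr_config")
}

#' @export
#' @method print phr_config
print.phr_config <- function(x, ...) {
  cat("<phr_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
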