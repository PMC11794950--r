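#' Simulation configuration
#'
#' Parameters of the synthetic trimodal generator. The defaults define the
#' desk-scale study conditions used throughout the tests: 2,000 cells, 5,000
#' peaks, 500 genes, 5 TFs over 8 cell types, per-cell depths emulating the
#' sparse regime of real data (median tens of ADT UMIs, free-oligo spike-in,
#' negative-binomial overdispersion everywhere), one synthetic AT-rich
#' chromosome, and a cofactor-gated (AND-logic) regulatory architecture for
#' the last TF pair so knockout analyses have a planted answer.
#'
#' @param n_cells,n_peaks,n_genes,n_tfs,n_types Core dimensions.
#' @param peak_width Width of every peak (bp).
#' @param genome_length Length of the single synthetic chromosome; `NULL`
#'   derives a length that keeps regulatory modules more than `link_window`
#'   apart.
#' @param modules_per_tf,peaks_per_module,genes_per_module Regulatory module
#'   geometry: each module wires `peaks_per_module` enhancer peaks of one TF
#'   to `genes_per_module` nearby genes.
#' @param module_span Genomic span (bp) containing one module's peaks and
#'   gene TSSs.
#' @param mean_fragments,mean_adt_umis,mean_rna_umis Mean per-cell depths.
#' @param depth_sdlog Log-sd of per-cell depth factors.
#' @param nb_size_atac,nb_size_adt,nb_size_rna,nb_size_free Negative-binomial
#'   size (inverse overdispersion); `Inf` gives the Poisson limit.
#' @param n_control_adts Additional ADT tags without a TF behind them (pure
#'   nonspecific background); real panels carry dozens of tags, and a larger
#'   panel also stabilizes the compositional CLR.
#' @param background_adt_frac Fraction of a cell's expected ADT counts that is
#'   nonspecific background (driven by the permeabilization factor).
#' @param free_oligo_mean Mean free-oligo count at permeabilization factor 1.
#' @param perm_sdlog Log-sd of the per-cell permeabilization factor.
#' @param perm_gamma Range of per-tag sensitivity exponents on the
#'   permeabilization factor: tag backgrounds scale as `perm^gamma_j` with
#'   `gamma_j` spread evenly over this range (antibodies differ in how
#'   strongly permeabilization and stickiness affect them, which is what
#'   makes the nonspecific component survive the compositional CLR).
#' @param active_level,inactive_level,activity_cv TF protein abundance in
#'   active vs inactive cell types and its lognormal noise.
#' @param trajectory_effect Optional log-scale modulation of activity along a
#'   latent per-cell trajectory coordinate (0 disables).
#' @param binding_threshold Activity above which a TF is considered bound at
#'   its sites (drives footprints and AND-gates).
#' @param footprint_depth Fractional depletion of Tn5 insertion probability
#'   over bound motif cores, in [0, 1).
#' @param motif_length Motif length (bp). Motif consensus letters are C/G so
#'   that, against the AT-rich genome, the permissive 400 relative-score
#'   cutoff still separates planted sites from background sequence.
#' @param site_matches Number of consensus-matching positions in a planted
#'   motif instance (the rest is A/T filler). Must exceed 40% of
#'   `motif_length` so the instance scores above the 400 cutoff; keeping it
#'   well below `motif_length` makes instances of one motif invisible to
#'   every other motif.
#' @param n_decoy_motifs Motifs without TF activity; each still gets
#'   `n_decoy_sites` planted instances in random background peaks.
#' @param n_decoy_sites Planted instances per decoy motif.
#' @param base_probs Background base composition of the synthetic genome
#'   (named A/C/G/T, summing to 1).
#' @param n_bound_extra Extra "bound but inert" peaks assigned to the primary
#'   TF's binding universe (CUT&Tag-like: bound without accessibility
#'   effects).
#' @param bound_motif_frac,bound_cofactor_frac Fractions of inert bound peaks
#'   carrying the primary and cofactor motif.
#' @param p_activating Probability that a wired gene is activated (rest are
#'   repressed) by its module's peaks.
#' @param baseline_logit_mean,baseline_logit_sd,wired_baseline Peak baseline
#'   accessibility logits (background peaks are drawn; wired peaks start
#'   closed).
#' @param effect_range Uniform range of TF-on-peak logit effects (per unit
#'   activity).
#' @param seed Integer master seed; every simulation stage derives its stream
#'   from it, so equal seeds give identical outputs.
#' @return A list of class `phr_sim_config`.
#' @export
sim_config <- function(n_cells = 2000, n_peaks = 5000, n_genes = 500,
                       n_tfs = 5, n_types = 8,
                       peak_width = 600, genome_length = NULL,
                       modules_per_tf = 20, peaks_per_module = 3,
                       genes_per_module = 2, module_span = 1e5,
                       n_control_adts = 15,
                       mean_fragments = 1500, mean_adt_umis = 60,
                       mean_rna_umis = 600, depth_sdlog = 0.35,
                       nb_size_atac = 8, nb_size_adt = 6,
                       nb_size_rna = 2, nb_size_free = 100,
                       background_adt_frac = 0.65, free_oligo_mean = 100,
                       perm_sdlog = 0.7, perm_gamma = c(0.3, 1.7),
                       active_level = 3, inactive_level = 0.02,
                       activity_cv = 0.35, trajectory_effect = 0,
                       binding_threshold = 1, footprint_depth = 0.6,
                       motif_length = 40, site_matches = 18,
                       n_decoy_motifs = 15, n_decoy_sites = 60,
                       base_probs = c(A = 0.42, C = 0.08, G = 0.08, T = 0.42),
                       n_bound_extra = 300, bound_motif_frac = 0.4,
                       bound_cofactor_frac = 0.15,
                       p_activating = 0.7,
                       baseline_logit_mean = -2.5, baseline_logit_sd = 0.6,
                       wired_baseline = -3.5,
                       effect_range = c(1.3, 2),
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  for (nm in c("n_cells", "n_peaks", "n_genes", "n_tfs", "n_types",
               "peak_width", "mean_fragments", "mean_adt_umis",
               "mean_rna_umis")) {
    if (cfg[[nm]] <= 0) abort(sprintf("`%s` must be positive.", nm))
  }
  for (nm in c("nb_size_atac", "nb_size_adt", "nb_size_rna", "nb_size_free")) {
    if (cfg[[nm]] <= 0) abort(sprintf("`%s` must be > 0.", nm))
  }
  if (footprint_depth < 0 || footprint_depth >= 1) {
    abort("`footprint_depth` must lie in [0, 1).")
  }
  if (abs(sum(base_probs) - 1) > 1e-9 || length(base_probs) != 4) {
    abort("`base_probs` must be 4 frequencies summing to 1.")
  }
  n_wired <- n_tfs * modules_per_tf * peaks_per_module
  if (n_wired > n_peaks) {
    abort(sprintf("%d wired peaks exceed n_peaks = %d.", n_wired, n_peaks))
  }
  if (n_tfs * modules_per_tf * genes_per_module > n_genes) {
    abort("Wired genes exceed `n_genes`.")
  }
  if (site_matches > motif_length || site_matches <= 0.4 * motif_length) {
    abort("`site_matches` must lie in (0.4 * motif_length, motif_length].")
  }
  structure(cfg, class = "phr_sim_config")
}

# ---- motif library construction ---------------------------------------------

# Build the motif library: one C/G-consensus motif per TF plus decoys. With
# the AT-rich genome background, consensus letters are rare outside planted
# sites, so relative scores above 400 essentially never arise by chance; and
# because planted instances are degenerate (see peak_sequences), sites of one
# motif do not score above 400 for any other motif.
build_motif_library <- function(cfg, tf_names) {
  L <- cfg$motif_length
  make_motif <- function(string, name, tf) {
    pfm <- matrix(4, 4, L, dimnames = list(DNA_BASES, NULL))
    pfm[cbind(string, seq_len(L))] <- 88
    motif_model(name, pfm, tf_name = tf)
  }
  motifs <- list()
  for (t in seq_along(tf_names)) {
    nm <- sprintf("M%03d_%s", t, tf_names[t])
    motifs[[nm]] <- make_motif(sample(c(2L, 3L), L, replace = TRUE), nm,
                               tf_names[t])
  }
  for (d in seq_len(cfg$n_decoy_motifs)) {
    nm <- sprintf("M%03d_DCY%02d", length(tf_names) + d, d)
    motifs[[nm]] <- make_motif(sample(c(2L, 3L), L, replace = TRUE), nm,
                               NA_character_)
  }
  motifs
}

# ---- ground truth ------------------------------------------------------------

# Active-type subsets: small pairwise overlap keeps TF activities nearly
# orthogonal across cell types; the primary/cofactor pair is forced to share
# one type (the AND-gate context).
choose_active_sets <- function(n_tfs, n_types, k) {
  sets <- list()
  for (t in seq_len(n_tfs)) {
    best <- NULL
    best_ov <- Inf
    for (try in 1:300) {
      cand <- sort(sample.int(n_types, k))
      ov <- if (!length(sets)) {
        0L
      } else {
        max(vapply(sets, function(s) length(intersect(s, cand)), 1L))
      }
      if (ov < best_ov) {
        best_ov <- ov
        best <- cand
      }
      if (ov <= 1) break
    }
    sets[[t]] <- best
  }
  if (n_tfs >= 2) {
    # the primary (cofactor-gated) TF is restricted to a smaller domain: one
    # type shared with the cofactor (where the AND-gate fires) plus at most
    # one type of its own
    p <- n_tfs - 1L
    co <- n_tfs
    shared <- sets[[co]][1]
    others <- setdiff(seq_len(n_types), unlist(sets[c(co)]))
    own <- if (length(others)) sample(others, 1) else shared
    sets[[p]] <- sort(unique(c(shared, own)))
  }
  sets
}

#' Generate the planted ground truth
#'
#' Lays out a single synthetic chromosome with per-TF regulatory modules
#' (enhancer peaks wired to nearby genes, all within the 500 kb link window),
#' draws cell types, TF protein activities (cell-type structured), and
#' per-cell permeabilization factors, builds the motif library with planted
#' consensus sites in wired peaks, and records the TF-to-peak-to-gene edge
#' set used as the recovery oracle. When at least two TFs are present, the
#' last TF acts as a pioneer cofactor that gates the (second-to-last)
#' primary TF's peaks: those peaks open only where both are active, the
#' architecture probed by knockout experiments.
#'
#' @param config A [sim_config()].
#' @return A list of class `phr_truth`.
#' @export
generate_truth <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n_tfs <- cfg$n_tfs
  tf_names <- paste0("TF", seq_len(n_tfs))
  primary <- if (n_tfs >= 2) tf_names[n_tfs - 1L] else NA_character_
  cofactor <- if (n_tfs >= 2) tf_names[n_tfs] else NA_character_

  # genome geometry; modules are spaced so that no gene outside a module can
  # fall within the 500 kb link window of another module's peaks, keeping the
  # planted TF->peak->gene edge set unambiguous under the distance rule
  link_window <- 500000
  n_modules <- n_tfs * cfg$modules_per_tf
  if (is.null(cfg$genome_length)) {
    pitch <- cfg$module_span + 2 * link_window + 200000
    cfg$genome_length <- n_modules * pitch
  }
  pitch <- floor(cfg$genome_length / n_modules)
  span <- min(cfg$module_span, floor(pitch / 3))
  min_span <- (cfg$peaks_per_module + 1) * (cfg$peak_width + 10)
  if (span < min_span) {
    abort("Infeasible geometry: peaks cannot fit in the genome length.")
  }

  # modules: interleave TFs along the chromosome
  module_tf <- rep(tf_names, length.out = n_modules)
  module_start <- (seq_len(n_modules) - 1L) * pitch +
    floor((pitch - span) / 2)

  slots_per_module <- floor(span / cfg$peak_width) - 1L
  wired <- purrr::map_dfr(seq_len(n_modules), function(m) {
    at <- sort(sample.int(slots_per_module, cfg$peaks_per_module))
    tibble::tibble(
      chrom = "chrS",
      start = module_start[m] + (at - 1L) * cfg$peak_width,
      end = module_start[m] + at * cfg$peak_width,
      role = "enhancer", module = m, tf = module_tf[m]
    )
  })

  # background peaks on a global grid, away from module regions
  n_bg <- cfg$n_peaks - nrow(wired)
  slot_w <- cfg$peak_width + 200
  slots <- seq(0, cfg$genome_length - slot_w, by = slot_w)
  in_module <- rep(FALSE, length(slots))
  for (m in seq_len(n_modules)) {
    in_module <- in_module |
      (slots + slot_w > module_start[m] - cfg$peak_width &
         slots < module_start[m] + span + cfg$peak_width)
  }
  free_slots <- slots[!in_module]
  if (length(free_slots) < n_bg) {
    abort("Infeasible geometry: peaks cannot fit in the genome length.")
  }
  bg_start <- sort(sample(free_slots, n_bg))
  background <- tibble::tibble(
    chrom = "chrS", start = bg_start, end = bg_start + cfg$peak_width,
    role = "background", module = NA_integer_, tf = NA_character_
  )

  peaks <- dplyr::arrange(dplyr::bind_rows(wired, background), .data$start)
  peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  peaks$baseline <- ifelse(
    peaks$role == "enhancer", cfg$wired_baseline,
    rnorm(nrow(peaks), cfg$baseline_logit_mean, cfg$baseline_logit_sd)
  )

  # TF -> peak effect edges; the primary TF's peaks are AND-gated
  enh <- peaks[peaks$role == "enhancer", ]
  peak_edges <- tibble::tibble(
    peak_id = enh$peak_id, tf = enh$tf,
    effect = runif(nrow(enh), cfg$effect_range[1], cfg$effect_range[2]),
    gate_tf = ifelse(!is.na(primary) & enh$tf == primary, cofactor,
                     NA_character_)
  )
  cofactor_rules <- peak_edges[!is.na(peak_edges$gate_tf),
                               c("peak_id", "tf", "gate_tf")]

  # motif library and planted sites
  motifs <- build_motif_library(cfg, tf_names)
  adt_map <- setNames(names(motifs)[seq_len(n_tfs)], tf_names)
  L <- cfg$motif_length
  center_off <- function(n, width) {
    jitter <- sample(seq(-40, 40), n, replace = TRUE)
    pmin(pmax(floor(width / 2 - L / 2) + jitter, 0L), width - L)
  }
  site_strand <- function(n) sample(c("+", "-"), n, replace = TRUE)
  width <- cfg$peak_width
  sites <- tibble::tibble(
    peak_id = enh$peak_id, motif = unname(adt_map[enh$tf]), tf = enh$tf,
    offset = center_off(nrow(enh), width), strand = site_strand(nrow(enh)),
    functional = TRUE
  )
  # gated peaks also carry (and are footprinted by) the cofactor motif
  gated <- enh[enh$tf %in% primary, ]
  if (nrow(gated)) {
    side <- sample(c(-1, 1), nrow(gated), replace = TRUE)
    off <- pmin(pmax(floor(width / 2 - L / 2) + side *
                       sample(90:160, nrow(gated), replace = TRUE), 0L),
                width - L)
    sites <- dplyr::bind_rows(sites, tibble::tibble(
      peak_id = gated$peak_id, motif = unname(adt_map[cofactor]),
      tf = cofactor, offset = off, strand = site_strand(nrow(gated)),
      functional = TRUE
    ))
  }

  # bound-but-inert universe for the primary TF (binding without effect)
  bound <- NULL
  if (!is.na(primary)) {
    bg_ids <- peaks$peak_id[peaks$role == "background"]
    inert <- sample(bg_ids, min(cfg$n_bound_extra, length(bg_ids)))
    bound <- tibble::tibble(tf = primary,
                            peak_id = c(peak_edges$peak_id[peak_edges$tf ==
                                                             primary], inert))
    plant <- function(ids, motif, tf) {
      if (!length(ids)) return(NULL)
      tibble::tibble(peak_id = ids, motif = motif, tf = tf,
                     offset = sample.int(width - L, length(ids)),
                     strand = site_strand(length(ids)), functional = FALSE)
    }
    n_inert <- length(inert)
    sites <- dplyr::bind_rows(
      sites,
      plant(sample(inert, round(cfg$bound_motif_frac * n_inert)),
            unname(adt_map[primary]), primary),
      plant(sample(inert, round(cfg$bound_cofactor_frac * n_inert)),
            unname(adt_map[cofactor]), cofactor)
    )
  }

  # decoy motifs occur in random background peaks (no activity behind them)
  bg_pool <- peaks$peak_id[peaks$role == "background"]
  decoy_names <- setdiff(names(motifs), adt_map)
  for (dn in decoy_names) {
    ids <- sample(bg_pool, min(cfg$n_decoy_sites, length(bg_pool)))
    sites <- dplyr::bind_rows(sites, tibble::tibble(
      peak_id = ids, motif = dn, tf = NA_character_,
      offset = sample.int(width - L, length(ids), replace = TRUE),
      strand = site_strand(length(ids)), functional = FALSE
    ))
  }

  # genes: wired per module, the rest background
  n_wired_genes <- n_modules * cfg$genes_per_module
  gene_module <- rep(seq_len(n_modules), each = cfg$genes_per_module)
  wired_tss <- module_start[gene_module] +
    sample.int(span, n_wired_genes, replace = TRUE)
  # background genes: preferably farther than the link window from any
  # module, falling back to merely outside modules on cramped genomes
  n_bg_genes <- cfg$n_genes - n_wired_genes
  sample_tss <- function(margin, n_draw) {
    cand <- sample.int(cfg$genome_length, n_draw)
    mod_of <- findInterval(cand, module_start - margin)
    inside <- mod_of >= 1 &
      cand <= (module_start[pmax(mod_of, 1)] + span + margin)
    cand[!inside]
  }
  bg_tss <- numeric(0)
  for (margin in c(link_window + 2 * cfg$peak_width, 0)) {
    for (i in 1:20) {
      if (length(bg_tss) >= n_bg_genes) break
      bg_tss <- c(bg_tss, sample_tss(margin, n_bg_genes * 4))
    }
    if (length(bg_tss) >= n_bg_genes) break
  }
  if (length(bg_tss) < n_bg_genes) {
    bg_tss <- c(bg_tss, sample.int(cfg$genome_length,
                                   n_bg_genes - length(bg_tss)))
  }
  bg_tss <- sort(bg_tss[seq_len(n_bg_genes)])
  genes <- tibble::tibble(
    gene = sprintf("gene%04d", seq_len(cfg$n_genes)),
    chrom = "chrS",
    tss = c(wired_tss, bg_tss),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    module = c(gene_module, rep(NA_integer_, n_bg_genes)),
    sign = c(ifelse(runif(n_wired_genes) < cfg$p_activating, 1L, -1L),
             rep(NA_integer_, n_bg_genes))
  )
  genes$baseline <- ifelse(
    is.na(genes$sign), exp(rnorm(cfg$n_genes, 0, 0.5)),
    ifelse(genes$sign > 0, runif(cfg$n_genes, 0.2, 0.5),
           runif(cfg$n_genes, 2.5, 4))
  )
  gene_edges <- genes[!is.na(genes$module), ] |>
    dplyr::select("gene", "module", "sign") |>
    dplyr::inner_join(
      dplyr::select(dplyr::filter(peaks, .data$role == "enhancer"),
                    "peak_id", "module"),
      by = "module", relationship = "many-to-many"
    ) |>
    dplyr::mutate(effect = ifelse(.data$sign > 0,
                                  runif(dplyr::n(), 0.8, 1.4),
                                  runif(dplyr::n(), 0.6, 1.0)))

  # recovery oracle: module TF edges, plus the cofactor on gated peaks
  truth_links <- gene_edges |>
    dplyr::inner_join(dplyr::select(peak_edges, "peak_id", "tf", "gate_tf"),
                      by = "peak_id") |>
    dplyr::select("tf", "peak_id", "gene", "sign", "gate_tf")
  gated_links <- truth_links[!is.na(truth_links$gate_tf), ]
  if (nrow(gated_links)) {
    gated_links$tf <- gated_links$gate_tf
    truth_links <- dplyr::bind_rows(truth_links, gated_links)
  }
  truth_links$gate_tf <- NULL

  # cells
  k <- max(1L, min(3L, cfg$n_types %/% 2L))
  active_sets <- choose_active_sets(n_tfs, cfg$n_types, k)
  cell_type <- sample.int(cfg$n_types, cfg$n_cells, replace = TRUE)
  tau <- runif(cfg$n_cells)
  perm <- exp(rnorm(cfg$n_cells, -cfg$perm_sdlog^2 / 2, cfg$perm_sdlog))
  act <- matrix(0, cfg$n_cells, n_tfs, dimnames = list(NULL, tf_names))
  for (t in seq_len(n_tfs)) {
    on <- cell_type %in% active_sets[[t]]
    lev <- ifelse(on, cfg$active_level, cfg$inactive_level)
    act[, t] <- lev * exp(rnorm(cfg$n_cells, 0, cfg$activity_cv) +
                            cfg$trajectory_effect * (tau - 0.5))
  }

  out <- structure(
    list(config = cfg, tf_names = tf_names,
         pioneer = setNames(tf_names != primary | is.na(primary), tf_names),
         primary = primary, cofactor = cofactor,
         active_sets = setNames(active_sets, tf_names),
         cell_type = cell_type, trajectory = tau, perm_factor = perm,
         tf_activity = act,
         peaks = peaks, peak_edges = peak_edges,
         cofactor_rules = cofactor_rules, motif_sites = sites,
         bound = bound, genes = genes, gene_edges = gene_edges,
         truth_links = truth_links,
         motifs = motifs, adt_map = adt_map,
         footprint_depth = cfg$footprint_depth,
         binding_threshold = cfg$binding_threshold),
    class = "phr_truth"
  )
  out$peaks$gc <- peak_gc(peak_sequences(out))
  out
}

#' @export
#' @method print phr_truth
print.phr_truth <- function(x, ...) {
  cat(sprintf(paste0("<phr_truth> %d cells, %d peaks (%d wired), %d genes, ",
                     "%d TFs, %d motifs\n"),
              x$config$n_cells, nrow(x$peaks),
              sum(x$peaks$role == "enhancer"), nrow(x$genes),
              length(x$tf_names), length(x$motifs)))
  if (!is.na(x$primary)) {
    cat(sprintf("  primary %s gated by cofactor %s (%d peaks)\n",
                x$primary, x$cofactor, nrow(x$cofactor_rules)))
  }
  invisible(x)
}

# Cell-by-peak open probabilities implied by the planted architecture.
open_probability <- function(truth, tf_activity = truth$tf_activity) {
  cfg <- truth$config
  P <- matrix(rep(truth$peaks$baseline, each = nrow(tf_activity)),
              nrow(tf_activity), nrow(truth$peaks))
  colnames(P) <- truth$peaks$peak_id
  for (e in seq_len(nrow(truth$peak_edges))) {
    j <- match(truth$peak_edges$peak_id[e], truth$peaks$peak_id)
    contrib <- truth$peak_edges$effect[e] *
      tf_activity[, truth$peak_edges$tf[e]]
    gate <- truth$peak_edges$gate_tf[e]
    if (!is.na(gate)) {
      contrib <- contrib * (tf_activity[, gate] > truth$binding_threshold)
    }
    P[, j] <- P[, j] + contrib
  }
  stats::plogis(P)
}

rnb <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, size = size, mu = mu)
}

#' Simulate trimodal counts from a ground truth
#'
#' ATAC counts are negative binomial with mean proportional to each cell's
#' fragment depth times the peak's open probability (a logistic function of
#' baseline plus TF activity effects, AND-gated where a cofactor rule
#' applies). ADT counts mix specific signal (proportional to TF activity)
#' with nonspecific background proportional to the cell's permeabilization
#' factor; free-oligo counts read out that same factor. RNA counts follow
#' per-gene rates shifted up or down by the open probability of wired peaks.
#'
#' @param truth A `phr_truth`.
#' @param seed Seed for this draw; defaults to `config$seed + 1`.
#' @param genotype Genotype label stored in the cell metadata.
#' @param barcode_prefix Prefix of generated cell barcodes.
#' @return A `phr_dataset` (RNA layer flagged "measured").
#' @export
simulate_counts <- function(truth, seed = NULL, genotype = "WT",
                            barcode_prefix = "cell") {
  cfg <- truth$config
  set.seed(seed %||% (cfg$seed + 1L))
  n <- cfg$n_cells
  barcodes <- sprintf("%s%05d", barcode_prefix, seq_len(n))
  act <- truth$tf_activity
  perm <- truth$perm_factor

  P <- open_probability(truth)
  frag_depth <- exp(rnorm(n, log(cfg$mean_fragments) - cfg$depth_sdlog^2 / 2,
                          cfg$depth_sdlog))
  mu_atac <- P * (frag_depth / rowSums(P))
  atac <- Matrix::drop0(Matrix::Matrix(
    rnb(length(mu_atac), mu_atac, cfg$nb_size_atac),
    n, ncol(P), dimnames = list(barcodes, colnames(P)), sparse = TRUE))

  n_tfs <- cfg$n_tfs
  n_tags <- n_tfs + cfg$n_control_adts
  tag_names <- c(truth$tf_names,
                 sprintf("CTRL%02d", seq_len(cfg$n_control_adts)))
  signal_budget <- (1 - cfg$background_adt_frac) * cfg$mean_adt_umis
  adt_scale <- signal_budget / cfg$active_level
  bg_tag <- runif(n_tags, 0.8, 1.2) *
    (cfg$background_adt_frac * cfg$mean_adt_umis / n_tags)
  gamma <- seq(cfg$perm_gamma[1], cfg$perm_gamma[2], length.out = n_tags)
  signal <- cbind(adt_scale * act,
                  matrix(0, n, cfg$n_control_adts))
  mu_adt <- signal +
    matrix(rep(perm, n_tags), n, n_tags)^rep(gamma, each = n) *
      rep(bg_tag, each = n)
  adt <- matrix(rnb(length(mu_adt), mu_adt, cfg$nb_size_adt), n, n_tags,
                dimnames = list(barcodes, tag_names))

  free <- rnb(n, cfg$free_oligo_mean * perm, cfg$nb_size_free)

  rate <- matrix(rep(truth$genes$baseline, each = n), n, cfg$n_genes)
  for (e in seq_len(nrow(truth$gene_edges))) {
    g <- match(truth$gene_edges$gene[e], truth$genes$gene)
    rate[, g] <- rate[, g] + truth$gene_edges$sign[e] *
      truth$gene_edges$effect[e] * P[, truth$gene_edges$peak_id[e]]
  }
  rate <- pmax(rate, 0.02)
  rna_depth <- exp(rnorm(n, log(cfg$mean_rna_umis) - cfg$depth_sdlog^2 / 2,
                         cfg$depth_sdlog))
  mu_rna <- rate * (rna_depth / rowSums(rate))
  rna <- Matrix::drop0(Matrix::Matrix(
    rnb(length(mu_rna), mu_rna, cfg$nb_size_rna),
    n, cfg$n_genes, dimnames = list(barcodes, truth$genes$gene),
    sparse = TRUE))

  peaks <- truth$peaks[, c("chrom", "start", "end", "peak_id", "gc")]
  trimodal_dataset(
    atac = atac, adt = adt, free_oligo = free, peaks = peaks, rna = rna,
    cell_meta = tibble::tibble(
      donor = sample(c("donor1", "donor2"), n, replace = TRUE),
      genotype = genotype,
      cell_type = paste0("type", truth$cell_type)
    ),
    tss = truth$genes[, c("gene", "chrom", "tss", "strand")],
    rna_provenance = "measured"
  )
}

#' Emit peak sequences with planted motif sites
#'
#' Deterministic given the truth's seed: AT-rich background base composition
#' with a degenerate motif instance written at each planted site's offset
#' (reverse-complemented on minus-strand sites). An instance matches the
#' motif consensus at `site_matches` randomly chosen positions and carries
#' A/T filler elsewhere, so it scores `1000 * site_matches / motif_length`
#' (above the 400 cutoff) for its own motif and far below the cutoff for
#' every other motif.
#'
#' @param truth A `phr_truth`.
#' @return Named character vector of peak sequences.
#' @export
peak_sequences <- function(truth) {
  cfg <- truth$config
  set.seed(cfg$seed + 7000L)
  widths <- truth$peaks$end - truth$peaks$start
  letters <- sample(DNA_BASES, sum(widths), replace = TRUE,
                    prob = cfg$base_probs)
  ends <- cumsum(widths)
  seqs <- substring(paste(letters, collapse = ""), ends - widths + 1, ends)
  names(seqs) <- truth$peaks$peak_id
  cons <- lapply(truth$motifs, function(m) {
    strsplit(motif_consensus(m), "")[[1]]
  })
  L <- cfg$motif_length
  m_match <- cfg$site_matches
  for (i in seq_len(nrow(truth$motif_sites))) {
    s <- truth$motif_sites[i, ]
    inst <- sample(c("A", "T"), L, replace = TRUE)
    at <- sample.int(L, m_match)
    inst[at] <- cons[[s$motif]][at]
    ins <- paste(inst, collapse = "")
    if (s$strand == "-") ins <- reverse_complement(ins)
    substr(seqs[[s$peak_id]], s$offset + 1, s$offset + L) <- ins
  }
  seqs
}

#' Simulate Tn5 fragments
#'
#' For every cell-peak count, fragments are generated whose two insertion
#' sites are drawn uniformly over the peak, except that positions within a
#' functional motif core are depleted by the planted `footprint_depth` in
#' cells where the site's TF is bound (activity above the binding threshold).
#' The fragment count per cell-peak equals the ATAC count, so insertion
#' totals are consistent with the count matrix (two insertions per
#' fragment).
#'
#' @param truth A `phr_truth`.
#' @param dataset The `phr_dataset` simulated from the same truth.
#' @param peaks Optional character vector of peak ids to restrict to.
#' @param seed Seed for this draw; defaults to `config$seed + 3`.
#' @return Fragment tibble (`chrom`, `start`, `end`, `barcode`, `count`),
#'   sorted by position.
#' @export
simulate_fragments <- function(truth, dataset, peaks = NULL, seed = NULL) {
  cfg <- truth$config
  set.seed(seed %||% (cfg$seed + 3L))
  peaks <- peaks %||% truth$peaks$peak_id
  L <- cfg$motif_length
  depth <- truth$footprint_depth
  thr <- truth$binding_threshold
  fsites <- truth$motif_sites[truth$motif_sites$functional &
                                truth$motif_sites$peak_id %in% peaks, ]
  barcodes <- rownames(dataset$atac)
  out <- list()
  emit <- function(peak_row, cells, counts, w = NULL) {
    if (!length(cells)) return(NULL)
    width <- peak_row$end - peak_row$start
    nfrag <- sum(counts)
    pos <- if (is.null(w)) {
      matrix(sample.int(width, 2 * nfrag, replace = TRUE), nfrag, 2)
    } else {
      matrix(sample.int(width, 2 * nfrag, replace = TRUE, prob = w), nfrag, 2)
    }
    tibble::tibble(
      chrom = peak_row$chrom,
      start = peak_row$start + pmin(pos[, 1], pos[, 2]) - 1L,
      end = peak_row$start + pmax(pos[, 1], pos[, 2]),
      barcode = rep(barcodes[cells], counts),
      count = 1L
    )
  }
  trip <- Matrix::summary(dataset$atac)
  peak_of <- colnames(dataset$atac)
  keep <- peak_of[trip$j] %in% peaks
  trip <- trip[keep, , drop = FALSE]
  has_site <- peak_of[trip$j] %in% fsites$peak_id
  # peaks without functional sites: uniform insertion positions, one batch
  plain <- trip[!has_site, , drop = FALSE]
  if (nrow(plain)) {
    width <- cfg$peak_width
    nfrag <- sum(plain$x)
    pos <- matrix(sample.int(width, 2 * nfrag, replace = TRUE), nfrag, 2)
    starts <- rep(truth$peaks$start[match(peak_of[plain$j],
                                          truth$peaks$peak_id)], plain$x)
    out[[1]] <- tibble::tibble(
      chrom = "chrS",
      start = starts + pmin(pos[, 1], pos[, 2]) - 1L,
      end = starts + pmax(pos[, 1], pos[, 2]),
      barcode = rep(barcodes[plain$i], plain$x),
      count = 1L
    )
  }
  # peaks with footprints: per peak, split cells by bound pattern
  fp <- trip[has_site, , drop = FALSE]
  if (nrow(fp)) {
    for (pid in unique(peak_of[fp$j])) {
      rows <- fp[peak_of[fp$j] == pid, , drop = FALSE]
      prow <- truth$peaks[match(pid, truth$peaks$peak_id), ]
      width <- prow$end - prow$start
      ss <- fsites[fsites$peak_id == pid, ]
      bound <- matrix(FALSE, nrow(rows), nrow(ss))
      for (s in seq_len(nrow(ss))) {
        bound[, s] <- truth$tf_activity[rows$i, ss$tf[s]] > thr
      }
      key <- apply(bound, 1, function(b) paste(as.integer(b), collapse = ""))
      for (kk in unique(key)) {
        sel <- key == kk
        w <- rep(1, width)
        on <- as.logical(as.integer(strsplit(kk, "")[[1]]))
        for (s in which(on)) {
          core <- (ss$offset[s] + 1):(ss$offset[s] + L)
          w[core] <- w[core] * (1 - depth)
        }
        out[[length(out) + 1L]] <-
          emit(prow, rows$i[sel], rows$x[sel],
               w = if (any(on)) w else NULL)
      }
    }
  }
  frags <- dplyr::bind_rows(out)
  if (!nrow(frags)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), barcode = character(),
                          count = integer()))
  }
  dplyr::arrange(frags, .data$chrom, .data$start)
}

#' Simulate a paired wild-type / knockout experiment
#'
#' KO cells are drawn with the target TF's activity set to zero: peaks whose
#' effects require it (directly or through a cofactor gate) revert to
#' baseline accessibility, and downstream genes follow. Genotype is recorded
#' in the cell metadata.
#'
#' @param truth A `phr_truth`.
#' @param ko_tf TF name to knock out.
#' @param seed Base seed; WT and KO draws use `seed` and `seed + 10`.
#' @return A combined `phr_dataset` with `genotype` in `cell_meta`.
#' @export
simulate_perturbation <- function(truth, ko_tf, seed = NULL) {
  if (!ko_tf %in% truth$tf_names) {
    abort(sprintf("Unknown TF: %s", ko_tf))
  }
  cfg <- truth$config
  seed <- seed %||% (cfg$seed + 1L)
  wt <- simulate_counts(truth, seed = seed, genotype = "WT",
                        barcode_prefix = "WT")
  truth_ko <- truth
  truth_ko$tf_activity[, ko_tf] <- 0
  ko <- simulate_counts(truth_ko, seed = seed + 10L, genotype = "KO",
                        barcode_prefix = "KO")
  trimodal_dataset(
    atac = rbind(wt$atac, ko$atac),
    adt = rbind(wt$adt, ko$adt),
    free_oligo = c(wt$free_oligo, ko$free_oligo),
    peaks = wt$peaks,
    rna = rbind(wt$rna, ko$rna),
    cell_meta = dplyr::bind_rows(
      wt$cell_meta[setdiff(names(wt$cell_meta), "barcode")],
      ko$cell_meta[setdiff(names(ko$cell_meta), "barcode")]
    ),
    tss = wt$tss, rna_provenance = "measured"
  )
}

#' Score recovered links against the planted truth
#'
#' @param links A `phr_links` object or its tibble (columns `adt`,
#'   `peak_id`, `gene`, `class`).
#' @param truth A `phr_truth`.
#' @return One-row tibble: `n_pred`, `n_truth`, `tp`, `precision`, `recall`,
#'   `sign_agreement`.
#' @export
evaluate_link_recovery <- function(links, truth) {
  tab <- if (inherits(links, "phr_links")) links$table else links
  pred <- dplyr::distinct(tab, .data$adt, .data$peak_id, .data$gene,
                          .data$class)
  tl <- dplyr::mutate(
    truth$truth_links,
    truth_class = ifelse(.data$sign > 0, "activating", "repressive"))
  hit <- dplyr::inner_join(pred, tl,
                           by = c(adt = "tf", "peak_id", "gene"))
  tibble::tibble(
    n_pred = nrow(pred), n_truth = nrow(tl), tp = nrow(hit),
    precision = ifelse(nrow(pred) > 0, nrow(hit) / nrow(pred), NA_real_),
    recall = nrow(hit) / nrow(tl),
    sign_agreement = ifelse(nrow(hit) > 0,
                            mean(hit$class == hit$truth_class), NA_real_)
  )
}
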