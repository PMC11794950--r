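test_that("truth and datasets are deterministic under a fixed seed", {
  t1 <- small_truth(seed = 5)
  t2 <- small_truth(seed = 5)
  expect_identical(t1$tf_activity, t2$tf_activity)
  expect_identical(t1$peaks, t2$peaks)
  expect_identical(t1$motif_sites, t2$motif_sites)
  d1 <- simulate_counts(t1)
  d2 <- simulate_counts(t2)
  expect_identical(as.matrix(d1$atac), as.matrix(d2$atac))
  expect_identical(d1$adt, d2$adt)
  f1 <- simulate_fragments(t1, d1, peaks = t1$peaks$peak_id[1:20])
  f2 <- simulate_fragments(t2, d2, peaks = t2$peaks$peak_id[1:20])
  expect_identical(f1, f2)
  expect_identical(peak_sequences(t1), peak_sequences(t2))
})

test_that("a single TF implies no cofactor rules; >= 2 TFs implies some", {
  t1 <- small_truth(n_tfs = 1, n_genes = 40, modules_per_tf = 4)
  expect_equal(nrow(t1$cofactor_rules), 0)
  t2 <- small_truth()
  expect_gt(nrow(t2$cofactor_rules), 0)
  expect_true(all(t2$cofactor_rules$gate_tf == t2$cofactor))
})

test_that("every TF regulates peaks and wired genes stay in the window", {
  truth <- small_truth()
  expect_true(all(truth$tf_names %in% truth$peak_edges$tf))
  # constrained genome: all truth gene-peak distances within the link window
  cfg <- sim_config(n_cells = 100, n_peaks = 100, n_genes = 30, n_tfs = 2,
                    n_types = 4, modules_per_tf = 3, peaks_per_module = 2,
                    genes_per_module = 2, genome_length = 1e6,
                    n_bound_extra = 10, n_decoy_motifs = 2,
                    n_decoy_sites = 5, seed = 2)
  truth2 <- generate_truth(cfg)
  mid <- setNames((truth2$peaks$start + truth2$peaks$end) / 2,
                  truth2$peaks$peak_id)
  tssv <- setNames(truth2$genes$tss, truth2$genes$gene)
  d <- abs(mid[truth2$truth_links$peak_id] - tssv[truth2$truth_links$gene])
  expect_true(all(d <= 5e5))
})

test_that("infeasible genome geometry raises a configuration error", {
  cfg <- sim_config(n_cells = 50, n_peaks = 4000, n_genes = 500,
                    genome_length = 1e5, seed = 1)
  expect_error(generate_truth(cfg), "geometry")
})

test_that("simulated layers share the cell index and are non-negative", {
  truth <- small_truth()
  ds <- simulate_counts(truth)
  cells <- rownames(ds$atac)
  expect_identical(rownames(ds$adt), cells)
  expect_identical(rownames(ds$rna), cells)
  expect_identical(names(ds$free_oligo), cells)
  expect_identical(ds$cell_meta$barcode, cells)
  expect_gte(min(ds$adt), 0)
  expect_gte(min(ds$atac), 0)
  expect_true(all(colnames(ds$rna) %in% ds$tss$gene))
})

test_that("fragment counts are consistent with the ATAC count matrix", {
  truth <- small_truth()
  ds <- simulate_counts(truth)
  sel <- truth$peaks$peak_id[c(1, 5, 50)]
  fr <- simulate_fragments(truth, ds, peaks = sel)
  # two insertions per fragment; fragments per peak match column totals
  starts <- truth$peaks$start[match(sel, truth$peaks$peak_id)]
  for (i in seq_along(sel)) {
    inpeak <- fr$start >= starts[i] & fr$start < starts[i] + 600
    expect_equal(sum(inpeak), sum(ds$atac[, sel[i]]))
  }
  # all insertions fall inside their peak
  expect_true(all(fr$end - fr$start >= 1))
})

test_that("zero ATAC counts produce zero fragments", {
  truth <- small_truth()
  ds <- simulate_counts(truth)
  pk <- truth$peaks$peak_id[3]
  ds$atac[, pk] <- 0
  fr <- simulate_fragments(truth, ds, peaks = pk)
  expect_equal(nrow(fr), 0)
})

test_that("without footprints, insertions are uniform over the peak", {
  truth <- small_truth(footprint_depth = 0, mean_fragments = 2000)
  ds <- simulate_counts(truth)
  pk <- truth$peaks$peak_id[which(truth$peaks$role == "enhancer")[1:4]]
  fr <- simulate_fragments(truth, ds, peaks = pk)
  starts <- truth$peaks$start[match(pk, truth$peaks$peak_id)]
  # positions relative to each fragment's peak
  pk_of <- findInterval(fr$start, sort(starts))
  rel <- c(fr$start - sort(starts)[pk_of], fr$end - 1 - sort(starts)[pk_of])
  bins <- table(cut(rel, breaks = seq(0, 600, by = 50),
                    include.lowest = TRUE))
  p <- suppressWarnings(chisq.test(bins)$p.value)
  expect_gt(p, 0.01)
})

test_that("the planted footprint depth shows up as core depletion", {
  truth <- small_truth(footprint_depth = 0.6, mean_fragments = 3000)
  ds <- simulate_counts(truth)
  # take one wired peak of TF1 and cells where TF1 is bound
  pe <- truth$peak_edges[truth$peak_edges$tf == "TF1", ]
  fr <- simulate_fragments(truth, ds, peaks = pe$peak_id)
  bound_cells <- rownames(ds$atac)[truth$tf_activity[, "TF1"] >
                                     truth$binding_threshold]
  fr <- fr[fr$barcode %in% bound_cells, ]
  sites <- truth$motif_sites[truth$motif_sites$peak_id %in% pe$peak_id &
                               truth$motif_sites$tf == "TF1", ]
  starts <- truth$peaks$start[match(sites$peak_id, truth$peaks$peak_id)]
  ins <- c(fr$start, fr$end - 1)
  core <- 0
  flank <- 0
  for (i in seq_len(nrow(sites))) {
    rel <- ins - starts[i] - sites$offset[i]
    core <- core + sum(rel >= 0 & rel < 40)
    flank <- flank + sum((rel >= -80 & rel < -40) | (rel >= 40 & rel < 120))
  }
  ratio <- (core / 40) / (flank / 120)
  expect_lt(abs(ratio - 0.4), 0.1)
})

test_that("knockout zeroes the target TF and gated peaks lose accessibility", {
  truth <- small_truth()
  pert <- simulate_perturbation(truth, truth$primary)
  expect_setequal(unique(pert$cell_meta$genotype), c("WT", "KO"))
  gated <- truth$cofactor_rules$peak_id
  wt <- pert$cell_meta$genotype == "WT"
  mean_wt <- Matrix::colMeans(pert$atac[wt, gated, drop = FALSE])
  mean_ko <- Matrix::colMeans(pert$atac[!wt, gated, drop = FALSE])
  expect_gt(mean(mean_wt), 2 * mean(mean_ko))
  expect_error(simulate_perturbation(truth, "nope"), "Unknown TF")
})

test_that("knocking out a TF without effects leaves other peaks unchanged", {
  truth <- small_truth()
  pert <- simulate_perturbation(truth, truth$primary)
  other <- truth$peaks$peak_id[truth$peaks$role == "background"]
  wt <- pert$cell_meta$genotype == "WT"
  m1 <- mean(pert$atac[wt, other])
  m2 <- mean(pert$atac[!wt, other])
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("planted TF effects are recovered by regression on activity", {
  cfg <- sim_config(n_cells = 2000, n_peaks = 600, n_genes = 80, n_tfs = 2,
                    n_types = 4, modules_per_tf = 4, peaks_per_module = 3,
                    genes_per_module = 2, n_bound_extra = 30,
                    n_decoy_motifs = 2, n_decoy_sites = 10,
                    depth_sdlog = 0.01, nb_size_atac = Inf,
                    mean_fragments = 3000, seed = 3)
  truth <- generate_truth(cfg)
  ds <- simulate_counts(truth)
  P <- phosphoreg:::open_probability(truth)
  scale_i <- cfg$mean_fragments / rowSums(P)
  pe <- truth$peak_edges[truth$peak_edges$tf == truth$cofactor, ][1:5, ]
  zscores <- vapply(seq_len(nrow(pe)), function(k) {
    j <- pe$peak_id[k]
    a <- truth$tf_activity[, truth$cofactor]
    counts <- as.numeric(ds$atac[, j])
    nll <- function(par) {
      mu <- scale_i * stats::plogis(par[1] + par[2] * a)
      -sum(stats::dpois(counts, mu, log = TRUE))
    }
    fit <- optim(c(-3, 1), nll, hessian = TRUE)
    se <- sqrt(diag(solve(fit$hessian)))[2]
    (fit$par[2] - pe$effect[k]) / se
  }, 0)
  expect_gte(mean(abs(zscores) <= 2), 0.8)
})

test_that("free-oligo counts and ADT background co-vary by construction", {
  truth <- default_truth()
  ds <- default_dataset()
  # a background-dominated tag tracks the free oligo across cells
  ctrl <- grep("CTRL", colnames(ds$adt), value = TRUE)
  rho <- max(abs(cor(log1p(ds$adt[, ctrl]), log1p(ds$free_oligo),
                     method = "spearman")))
  expect_gt(rho, 0.3)
})
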