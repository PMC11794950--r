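adaptive_on <- function(r, ...) {
  phosphoreg:::adaptive_cutoff(setNames(r, paste0("p", seq_along(r))),
                               pipeline_config(...))
}

test_that("the adaptive cutoff rule follows the decrement schedule", {
  # 2% of peaks above 0.5 -> stays at 0.5
  r <- c(rep(0.9, 2), rep(0.1, 98))
  out <- adaptive_on(r)
  expect_equal(out$cutoff, 0.5)
  expect_equal(out$status, "ok")
  expect_length(out$candidates, 2)

  # max r = 0.45 and 1.5% above 0.4 -> first satisfied at 0.4
  r2 <- c(rep(0.45, 3), rep(0.05, 197))
  out2 <- adaptive_on(r2)
  expect_equal(out2$cutoff, 0.4)
  expect_length(out2$candidates, 3)

  # nothing correlates -> floor reached, empty set, no exception
  r3 <- runif(200, 0, 0.05)
  out3 <- adaptive_on(r3)
  expect_equal(out3$status, "floor_reached")
  expect_length(out3$candidates, 0)
})

test_that("relaxing the fraction rule never raises the cutoff", {
  set.seed(41)
  for (i in 1:20) {
    r <- runif(300, -0.2, 0.8)
    cuts <- vapply(c(0.005, 0.01, 0.05, 0.2),
                   function(f) adaptive_on(r, corr_min_frac = f)$cutoff, 0)
    expect_true(all(diff(cuts) <= 1e-12))
  }
})

test_that("motif filtering keeps only candidates carrying the motif", {
  hits <- structure(list(
    hits = tibble::tibble(motif = c("m1", "m1", "m2"),
                          peak_id = c("pA", "pB", "pC"),
                          offset = c(1L, 2L, 3L), strand = "+",
                          score = c(900, 500, 700)),
    membership = Matrix::sparseMatrix(
      i = c(1, 2, 3), j = c(1, 1, 2), x = TRUE, dims = c(3, 2),
      dimnames = list(c("pA", "pB", "pC"), c("m1", "m2"))),
    cutoff = 400), class = "phr_hits")
  out <- motif_filter(c("pA", "pC", "pZ"), hits, "TF1", c(TF1 = "m1"))
  expect_equal(out$peak_id, "pA")
  expect_equal(out$motif_score, 900)
  expect_equal(nrow(motif_filter(character(), hits, "TF1", c(TF1 = "m1"))), 0)
  expect_error(motif_filter("pA", hits, "pRPS6", c(TF1 = "m1")),
               "explicit mapping")
})

test_that("peak-gene links obey the distance window and the z test", {
  # hand-built metacell object: 30 metacells, one causal peak-gene pair
  set.seed(42)
  k <- 30
  nbg <- 200
  driver <- rnorm(k)
  atac <- cbind(p_near = driver + rnorm(k, 0, 0.1),
                p_far = driver + rnorm(k, 0, 0.1),
                matrix(rnorm(k * nbg), k))
  colnames(atac)[3:(nbg + 2)] <- paste0("bg", seq_len(nbg))
  rna <- cbind(g1 = driver + rnorm(k, 0, 0.1))
  mc <- structure(list(norm = list(atac = atac, rna = rna)),
                  class = "phr_metacells")
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(1000, 700000, seq(2000, by = 1500, length.out = nbg)),
    end = c(1600, 700600, seq(2600, by = 1500, length.out = nbg)),
    peak_id = colnames(atac), gc = 0.4)
  tss <- tibble::tibble(gene = "g1", chrom = "chr1", tss = 100, strand = "+")
  links <- link_peaks_to_genes(mc, peaks, tss,
                               pipeline_config(n_background_peaks = 50),
                               seed = 1)
  expect_true("p_near" %in% links$peak_id)   # r ~ 0.99, matched bg is null
  expect_false("p_far" %in% links$peak_id)   # 700 kb away: never tested
  expect_true(all(links$p < 0.1 & abs(links$peak_gene_r) > 0.01))
})

test_that("link classification applies the +/-0.2 sign rule", {
  gene_links <- tibble::tibble(
    gene = c("g1", "g2", "g3"), peak_id = "pk",
    peak_gene_r = c(0.25, -0.25, 0.1), z = c(3, -3, 1),
    p = c(0.01, 0.01, 0.05), distance = 1000)
  cand <- tibble::tibble(peak_id = "pk", motif = "m1", motif_score = 800)
  out <- classify_links(gene_links, list(TF1 = cand))
  expect_equal(nrow(out$table), 2)
  expect_equal(out$table$class[out$table$gene == "g1"], "activating")
  expect_equal(out$table$class[out$table$gene == "g2"], "repressive")
  expect_false("g3" %in% out$table$gene)
})

test_that("full pipeline recovers planted links on the small simulator", {
  truth <- small_truth()
  ds <- simulate_counts(truth)
  hits <- scan_peaks(truth$motifs, peak_sequences(truth), cutoff = 400)
  links <- run_linkage(ds, hits, truth$adt_map,
                       config = small_pipeline_config())
  ev <- evaluate_link_recovery(links, truth)
  # desk-scale sanity bounds; the full-scale run asserts the strong claims
  expect_gt(ev$precision, 0.7)
  expect_gt(ev$recall, 0.1)
  expect_gt(ev$sign_agreement, 0.85)
  # tidy/glance accessors agree with the table
  expect_equal(nrow(tidy(links)), ev$n_pred)
  expect_equal(glance(links)$n_links, ev$n_pred)
})
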