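test_that("quantile partition labels ranks with stable ties", {
  expect_equal(quantile_partition(1:10, q = 10), setNames(1:10, NULL),
               ignore_attr = TRUE)
  ties <- quantile_partition(rep(3, 7), q = 3)
  expect_equal(as.integer(table(ties)), c(2L, 2L, 3L))
  expect_equal(ties, quantile_partition(rep(3, 7) + 100, q = 3))
  x <- c(5, 1, 9, 2, 7, 3)
  expect_equal(quantile_partition(x, 2), quantile_partition(x + 42, 2))
  expect_error(quantile_partition(1:5, q = 1), "at least 2")
  expect_error(quantile_partition(1:3, q = 5), "at least")
})

test_that("footprint profiles recover the planted depletion by ADT decile", {
  truth <- small_truth(mean_fragments = 2500)
  ds <- simulate_counts(truth)
  hits <- scan_peaks(truth$motifs[truth$adt_map[["TF1"]]],
                     peak_sequences(truth), cutoff = 400)
  adtn <- adt_normalize(ds)
  dec <- quantile_partition(adtn[, "TF1"], 10)
  names(dec) <- rownames(ds$atac)
  wired <- truth$peak_edges$peak_id[truth$peak_edges$tf == "TF1"]
  frags <- simulate_fragments(truth, ds, peaks = wired)
  fp <- footprint(frags, hits, truth$adt_map[["TF1"]], ds$peaks,
                  list(high = wired), dec, motif_length = 40)
  top <- fp$summary$core_flank_ratio[fp$summary$group == 10]
  bottom <- fp$summary$core_flank_ratio[fp$summary$group == 1]
  expect_lt(top, 0.65)
  expect_gt(bottom, 0.7)
  # flank-normalized values average 1 over the flank band by construction
  flank_band <- dplyr::filter(fp$profile, abs(position) >= 200, group == 10)
  expect_equal(mean(flank_band$norm, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("normalized profiles are invariant to uniform depth rescaling", {
  truth <- small_truth()
  ds <- simulate_counts(truth)
  hits <- scan_peaks(truth$motifs[truth$adt_map[["TF1"]]],
                     peak_sequences(truth), cutoff = 400)
  wired <- truth$peak_edges$peak_id[truth$peak_edges$tf == "TF1"]
  frags <- simulate_fragments(truth, ds, peaks = wired)
  groups <- setNames(rep(1L, nrow(ds$atac)), rownames(ds$atac))
  f1 <- footprint(frags, hits, truth$adt_map[["TF1"]], ds$peaks,
                  list(s = wired), groups, motif_length = 40)
  frags2 <- frags
  frags2$count <- frags2$count * 2
  f2 <- footprint(frags2, hits, truth$adt_map[["TF1"]], ds$peaks,
                  list(s = wired), groups, motif_length = 40)
  expect_equal(f1$profile$norm, f2$profile$norm)
})

test_that("coverage tracks scale per group and reflect single fragments", {
  frags <- tibble::tibble(chrom = "chrS", start = 10, end = 60,
                          barcode = "c1", count = 1L)
  labels <- c(c1 = 1L, c2 = 2L)
  expect_warning(
    cov <- quantile_coverage(frags, list(chrom = "chrS", start = 0, end = 100),
                             labels),
    "Empty group")
  g1 <- cov[cov$group == 1, ]
  expect_equal(unique(g1$coverage[g1$pos >= 10 & g1$pos < 60]), 1e4)
  expect_equal(unique(g1$coverage[g1$pos < 10 | g1$pos >= 60]), 0)
  expect_true(all(cov$coverage[cov$group == 2] == 0))
})

test_that("identical groups give identical coverage tracks", {
  set.seed(51)
  frags <- tibble::tibble(
    chrom = "chrS",
    start = s <- sample(0:400, 200, TRUE), end = s + sample(20:80, 200, TRUE),
    barcode = rep(c("a1", "b1"), each = 100), count = 1L)
  # same fragment set in both cells
  frags$start[101:200] <- frags$start[1:100]
  frags$end[101:200] <- frags$end[1:100]
  cov <- quantile_coverage(frags, list(chrom = "chrS", start = 0, end = 500),
                           c(a1 = 1L, b1 = 2L), binsize = 5)
  expect_equal(cov$coverage[cov$group == 1], cov$coverage[cov$group == 2])
})

test_that("coverage at a wired peak rises with the ADT quantile", {
  truth <- small_truth(mean_fragments = 2500)
  ds <- simulate_counts(truth)
  adtn <- adt_normalize(ds)
  dec <- quantile_partition(adtn[, "TF1"], 10)
  names(dec) <- rownames(ds$atac)
  pk <- truth$peak_edges$peak_id[truth$peak_edges$tf == "TF1"][1]
  row <- truth$peaks[truth$peaks$peak_id == pk, ]
  frags <- simulate_fragments(truth, ds, peaks = pk)
  cov <- quantile_coverage(frags, row, dec, binsize = 50)
  m <- tapply(cov$coverage, cov$group, mean)
  expect_gt(m[["10"]], m[["1"]])
})
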