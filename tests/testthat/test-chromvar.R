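# Independent brute-force motif deviation implementation: plain loops over
# cells, motifs, and background iterations, no shared code with the package
# beyond the sampled background peak table.
brute_force_deviations <- function(counts, membership, bg_peaks, n_bg) {
  counts <- as.matrix(counts)
  membership <- as.matrix(membership) > 0
  n_cells <- nrow(counts)
  n_motifs <- ncol(membership)
  total <- sum(counts)
  p <- colSums(counts) / total
  d <- rowSums(counts)
  raw_for <- function(peaks_of_motif) {
    raw <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      expected <- d[i] * sum(p[peaks_of_motif])
      obs <- sum(counts[i, peaks_of_motif])
      raw[i] <- (obs - expected) / expected
    }
    raw
  }
  z <- raw <- matrix(NA_real_, n_cells, n_motifs)
  for (m in seq_len(n_motifs)) {
    peaks <- which(membership[, m])
    raw[, m] <- raw_for(peaks)
    bg <- matrix(0, n_cells, n_bg)
    for (b in seq_len(n_bg)) {
      bg[, b] <- raw_for(bg_peaks[peaks, b])
    }
    mu <- apply(bg, 1, mean)
    sdv <- apply(bg, 1, sd)
    z[, m] <- (raw[, m] - mu) / sdv
  }
  list(z = z, raw = raw)
}

test_that("deviation z-scores match the brute-force oracle", {
  set.seed(21)
  counts <- matrix(rpois(20 * 30, 3), 20, 30)
  rownames(counts) <- paste0("c", 1:20)
  colnames(counts) <- paste0("p", 1:30)
  membership <- matrix(FALSE, 30, 2,
                       dimnames = list(colnames(counts), c("m1", "m2")))
  membership[1:8, 1] <- TRUE
  membership[seq(2, 30, by = 3), 2] <- TRUE
  gc <- runif(30, 0.3, 0.7)
  bg <- sample_background_peaks(gc, colSums(counts) / sum(counts), n = 12,
                                bins = 3, seed = 4)
  got <- chromvar_deviations(counts, membership, n_background = 12,
                             bg_peaks = bg)
  want <- brute_force_deviations(counts, membership, bg, 12)
  expect_equal(unname(got$z), want$z, tolerance = 1e-10)
  expect_equal(unname(got$raw), want$raw, tolerance = 1e-10)
})

test_that("counts matching the expectation model give zero raw deviations", {
  d <- c(10, 20, 40)
  q <- c(1, 2, 3, 4)
  counts <- outer(d, q)
  colnames(counts) <- paste0("p", 1:4)
  membership <- cbind(m1 = c(TRUE, TRUE, FALSE, FALSE))
  rownames(membership) <- colnames(counts)
  dev <- chromvar_deviations(counts, membership, n_background = 5, seed = 1)
  expect_equal(max(abs(dev$raw)), 0)
})

test_that("deviations are deterministic given the seed", {
  set.seed(22)
  counts <- matrix(rpois(200, 2), 10, 20)
  colnames(counts) <- paste0("p", 1:20)
  memb <- cbind(m1 = seq_len(20) <= 5)
  rownames(memb) <- colnames(counts)
  d1 <- chromvar_deviations(counts, memb, seed = 9, n_background = 10)
  d2 <- chromvar_deviations(counts, memb, seed = 9, n_background = 10)
  expect_identical(d1$z, d2$z)
})

test_that("a motif whose peaks carry no counts is reported missing", {
  counts <- cbind(p1 = c(2, 3), p2 = c(0, 0), p3 = c(1, 4))
  memb <- cbind(dead = c(FALSE, TRUE, FALSE), live = c(TRUE, FALSE, TRUE))
  rownames(memb) <- colnames(counts)
  dev <- chromvar_deviations(counts, memb, n_background = 5, seed = 1)
  expect_true("dead" %in% dev$missing)
  expect_true(all(is.na(dev$z[, "dead"])))
})

test_that("deviations recover planted TF activity on simulated data", {
  truth <- default_truth()
  ds <- default_dataset()
  hits <- default_hits()
  dev <- chromvar_deviations(ds$atac, hits$membership, gc = ds$peaks$gc,
                             seed = 1)
  for (tf in truth$tf_names[truth$pioneer]) {
    expect_gt(cor(dev$z[, truth$adt_map[[tf]]], truth$tf_activity[, tf]),
              0.6)
  }
})

test_that("ADT-motif rank table: self-correlation, permutation invariance", {
  set.seed(23)
  z <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(NULL, paste0("m", 1:6)))
  adt <- z[, 1:3]
  colnames(adt) <- c("A1", "A2", "A3")
  cmap <- c(A1 = "m1", A2 = "m2", A3 = "m3")
  rk <- adt_motif_rank_correlation(adt, z, cmap)
  expect_true(all(rk$canonical$rank == 1))
  expect_true(all(rk$canonical$percentile == 100))
  # permuting cells leaves the table unchanged
  perm <- sample(40)
  rk2 <- adt_motif_rank_correlation(adt[perm, ], z[perm, ], cmap)
  expect_equal(rk$table, rk2$table)
  # zero-variance ADT flagged
  adt0 <- cbind(adt, A4 = rep(1, 40))
  rk3 <- adt_motif_rank_correlation(adt0, z, cmap)
  expect_true("A4" %in% rk3$flagged)
})

test_that("under the null the canonical percentile is uniform on average", {
  set.seed(24)
  pct <- replicate(100, {
    z <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(NULL, paste0("m", 1:10)))
    adt <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "A"))
    rk <- adt_motif_rank_correlation(adt, z, c(A = "m5"))
    rk$canonical$percentile
  })
  expect_lt(abs(mean(pct) - 55), 8) # E[percentile] = 100*(n+1)/(2n) = 55
})
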