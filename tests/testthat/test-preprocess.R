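make_qc_dataset <- function(adt_totals) {
  n <- length(adt_totals)
  atac <- Matrix::Matrix(matrix(5, n, 4), sparse = TRUE)
  rownames(atac) <- paste0("bc", seq_len(n))
  peaks <- tibble::tibble(chrom = "chr1", start = 0:3 * 100,
                          end = 0:3 * 100 + 50,
                          peak_id = paste0("p", 1:4))
  adt <- cbind(adt_totals, 0)
  trimodal_dataset(atac, adt, free_oligo = rep(1, n), peaks = peaks)
}

test_that("the ADT-count QC rule is a strict 'over 10,000' cutoff", {
  ds <- make_qc_dataset(c(10001, 10000, 50))
  cfg <- pipeline_config(peak_count_bounds = c(1, 1e6))
  out <- qc_filter(ds, cfg)
  expect_equal(out$n_after, 2)
  expect_true("bc2" %in% out$dataset$cell_meta$barcode)
  expect_false("bc1" %in% out$dataset$cell_meta$barcode)
  expect_equal(out$report$n_removed[out$report$rule == "adt_count_max"], 1L)
})

test_that("an empty QC rule set is the identity and total removal errors", {
  ds <- make_qc_dataset(c(100, 200))
  cfg <- pipeline_config()
  cfg$adt_count_max <- NULL
  cfg$rna_umi_bounds <- NULL
  cfg$peak_count_bounds <- NULL
  expect_equal(qc_filter(ds, cfg)$n_after, 2)
  cfg2 <- pipeline_config(adt_count_max = 1)
  expect_error(qc_filter(ds, cfg2), "every cell")
})

test_that("CLR matches hand-computed values and is zero-sum per cell", {
  expect_equal(clr_normalize(rbind(c(1, 1, 1, 1))), rbind(c(0, 0, 0, 0)))
  out <- clr_normalize(rbind(c(3, 0)))
  expect_equal(out[1, ], c(0.693147, -0.693147), tolerance = 1e-6,
               ignore_attr = TRUE)
  set.seed(1)
  x <- matrix(rpois(60, 5), 10, 6)
  expect_lt(max(abs(rowSums(clr_normalize(x)))), 1e-12)
  # tag margin centers columns instead
  expect_lt(max(abs(colSums(clr_normalize(x, margin = "tags")))), 1e-12)
})

test_that("free-oligo regression removes the covariate exactly", {
  set.seed(2)
  n <- 200
  free <- rpois(n, 50)
  x <- log1p(free)
  clr <- cbind(2 + 3 * x + rnorm(n, 0, 0.1), 1 - 0.5 * x)
  fit <- regress_free_oligo(clr, free)
  # residuals orthogonal to the covariate (zero covariance)
  xc <- x - mean(x)
  expect_lt(max(abs(crossprod(xc, fit$residuals))) / length(x), 1e-10)
  expect_lt(abs(cor(fit$residuals[, 1], x)), 1e-10)
  # a perfectly linear tag has zero residuals
  expect_lt(max(abs(fit$residuals[, 2])), 1e-10)
  expect_equal(unname(fit$slopes[2]), -0.5, tolerance = 1e-10)
})

test_that("a constant covariate returns centered CLR with zero slopes", {
  clr <- cbind(a = rnorm(10), b = rnorm(10))
  expect_warning(fit <- regress_free_oligo(clr, rep(7, 10)), "Constant")
  expect_equal(fit$slopes, c(a = 0, b = 0))
  expect_equal(fit$residuals, clr - rep(colMeans(clr), each = 10))
})

test_that("staining index evaluates its formula and invariances", {
  expect_equal(
    staining_index(list(median = 10, sd = 2), list(median = 4, sd = 1.5)),
    2.0)
  x <- c(1, 2, 3, 4, 10)
  expect_equal(staining_index(x, x), 0)
  y <- c(5, 6, 8, 9, 12)
  expect_equal(staining_index(3 * y, 3 * x), staining_index(y, x))
  expect_error(staining_index(list(median = 1, sd = 1),
                              list(median = 0, sd = 0)), "sd")
})

test_that("TF-IDF matches the hand case and its structural contracts", {
  one <- tfidf(Matrix::Matrix(5, 1, 1, sparse = TRUE,
                              dimnames = list("c", "p")))
  expect_equal(one[1, 1], log(10001))

  set.seed(3)
  x <- matrix(rpois(80, 2), 8, 10)
  x[, 4] <- 0          # absent peak
  x[x == 0 & col(x) != 4 & row(x) == 1] <- 1  # keep cells nonzero
  out <- tfidf(x)
  expect_true(all(out[, 4] == 0))
  # doubling one cell's counts leaves its values unchanged (row-normalized
  # term; the nonzero pattern and hence IDF are unchanged)
  x2 <- x
  x2[2, ] <- 2 * x[2, ]
  expect_equal(as.matrix(tfidf(x2))[2, ], as.matrix(out)[2, ])

  bad <- x
  bad[3, ] <- 0
  rownames(bad) <- paste0("cell", 1:8)
  expect_error(tfidf(bad), "cell3")
})

test_that("LSI matches a dense SVD oracle and flags depth components", {
  set.seed(4)
  x <- matrix(rnorm(50 * 80), 50, 80)
  fit <- lsi(x, n_components = 10)
  sv <- svd(x)$d[1:10]
  expect_equal(fit$d, sv, tolerance = 1e-8)
  # embedding reproducible
  fit2 <- lsi(x, n_components = 10)
  expect_identical(fit$embedding, fit2$embedding)

  # rank-1 matrix: first component carries >99.9% of the Frobenius norm
  r1 <- outer(runif(30, 1, 2), runif(40, 1, 2)) + matrix(rnorm(1200, 0, 1e-3), 30)
  f1 <- lsi(r1, n_components = 3)
  expect_gt(f1$d[1]^2 / sum(svd(r1)$d^2), 0.999)

  # depth flagging picks up a component aligned with totals
  expect_true(any(abs(lsi(r1, 3, counts_total = rowSums(r1))$depth_cor) > 0.75))
  expect_error(lsi(x, n_components = 60), "smaller")
  exact1 <- outer(1:10, 1:8)
  expect_error(lsi(exact1, n_components = 5), "rank")
})
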