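test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  set.seed(7)
  r <- matrix(rnorm(60), 10, 6)
  qr <- quantile_normalize(r)
  sorted <- apply(qr, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  expect_equal(quantile_normalize(qr), qr, tolerance = 1e-12)  # idempotent
  # ranks within columns are preserved
  expect_equal(apply(qr, 2, rank), apply(r, 2, rank))
})

test_that("quantile normalization edge cases", {
  one_row <- matrix(c(3, 5, 10), nrow = 1)
  expect_equal(as.vector(quantile_normalize(one_row)), rep(6, 3))
  same <- cbind(c(1, 2), c(1, 2))
  expect_equal(quantile_normalize(same), same, ignore_attr = TRUE)
  expect_error(quantile_normalize(cbind(c(1, NA), c(1, 2))), "finite")
  expect_error(quantile_normalize(matrix(1:3, ncol = 1)), "2 columns")
})

test_that("platform preparation applies the documented transforms", {
  # identical columns make quantile normalization a no-op, exposing the
  # raw transform
  cnt <- toy_dataset(values = rep(c(0, 3, 7, 15), 4), platform = "counts")
  prep <- prepare_matrix(cnt)
  expect_equal(unname(prep[, 1]), log2(c(0, 3, 7, 15) + 0.5))

  logged <- toy_dataset(values = rep(c(2, 8, 12, 20), 4))
  expect_equal(unname(prepare_matrix(logged)[, 1]), c(2, 8, 12, 20))

  unlogged <- toy_dataset(values = rep(c(10, 100, 1000, 10000), 4))
  expect_equal(unname(prepare_matrix(unlogged)[, 1]),
               log2(c(10, 100, 1000, 10000) + 1))

  # output is a fixed point of quantile normalization (tie-free values)
  set.seed(1)
  ds <- toy_dataset(values = rnorm(16, 10), platform = "intensity")
  pm <- prepare_matrix(ds)
  expect_equal(quantile_normalize(pm), pm, tolerance = 1e-12)
})

test_that("moderated t with zero prior df equals the ordinary pooled t", {
  set.seed(11)
  m <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("G", 1:5), paste0("S", 1:8)))
  groups <- rep(c("diploid", "polyploid"), each = 4)
  res <- moderated_t_test(m, groups, d0 = 0)
  for (g in 1:5) {
    ora <- pooled_t_oracle(m[g, 5:8], m[g, 1:4])
    expect_equal(res$lfc[g], ora$lfc, tolerance = 1e-12)
    expect_equal(res$t[g], ora$t, tolerance = 1e-12)
    expect_equal(res$p[g], ora$p, tolerance = 1e-12)
  }
})

test_that("hand-worked two-group case", {
  m <- rbind(G1 = c(1, 2, 3, 4, 5, 6))
  groups <- rep(c("diploid", "polyploid"), each = 3)
  res <- moderated_t_test(m, groups, d0 = 0)
  expect_equal(res$lfc, 3)
  expect_equal(res$t, 3 / sqrt(2 / 3), tolerance = 1e-12)
})

test_that("label exchange flips fold changes and preserves p-values", {
  set.seed(13)
  m <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(paste0("G", 1:40), paste0("S", 1:10)))
  g1 <- rep(c("diploid", "polyploid"), each = 5)
  g2 <- rep(c("polyploid", "diploid"), each = 5)
  r1 <- moderated_t_test(m, g1)
  r2 <- moderated_t_test(m, g2)
  expect_equal(r1$lfc, -r2$lfc, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("flat genes and undersized groups are handled as documented", {
  m <- rbind(G1 = c(5, 5, 5, 5), G2 = c(1, 2, 5, 7))
  groups <- rep(c("diploid", "polyploid"), each = 2)
  res <- moderated_t_test(m, groups, d0 = 0)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  expect_error(moderated_t_test(m[, 1:3], c("diploid", "diploid", "polyploid")),
               "at least 2 samples")
})

test_that("moderated t agrees with the reference empirical-Bayes fit", {
  set.seed(17)
  m <- matrix(rnorm(200 * 12, sd = rep(sqrt(1 / stats::rgamma(200, 4, 4)),
                                       12)), 200, 12,
              dimnames = list(paste0("G", 1:200), paste0("S", 1:12)))
  groups <- rep(c("diploid", "polyploid"), each = 6)
  res <- moderated_t_test(m, groups)
  design <- cbind(1, groups == "polyploid")
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t, fit$t[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$p, fit$p.value[, 2], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("DEG selection applies strict thresholds and sign rules", {
  res <- data.frame(
    gene_id = c("A", "B", "C", "D", "E"),
    lfc = c(1, 1, -2, 0.5, 0),
    t = 1,
    p = c(0.04, 0.04, 0.01, 0.05, 0.001),
    fdr = c(0.09, 0.2, 0.05, 0.09, 0.01)
  )
  degs <- select_degs(res)
  expect_equal(degs$up, "A")      # B fails FDR, D fails strict p
  expect_equal(degs$down, "C")    # E has lfc exactly 0
})
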