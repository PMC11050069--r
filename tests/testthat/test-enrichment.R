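test_that("hypergeometric tail matches exact enumeration on worked cases", {
  # 92378 of the 184756 ways to draw 10 from 20 contain >= 3 of a 5-class
  expect_equal(hypergeom_upper_tail(20, 5, 10, 3), 0.5, tolerance = 1e-14)
  expect_equal(hypergeom_upper_tail(20, 5, 10, 3),
               hyper_tail_enumeration(20, 5, 10, 3), tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(12, 4, 6, 2),
               hyper_tail_enumeration(12, 4, 6, 2), tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(15, 7, 5, 0), 1)
  expect_equal(hypergeom_upper_tail(9, 4, 9, 4), 1)  # query = background
  # large background: stable against a log-space binomial-coefficient sum
  js <- 50:358
  log_terms <- lchoose(1000, js) + lchoose(1e5 - 1000, 358 - js) -
    lchoose(1e5, 358)
  expect_equal(hypergeom_upper_tail(1e5, 1000, 358, 50), sum(exp(log_terms)),
               tolerance = 1e-10)
})

test_that("tail routine rejects invalid parameters and is monotone in k", {
  expect_error(hypergeom_upper_tail(10, 11, 5, 1),
               class = "ploidysig_domain_error")
  expect_error(hypergeom_upper_tail(10, 5, 5, 6),
               class = "ploidysig_domain_error")
  expect_error(hypergeom_upper_tail(10, -1, 5, 0),
               class = "ploidysig_domain_error")
  p <- vapply(0:5, function(k) hypergeom_upper_tail(30, 5, 10, k), numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("O/E bookkeeping follows the observed-over-expected definition", {
  bg <- paste0("G", 1:2000)
  sig <- list(BIG = paste0("G", 1:1000))
  query <- paste0("G", c(1:50, 1500:1807))  # n = 358, 50 in the signature
  tab <- enrich(query, signature_collection(sig), bg)
  expect_equal(tab$k, 50)
  expect_equal(tab$expected, 358 * 1000 / 2000)
  expect_equal(tab$oe_ratio, 50 / 179, tolerance = 1e-12)
  expect_equal(tab$p, hypergeom_upper_tail(2000, 1000, 358, 50))

  # a signature equal to the whole background can never pass the O/E cut
  full <- enrich(paste0("G", 1:100), signature_collection(list(ALL = bg)), bg)
  expect_lte(full$oe_ratio, 1)
  expect_false(full$selected)
})

test_that("the reporting filter requires both bounds strictly", {
  tab <- data.frame(signature = c("S1", "S2", "S3"),
                    k = c(10, 10, 10), K = 20, n = 50, N = 1000,
                    expected = 1, oe_ratio = c(1.4, 2.0, 2.0),
                    p = 1e-5, fdr = c(0.005, 0.005, 0.02),
                    member_genes = "")
  tab$selected <- tab$fdr < 0.01 & tab$oe_ratio > 1.5
  expect_equal(tab$selected, c(FALSE, TRUE, FALSE))
  # and enrich() computes the same flag from its own columns
  bg <- paste0("G", 1:200)
  sigs <- signature_collection(list(HIT = paste0("G", 1:20),
                                    MISS = paste0("G", 101:120)))
  res <- enrich(paste0("G", 1:25), sigs, bg)
  expect_equal(res$selected,
               res$fdr < 0.01 & res$oe_ratio > 1.5)
})

test_that("queries outside the background and empty queries are handled", {
  bg <- paste0("G", 1:50)
  sigs <- signature_collection(list(S = paste0("G", 1:10)))
  expect_error(enrich(c("G1", "NOPE"), sigs, bg), "NOPE",
               class = "ploidysig_domain_error")
  tab <- enrich(character(), sigs, bg)
  expect_equal(tab$p, 1)
  expect_false(any(tab$selected))
})

test_that("signature members outside the background are dropped before sizing", {
  bg <- paste0("G", 1:100)
  sigs <- signature_collection(list(S = c(paste0("G", 1:10), "ALIEN1", "ALIEN2")))
  tab <- enrich(paste0("G", 1:5), sigs, bg)
  expect_equal(tab$K, 10)
})

test_that("O/E ratios average to one under random queries", {
  set.seed(909)
  bg <- paste0("G", 1:2000)
  sigs <- signature_collection(setNames(
    lapply(1:30, function(i) sample(bg, 100)), paste0("S", 1:30)))
  oe <- replicate(40, mean(enrich(sample(bg, 200), sigs, bg)$oe_ratio))
  expect_lt(abs(mean(oe) - 1), 0.05)
})

test_that("enrichment reports round-trip their numeric fields", {
  bg <- paste0("G", 1:300)
  sigs <- signature_collection(list(A = paste0("G", 1:30),
                                    B = paste0("G", 200:240)))
  tab <- enrich(paste0("G", 1:40), sigs, bg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_report(tab, path, filtered = FALSE)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$signature, tab$signature)
  expect_equal(back$gene_number, tab$k)
  expect_equal(back$oe_ratio, as.numeric(sprintf("%.2f", tab$oe_ratio)))
  expect_equal(back$fdr, tab$fdr, tolerance = 0.01)

  write_enrichment_report(tab[tab$selected, ], path)
  empty <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(colnames(empty),
               c("signature", "gene_number", "oe_ratio", "fdr", "member_genes"))
})
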