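test_that("one-step neighborhoods are proper and symmetric", {
  leaves <- LETTERS[2:9]
  g <- toy_graph(cbind("A", leaves))
  expect_setequal(neighborhood(g, "A"), leaves)
  expect_length(neighborhood(g, "A"), 8)
  expect_equal(neighborhood(g, "B"), "A")
  g2 <- igraph::add_vertices(g, 1, name = "Z")
  expect_length(neighborhood(g2, "Z"), 0)
  expect_length(neighborhood(g2, "missing"), 0)
  for (v in c("A", "B", "C")) {
    for (u in neighborhood(g2, v)) {
      expect_true(v %in% neighborhood(g2, u))
    }
  }
})

test_that("PIEA p-values match hand-enumerated hypergeometric tails", {
  # star gene with 4 neighbors, all in a DEG set of 5, background 10
  bg <- paste0("G", 1:10)
  g <- toy_graph(cbind("G1", c("G2", "G3", "G4", "G5")))
  deg <- c("G2", "G3", "G4", "G5", "G6")
  rec <- piea_scan(g, deg, bg, min_degree = 3)
  row <- rec[rec$gene_id == "G1", ]
  expect_equal(row$K_nb, 4)
  expect_equal(row$k_nb, 4)
  expect_equal(row$p, 6 / 252, tolerance = 1e-12)
  expect_equal(row$p, hyper_tail_enumeration(10, 5, 4, 4), tolerance = 1e-12)
})

test_that("only genes with strictly more than min_degree interactants are tested", {
  g <- toy_graph(rbind(cbind("H5", paste0("a", 1:5)),
                       cbind("H6", paste0("b", 1:6))))
  bg <- c("H5", "H6", paste0("a", 1:5), paste0("b", 1:6))
  rec <- piea_scan(g, c("a1", "b1"), bg, min_degree = 5)
  expect_false("H5" %in% rec$gene_id)  # exactly 5 interactants
  expect_true("H6" %in% rec$gene_id)
})

test_that("degenerate and invalid PIEA inputs are handled", {
  g <- toy_graph(cbind("A", c("B", "C")))
  expect_error(piea_scan(g, c("B", "QQQ"), c("A", "B", "C")), "QQQ",
               class = "ploidysig_domain_error")
  rec <- piea_scan(g, "B", c("A", "B", "C"), min_degree = 5)
  expect_equal(nrow(rec), 0)
  # k = 0 gives p = 1
  g2 <- toy_graph(cbind("A", paste0("n", 1:8)))
  bg2 <- c("A", paste0("n", 1:8), "D1", "D2")
  rec2 <- piea_scan(g2, c("D1", "D2"), bg2)
  expect_equal(rec2$p[rec2$gene_id == "A"], 1)
})

test_that("master regulators must be enriched AND consistently regulated", {
  records <- data.frame(
    gene_id = c("A", "B", "C", "D"),
    direction = c("up", "up", "down", "down"),
    fdr = c(0.01, 0.01, 0.01, 0.5)
  )
  consensus <- structure(list(up = c("A", "X"), down = c("C", "D")),
                         class = "ConsensusSet")
  sel <- select_master_regulators(records, consensus, fdr_cut = 0.05)
  expect_equal(sel$up, "A")    # B significant but not a consensus gene
  expect_equal(sel$down, "C")  # D is consensus but fails the FDR cut
  empty <- structure(list(up = character(), down = character()),
                     class = "ConsensusSet")
  sel2 <- select_master_regulators(records, empty)
  expect_length(sel2$up, 0)
  expect_length(sel2$down, 0)
})

test_that("planted hubs are recovered on the small synthetic study", {
  study <- simulate_study(tiny_config())
  truth <- study$truth
  bg <- study$gene_universe
  rec <- piea_scan(study$network, c(truth$planted_up, truth$planted_down), bg)
  hits <- rec$gene_id[rec$fdr < 0.05]
  expect_true(all(truth$planted_hubs %in% hits))
})
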