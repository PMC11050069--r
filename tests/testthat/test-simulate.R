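test_that("invalid configurations are rejected with validation errors", {
  expect_error(simulation_config(n_genes = 100, n_planted_up = 40,
                                 n_planted_down = 40, cohort_noise_degs = 20,
                                 n_cohorts = 2),
               "exceed", class = "ploidysig_validation_error")
  expect_error(simulation_config(samples_per_group = 1),
               class = "ploidysig_validation_error")
  expect_error(simulation_config(platform_kinds = "microarray"),
               class = "ploidysig_validation_error")
  expect_error(tiny_config(network_params = list(attachment = 2,
                                                 n_planted_hubs = 2,
                                                 hub_neighborhood_size = 10000,
                                                 hub_deg_fraction = 0.5)),
               "hub_neighborhood_size", class = "ploidysig_validation_error")
})

test_that("simulation is deterministic under a fixed seed, byte for byte", {
  s1 <- simulate_study(tiny_config(seed = 5))
  s2 <- simulate_study(tiny_config(seed = 5))
  expect_identical(s1$datasets[[2]]$matrix, s2$datasets[[2]]$matrix)
  expect_identical(igraph::as_edgelist(s1$network),
                   igraph::as_edgelist(s2$network))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  s3 <- simulate_study(tiny_config(seed = 6))
  expect_false(identical(s1$datasets[[1]]$matrix, s3$datasets[[1]]$matrix))
})

test_that("planted structure respects its declared invariants", {
  study <- simulate_study(tiny_config())
  truth <- study$truth
  cfg <- study$config
  expect_length(intersect(truth$planted_up, truth$planted_down), 0)
  expect_length(truth$planted_up, cfg$n_planted_up)
  all_noise <- unlist(truth$noise_degs)
  expect_false(anyDuplicated(all_noise) > 0)
  expect_length(intersect(all_noise, c(truth$planted_up, truth$planted_down)),
                0)
  expect_true(all(truth$planted_hubs %in%
                    c(truth$planted_up, truth$planted_down)))
  # counts cohorts are integer and non-negative
  for (i in seq_along(study$datasets)) {
    if (cfg$platform_kinds[i] == "counts") {
      expect_true(all(study$datasets[[i]]$matrix >= 0))
    }
  }
})

test_that("mouse cohorts are only resolvable through the ortholog map", {
  study <- simulate_study(tiny_config())
  mouse_idx <- which(study$config$species == "mouse")[1]
  ds <- study$datasets[[mouse_idx]]
  expect_true(all(grepl("^MMG", rownames(ds$matrix))))
  mapped <- apply_orthologs(ds, study$ortholog_map, "human")
  expect_true(all(grepl("^HSG", rownames(mapped$matrix))))
  # planted genes always survive the 1:1 restriction
  expect_true(all(study$truth$planted_up %in% rownames(mapped$matrix)))
})

test_that("planted genes stochastically dominate null genes in evidence", {
  study <- simulate_study(tiny_config(seed = 3))
  truth <- study$truth
  for (ds in study$datasets) {
    res <- cohort_differential(apply_orthologs(ds, study$ortholog_map,
                                               "human"))
    planted <- res$p[res$gene_id %in% c(truth$planted_up, truth$planted_down)]
    nulls <- res$p[!res$gene_id %in% c(truth$planted_up, truth$planted_down,
                                       unlist(truth$noise_degs))]
    w <- stats::wilcox.test(planted, nulls, alternative = "less")
    expect_lt(w$p.value, 1e-10)
  }
})

test_that("a zero effect size leaves consensus recovery at the noise floor", {
  study <- simulate_study(tiny_config(seed = 9, effect_size = 0))
  res <- lapply(study$datasets, function(ds) {
    cohort_differential(apply_orthologs(ds, study$ortholog_map, "human"))
  })
  cons <- call_consensus(build_direction_matrix(res))
  planted <- c(study$truth$planted_up, study$truth$planted_down)
  expect_lte(length(intersect(c(cons$up, cons$down), planted)), 1)
})

test_that("network wiring gives hubs the requested DEG-rich neighborhoods", {
  study <- simulate_study(tiny_config())
  truth <- study$truth
  np <- study$config$network_params
  for (h in truth$hubs_up) {
    nb <- neighborhood(study$network, h)
    expect_length(nb, np$hub_neighborhood_size)
    expect_gt(length(nb), 5)
    frac <- mean(nb %in% truth$planted_up)
    expect_lt(abs(frac - np$hub_deg_fraction), 0.06)
  }
  deg_tab <- igraph::degree(study$network)
  expect_true(all(deg_tab[truth$planted_hubs] > 5))
})

test_that("signature collection plants enrichment where declared", {
  study <- simulate_study(tiny_config())
  truth <- study$truth
  planted <- c(truth$planted_up, truth$planted_down)
  frac <- study$config$signature_params$enrichment_fraction
  for (nm in truth$enriched_signatures) {
    obs <- mean(study$signatures[[nm]] %in% planted)
    expect_gte(obs, frac - 0.06)
  }
  null_names <- setdiff(names(study$signatures), truth$enriched_signatures)
  null_frac <- mean(unlist(study$signatures[null_names]) %in% planted)
  expect_lt(null_frac, 0.2)

  # a signature equal to the planted up set ranks first
  sigs <- study$signatures
  sigs2 <- signature_collection(c(unclass(sigs),
                                  list(EXACT_COPY = truth$planted_up)))
  tab <- enrich(truth$planted_up, sigs2, study$gene_universe)
  expect_equal(tab$signature[1], "EXACT_COPY")
})
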