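# Small study layout used by module tests; the acceptance tests use the
# package defaults instead.
tiny_config <- function(seed = 42, ...) {
  base <- list(
    n_cohorts = 3,
    n_genes = 300,
    samples_per_group = 4,
    n_planted_up = 15,
    n_planted_down = 15,
    effect_size = 2,
    cohort_noise_degs = 20,
    platform_kinds = c("intensity", "counts", "counts"),
    species = c("human", "mouse", "human"),
    network_params = list(attachment = 2, n_planted_hubs = 6,
                          hub_neighborhood_size = 12, hub_deg_fraction = 0.8),
    signature_params = list(n_signatures = 40, size_range = c(10, 40),
                            n_enriched = 4, enrichment_fraction = 0.5),
    n_validation_cohorts = 1,
    seed = seed
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  do.call(simulation_config, base)
}

# A deterministic toy ExpressionDataset.
toy_dataset <- function(values = NULL, platform = "intensity", n_genes = 4,
                        n_per_group = 2) {
  m <- matrix(if (is.null(values)) seq_len(n_genes * 2 * n_per_group)
              else values,
              nrow = n_genes,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", seq_len(2 * n_per_group))))
  expression_dataset(m,
                     rep(c("diploid", "polyploid"), each = n_per_group),
                     platform = platform)
}

# Graph from a two-column edge matrix of gene names.
toy_graph <- function(edges) {
  igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
}

# A clique on the given gene names, as an edge data frame.
clique_edges <- function(genes) {
  t(utils::combn(genes, 2))
}
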