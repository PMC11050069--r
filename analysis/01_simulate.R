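#!/usr/bin/env Rscript
# Stage 1: generate the synthetic five-cohort ploidy study and write every
# input table (expression, metadata, orthologs, network, signatures, truth)
# under results/study/inputs/.

suppressPackageStartupMessages(library(ploidysig))

seed <- 1
dir.create("results/study", recursive = TRUE, showWarnings = FALSE)

config <- simulation_config(seed = seed)
study <- simulate_study(config)
write_simulation(study, "results/study/inputs")

cat(sprintf("Simulated %d cohorts of %d genes (%d + %d samples each),\n",
            config$n_cohorts, config$n_genes,
            config$samples_per_group, config$samples_per_group))
cat(sprintf("platforms: %s; species: %s.\n",
            paste(config$platform_kinds, collapse = "/"),
            paste(config$species, collapse = "/")))
cat(sprintf("Planted: %d up + %d down consensus genes (log2 effect %.1f),\n",
            config$n_planted_up, config$n_planted_down, config$effect_size))
cat(sprintf("%d noise DEGs per cohort, %d hub regulators, %d enriched of %d signatures.\n",
            config$cohort_noise_degs,
            length(study$truth$planted_hubs),
            length(study$truth$enriched_signatures),
            config$signature_params$n_signatures))
cat(sprintf("Network: %d nodes, %d edges.\n",
            igraph::vcount(study$network), igraph::ecount(study$network)))
cat("Inputs written to results/study/inputs/\n")
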