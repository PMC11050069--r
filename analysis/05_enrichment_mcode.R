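#!/usr/bin/env Rscript
# Stage 5: signature over-representation of the consensus sets (cumulative
# hypergeometric p, BH FDR, O/E ratio; reported at FDR < 0.01 and O/E > 1.5
# against the whole-genome background) and MCODE complex extraction from
# the consensus-induced subgraph of the interaction network.

suppressPackageStartupMessages(library(ploidysig))

outdir <- "results/study"
signatures <- read_gmt("results/study/inputs/signatures.gmt")
universe <- read_gene_set("results/study/inputs/gene_universe.tsv")
network <- read_edge_list("results/study/inputs/network_edges.tsv")
cons_up <- read_gene_set(file.path(outdir, "consensus_up.tsv"))
cons_down <- read_gene_set(file.path(outdir, "consensus_down.tsv"))

for (dir in c("up", "down")) {
  query <- if (dir == "up") cons_up else cons_down
  tab <- enrich(query, signatures, universe)
  write_enrichment_report(tab, file.path(outdir, paste0("enrichment_", dir, ".tsv")))
  write_enrichment_report(tab, file.path(outdir,
                                         paste0("enrichment_", dir, "_full.tsv")),
                          filtered = FALSE)
  sel <- tab[tab$selected, ]
  cat(sprintf("Consensus %s (%d genes): %d/%d signatures pass FDR<0.01 & O/E>1.5\n",
              dir, length(query), nrow(sel), nrow(tab)))
  if (nrow(sel) > 0) {
    top <- sel[1, ]
    cat(sprintf("  top: %s (k=%d, O/E=%.2f, FDR=%.2e)\n",
                top$signature, top$k, top$oe_ratio, top$fdr))
  }
}

deg_graph <- induced_subgraph_genes(network, c(cons_up, cons_down))
complexes <- mcode(deg_graph)
write_mcode_report(complexes, file.path(outdir, "mcode_complexes.tsv"))
cat(sprintf("MCODE: %d complex(es) in the %d-node consensus subgraph\n",
            length(complexes), igraph::vcount(deg_graph)))
for (i in seq_along(complexes)) {
  cx <- complexes[[i]]
  cat(sprintf("  complex %d: %d genes, score %.2f (seed %s)\n",
              i, length(cx$members), cx$score, cx$seed))
  ctab <- enrich(cx$members, signatures, universe)
  csel <- ctab[ctab$selected, ]
  if (nrow(csel) > 0) {
    cat(sprintf("    enriched in %d signature(s); best %s (FDR=%.2e)\n",
                nrow(csel), csel$signature[1], csel$fdr[1]))
  }
}
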