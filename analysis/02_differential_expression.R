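#!/usr/bin/env Rscript
# Stage 2: per-cohort differential expression, polyploid vs diploid.
# Reads the stage-1 TSVs back through the package readers, translates mouse
# cohorts into the human namespace via the 1:1 ortholog map, quantile
# normalizes and applies the moderated t-test, then writes one DEG table
# per cohort under results/study/.

suppressPackageStartupMessages(library(ploidysig))

indir <- "results/study/inputs"
outdir <- "results/study"
platforms <- c("intensity", "counts", "intensity", "counts", "counts")
species <- c("human", "mouse", "mouse", "human", "human")

orthologs <- read_ortholog_map(file.path(indir, "orthologs.tsv"))

for (i in seq_along(platforms)) {
  nm <- sprintf("cohort%d", i)
  ds <- read_expression(file.path(indir, paste0(nm, "_expression.tsv")),
                        file.path(indir, paste0(nm, "_samples.tsv")),
                        platform = platforms[i], species = species[i])
  ds <- apply_orthologs(ds, orthologs, "human")
  res <- cohort_differential(ds)
  degs <- select_degs(res)
  write.table(res, file.path(outdir, paste0("deg_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s (%s, %s): %d genes tested, %d up, %d down (p<0.05, FDR<0.1)\n",
              nm, platforms[i], species[i], nrow(res),
              length(degs$up), length(degs$down)))
}
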