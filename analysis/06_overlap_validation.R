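#!/usr/bin/env Rscript
# Stage 6: external validation. The held-out cohort plays the role of an
# independent ploidy-affected dataset: its own DEG lists are matched
# direction-concordantly against the consensus signature and the overlaps
# scored by the hypergeometric tail on the shared tested universe.

suppressPackageStartupMessages(library(ploidysig))

outdir <- "results/study"
indir <- "results/study/inputs"

val <- read_expression(file.path(indir, "validation1_expression.tsv"),
                       file.path(indir, "validation1_samples.tsv"),
                       platform = "counts", species = "human")
vres <- cohort_differential(val)
vdeg <- select_degs(vres)
cat(sprintf("Validation cohort: %d genes tested, %d up, %d down\n",
            nrow(vres), length(vdeg$up), length(vdeg$down)))

cons <- structure(list(
  up = read_gene_set(file.path(outdir, "consensus_up.tsv")),
  down = read_gene_set(file.path(outdir, "consensus_down.tsv"))),
  class = "ConsensusSet")
dmat <- read.delim(file.path(outdir, "direction_matrix.tsv"),
                   stringsAsFactors = FALSE)
universe <- intersect(dmat$gene_id, vres$gene_id)

ov <- match_signature(cons, vdeg$up, vdeg$down, universe)
print(ov)
write_gene_set(ov$matched_up, file.path(outdir, "overlap_matched_up.tsv"))
write_gene_set(ov$matched_down, file.path(outdir, "overlap_matched_down.tsv"))
cat(sprintf("Matched %d/%d up and %d/%d down consensus genes in the external cohort\n",
            ov$n_matched_up, length(cons$up),
            ov$n_matched_down, length(cons$down)))
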