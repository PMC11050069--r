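#!/usr/bin/env Rscript
# Stage 3: sign-consistent consensus across all cohorts. A gene enters the
# consensus up (down) set only if it is called up (down) in every cohort;
# the universe is restricted to genes testable in all cohorts.

suppressPackageStartupMessages(library(ploidysig))

outdir <- "results/study"
deg_files <- sort(list.files(outdir, pattern = "^deg_cohort\\d+\\.tsv$",
                             full.names = TRUE))
results <- lapply(deg_files, read.delim, stringsAsFactors = FALSE)
names(results) <- sub("^deg_", "", sub("\\.tsv$", "", basename(deg_files)))

dmat <- build_direction_matrix(results)
cons <- call_consensus(dmat)

write.table(data.frame(gene_id = rownames(dmat), unclass(dmat),
                       check.names = FALSE),
            file.path(outdir, "direction_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gene_set(cons$up, file.path(outdir, "consensus_up.tsv"))
write_gene_set(cons$down, file.path(outdir, "consensus_down.tsv"))

cat(sprintf("Universe testable in all %d cohorts: %d genes\n",
            cons$n_cohorts, nrow(dmat)))
cat(sprintf("Consensus: %d induced, %d suppressed genes\n",
            length(cons$up), length(cons$down)))

truth_up <- read_gene_set("results/study/inputs/truth_planted_up.tsv")
truth_down <- read_gene_set("results/study/inputs/truth_planted_down.tsv")
cat(sprintf("Recovery of planted signal: up %d/%d, down %d/%d\n",
            length(intersect(cons$up, truth_up)), length(truth_up),
            length(intersect(cons$down, truth_down)), length(truth_down)))
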