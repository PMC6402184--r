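#!/usr/bin/env Rscript
## Stage 7: hypergeometric over-representation of the predicted target
## genes in the annotated gene sets (screen: p < 0.05).

library(lincnet)

targets <- read.delim("results/targets.tsv")
sets <- read_gmt("results/data/gene_sets.gmt")
universe <- as.character(sets$background)
enr <- enrich(unique(targets$gene_id), sets, universe = universe)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("top set: %s (k=%d/%d, p=%.3g)\n",
            enr$set[1], enr$k[1], enr$K[1], enr$p[1]))
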