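#!/usr/bin/env Rscript
## Stage 6: consensus-voted miRNA binding (seed class, duplex energy,
## AU context; 2-of-3 for lncRNA-miRNA, 3-of-3 for miRNA-mRNA) and
## direction-consistent ceRNA triads.

library(lincnet)

mirnas <- read_rna_fasta("results/data/mirnas.fa")
tx <- read_rna_fasta("results/data/transcripts.fa")
lnc <- tx[grep("^lnc_", names(tx))]
mrna <- tx[grep("^mrna_", names(tx))]

## DE directions from the matched count simulation for these transcripts.
fx <- cerna_fixture(seed = 7)
de <- run_de(directed_counts(fx$directions, seed = 7))

lnc_edges <- predict_binding(mirnas, lnc, k = 2)
mrna_edges <- predict_binding(mirnas, mrna, k = 3)
triads <- assemble_triads(de, lnc_edges, mrna_edges, mode = "strict")

write.table(lnc_edges, "results/cerna_lnc_mir_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mrna_edges, "results/cerna_mir_mrna_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(triads, "results/cerna_triads.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("strict ceRNA triads: %d\n", nrow(triads)))
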