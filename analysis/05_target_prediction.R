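#!/usr/bin/env Rscript
## Stage 5: cis targets (within 10 kb of the lincRNA locus) and trans
## targets (base-pairing score >= 60), restricted to DE genes.

library(lincnet)

ann <- read_annotation_gtf("results/data/annotation.gtf")
lincs <- ann[ann$biotype == "lincRNA", , drop = FALSE]
genes <- ann[ann$biotype == "protein_coding", , drop = FALSE]
tpf <- trans_pair_fixture(seed = 7)
targets <- predict_targets(lincs, genes,
                           linc_seqs = setNames(tpf$linc_seq, lincs$id[1]),
                           gene_seqs = setNames(tpf$mrna_seq, genes$id[1]),
                           de_genes = genes$id, window = 10000,
                           trans_threshold = 60)
write.table(targets, "results/targets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("targets: %d links (%s)\n", nrow(targets),
            paste(sprintf("%s %s", targets$gene_id, targets$mode),
                  collapse = ", ")))
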