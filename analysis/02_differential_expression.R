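#!/usr/bin/env Rscript
## Stage 2: Audic-Claverie differential expression on pooled libraries,
## with class-specific screening (|log2fc| >= 1; q < 0.001 for lncRNA and
## mRNA, q < 0.05 for miRNA).

library(lincnet)

feat <- read.delim("results/data/features.tsv")
cm <- read_counts_tsv("results/data/counts.tsv", "results/data/samples.tsv",
                      feature_class = feat$class,
                      feature_length = feat$length)
de <- run_de(cm)
write.table(de, "results/de_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("DE calls: %d up, %d down of %d features\n",
            sum(de$direction == "up"), sum(de$direction == "down"),
            nrow(de)))
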