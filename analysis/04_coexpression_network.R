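#!/usr/bin/env Rscript
## Stage 4: lincRNA-mRNA Pearson coexpression network on log2 RPKM,
## keeping edges with |r| >= 0.85.

library(lincnet)

feat <- read.delim("results/data/coexpr_features.tsv")
cm <- read_counts_tsv("results/data/coexpr_counts.tsv",
                      "results/data/coexpr_samples.tsv",
                      feature_class = feat$class,
                      feature_length = feat$length)
expr <- log2(t(t(cm$counts) / cm$samples$library_size) * 1e9 /
               cm$features$length + 0.1)
is_lnc <- cm$features$class == "lncRNA"
is_mrna <- cm$features$class == "mRNA"
net <- build_network(expr[is_lnc, , drop = FALSE],
                     expr[is_mrna, , drop = FALSE], threshold = 0.85)
write.table(net$edges, "results/coexpr_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_sif(net$edges, "results/coexpr_network.sif")

cat(sprintf("network: %d edges between %d lincRNAs and %d mRNAs\n",
            nrow(net$edges), length(unique(net$edges$linc_id)),
            length(unique(net$edges$mrna_id))))
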