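#!/usr/bin/env Rscript
## Stage 1: generate every synthetic input for the demo analysis.
## All computation lives in the lincnet package; this script only calls it
## and writes files under results/data/.

library(lincnet)

seed <- 7
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

## Count experiment with planted differential expression (5 vs 5 pooled).
cfg <- sim_config(seed = seed, n_lncrna = 100, n_mirna = 30, n_mrna = 200,
                  n_samples_per_group = 5, de_fraction = 0.1,
                  planted_log2fc = 2, nb_dispersion = 0,
                  baseline_mean = 100)
sim <- simulate_counts(cfg)
write_counts_tsv(sim$counts, "results/data/counts.tsv",
                 "results/data/samples.tsv")
write.table(data.frame(feature_id = sim$counts$features$feature_id,
                       class = sim$counts$features$class,
                       length = sim$counts$features$length),
            "results/data/features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_manifest_yaml(sim$truth, "results/data/truth.yaml")

## Separate experiment with a planted coexpression module (30 vs 30,
## fixed library size so RPKM is comparable across samples).
ccfg <- sim_config(seed = seed + 1, n_lncrna = 30, n_mirna = 2, n_mrna = 80,
                   n_samples_per_group = 30, de_fraction = 0,
                   baseline_mean = 1000, nb_dispersion = 0.1,
                   fixed_library_size = 1e6,
                   module_specs = list(list(size = 20,
                                            latent_correlation = 0.95)))
csim <- simulate_counts(ccfg)
write_counts_tsv(csim$counts, "results/data/coexpr_counts.tsv",
                 "results/data/coexpr_samples.tsv")
write.table(data.frame(feature_id = csim$counts$features$feature_id,
                       class = csim$counts$features$class,
                       length = csim$counts$features$length),
            "results/data/coexpr_features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_manifest_yaml(csim$truth, "results/data/coexpr_truth.yaml")

## Toy genome annotation with cis pairs at known gaps, plus the gene sets
## used by the enrichment stage.
acfg <- sim_config(seed = seed,
                   cis_pair_specs = list(list(gap_bp = 5000),
                                         list(gap_bp = 9900),
                                         list(gap_bp = 15000)))
ann <- simulate_annotation(acfg)
write_annotation_gtf(ann$features, "results/data/annotation.gtf")
genes <- ann$features$id[ann$features$biotype == "protein_coding"]
write_gmt(list(cis_module = ann$truth$cis_pairs$gene_id,
               background = genes),
          "results/data/gene_sets.gmt")

## Sequences with planted miRNA binding sites for the ceRNA stage.
fx <- cerna_fixture(seed = seed)
write_rna_fasta(fx$seqs$mirnas, "results/data/mirnas.fa")
write_rna_fasta(fx$seqs$transcripts, "results/data/transcripts.fa")

cat("simulated inputs written to results/data/\n")
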