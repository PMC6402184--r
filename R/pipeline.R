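## End-to-end orchestration of the synthetic demo analysis: simulate ->
## differential expression -> novel-lncRNA cascade -> coexpression ->
## target prediction -> ceRNA triads -> enrichment, with deterministic
## outputs and a machine-readable run manifest.

#' Pipeline configuration with the study's screening standards as defaults
#'
#' @param seed Integer seed driving every stage.
#' @param out_dir Output directory (created if missing).
#' @param de_thresholds Screening standards per class
#'   (\code{\link{de_thresholds}}: |log2fc| >= 1; q < 0.001 for
#'   lncRNA/mRNA, q < 0.05 for miRNA).
#' @param min_length,max_orf,cp_threshold Novel-lncRNA cascade gates
#'   (length >= 200 nt, ORF < 300 nt, coding potential < -1).
#' @param cor_threshold Coexpression screen (|r| > 0.85 is the retention
#'   rule; edges with |r| >= this value are kept).
#' @param cis_window Cis target window in bp (10 kb).
#' @param trans_threshold Minimum trans pairing score.
#' @param votes_lnc_mir,votes_mir_mrna Consensus votes required (2-of-3
#'   and 3-of-3).
#' @param enrich_alpha Enrichment screen (p < 0.05).
#' @param n_lncrna,n_mirna,n_mrna,n_samples_per_group,de_fraction,planted_log2fc,nb_dispersion,baseline_mean
#'   Demo simulation settings (see \code{\link{sim_config}}).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 7, out_dir = tempfile("lincnet_run_"),
                            de_thresholds = lincnet::de_thresholds(),
                            min_length = 200, max_orf = 300,
                            cp_threshold = -1,
                            cor_threshold = 0.85, cis_window = 10000,
                            trans_threshold = 60,
                            votes_lnc_mir = 2, votes_mir_mrna = 3,
                            enrich_alpha = 0.05,
                            n_lncrna = 100, n_mirna = 30, n_mrna = 200,
                            n_samples_per_group = 5, de_fraction = 0.1,
                            planted_log2fc = 2, nb_dispersion = 0,
                            baseline_mean = 100) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

## Small deterministic fingerprint of a configuration (polynomial rolling
## hash; only used to stamp the run manifest).
config_hash <- function(obj) {
  s <- paste(deparse(obj, control = "all"), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%d", h)
}

write_stage_tsv <- function(df, path, header_comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in header_comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic demo pipeline
#'
#' Generates the demo inputs from the config seed and runs every stage,
#' writing TSV/SIF/GTF/FASTA/YAML outputs plus a run manifest (config
#' hash, package version, seed, file list) under \code{out_dir}.  Identical
#' configs produce byte-identical outputs.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with every stage's in-memory result and the
#'   output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(file.path(out, "data"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(out, name)
    paths <<- c(paths, name)
    p
  }

  ## --- simulate the count experiment and call differential expression
  scfg <- sim_config(seed = config$seed,
                     n_lncrna = config$n_lncrna, n_mirna = config$n_mirna,
                     n_mrna = config$n_mrna,
                     n_samples_per_group = config$n_samples_per_group,
                     de_fraction = config$de_fraction,
                     planted_log2fc = config$planted_log2fc,
                     nb_dispersion = config$nb_dispersion,
                     baseline_mean = config$baseline_mean)
  sim <- simulate_counts(scfg)
  write_counts_tsv(sim$counts, emit("data/counts.tsv"),
                   emit("data/samples.tsv"))
  write_manifest_yaml(sim$truth, emit("data/truth.yaml"))
  de <- run_de(sim$counts, thresholds = config$de_thresholds)
  rec <- de_recovery(de, sim$truth)
  write_stage_tsv(de, emit("de_table.tsv"), c(
    sprintf("screening: |log2fc| >= 1; q < %g (lncRNA/mRNA), q < %g (miRNA)",
            config$de_thresholds$lncRNA$q, config$de_thresholds$miRNA$q),
    sprintf("planted-truth recovery: sensitivity %.3f, FDR %.3f",
            rec$sensitivity, rec$fdr)))

  ## --- novel-lncRNA cascade on the engineered fixture
  model <- toy_cp_model(seed = 101)
  fx <- novel_cascade_fixture(model, seed = config$seed)
  verdicts <- filter_cascade(fx$transcripts, model,
                             tx_coords = fx$tx_coords, known = fx$known,
                             min_length = config$min_length,
                             max_orf = config$max_orf,
                             cp_threshold = config$cp_threshold,
                             patterns = fx$patterns)
  write_stage_tsv(verdicts, emit("novel_verdicts.tsv"), sprintf(
    "gates: length >= %d nt, ORF < %d nt, coding potential < %g",
    config$min_length, config$max_orf, config$cp_threshold))

  ## --- coexpression network on a planted-module simulation
  ccfg <- sim_config(seed = config$seed + 1, n_lncrna = 30, n_mirna = 2,
                     n_mrna = 80, n_samples_per_group = 30,
                     de_fraction = 0, baseline_mean = 1000,
                     nb_dispersion = 0.1, fixed_library_size = 1e6,
                     module_specs = list(list(size = 20,
                                              latent_correlation = 0.95)))
  csim <- simulate_counts(ccfg)
  expr <- log2(t(t(csim$counts$counts) /
                   csim$counts$samples$library_size) * 1e9 /
               csim$counts$features$length + 0.1)
  is_lnc <- csim$counts$features$class == "lncRNA"
  is_mrna <- csim$counts$features$class == "mRNA"
  net <- build_network(expr[is_lnc, , drop = FALSE],
                       expr[is_mrna, , drop = FALSE],
                       threshold = config$cor_threshold)
  write_stage_tsv(net$edges, emit("coexpr_edges.tsv"),
                  sprintf("screen: |r| >= %g", config$cor_threshold))
  write_sif(net$edges, emit("coexpr_network.sif"))

  ## --- cis/trans target prediction on the toy genome
  acfg <- sim_config(seed = config$seed,
                     cis_pair_specs = list(list(gap_bp = 5000),
                                           list(gap_bp = 9900),
                                           list(gap_bp = 15000)),
                     cis_window = config$cis_window)
  ann <- simulate_annotation(acfg)
  write_annotation_gtf(ann$features, emit("data/annotation.gtf"))
  tpf <- trans_pair_fixture(seed = config$seed)
  lincs <- ann$features[ann$features$biotype == "lincRNA", , drop = FALSE]
  genes <- ann$features[ann$features$biotype == "protein_coding", ,
                        drop = FALSE]
  targets <- suppressMessages(predict_targets(
    lincs, genes,
    linc_seqs = setNames(tpf$linc_seq, lincs$id[1]),
    gene_seqs = setNames(tpf$mrna_seq, genes$id[1]),
    de_genes = genes$id, window = config$cis_window,
    trans_threshold = config$trans_threshold, restrict_to_de = TRUE))
  write_stage_tsv(targets, emit("targets.tsv"), sprintf(
    "cis window: %d bp; trans score >= %g", config$cis_window,
    config$trans_threshold))

  ## --- ceRNA triads from planted sites, with DE directions re-derived
  ## from a matched count simulation
  cefx <- cerna_fixture(seed = config$seed)
  cecm <- directed_counts(cefx$directions, seed = config$seed)
  cede <- run_de(cecm, thresholds = config$de_thresholds)
  lnc_seqs <- cefx$seqs$transcripts[grep("^lnc_",
                                         names(cefx$seqs$transcripts))]
  mrna_seqs <- cefx$seqs$transcripts[grep("^mrna_",
                                          names(cefx$seqs$transcripts))]
  lnc_edges <- predict_binding(cefx$seqs$mirnas, lnc_seqs,
                               k = config$votes_lnc_mir)
  mrna_edges <- predict_binding(cefx$seqs$mirnas, mrna_seqs,
                                k = config$votes_mir_mrna)
  triads <- assemble_triads(cede, lnc_edges, mrna_edges, mode = "strict")
  write_rna_fasta(cefx$seqs$mirnas, emit("data/mirnas.fa"))
  write_rna_fasta(cefx$seqs$transcripts, emit("data/transcripts.fa"))
  write_stage_tsv(lnc_edges, emit("cerna_lnc_mir_edges.tsv"),
                  sprintf("consensus: >= %d of 3 votes",
                          config$votes_lnc_mir))
  write_stage_tsv(mrna_edges, emit("cerna_mir_mrna_edges.tsv"),
                  sprintf("consensus: >= %d of 3 votes",
                          config$votes_mir_mrna))
  write_stage_tsv(triads, emit("cerna_triads.tsv"),
                  "mode: strict (sign(lncRNA) = sign(mRNA) = -sign(miRNA))")
  write_sif(triads[, c("lncrna", "mirna")], emit("cerna_triads.sif"),
            relation = "lnc_mir")

  ## --- enrichment of the cis/trans target genes
  universe <- genes$id
  gene_sets <- list(cis_module = ann$truth$cis_pairs$gene_id,
                    background = universe)
  enr <- enrich(unique(targets$gene_id), gene_sets, universe = universe,
                alpha = config$enrich_alpha)
  write_stage_tsv(enr, emit("enrichment.tsv"),
                  sprintf("screen: p < %g", config$enrich_alpha))

  ## --- run manifest
  hashed <- unclass(config)
  hashed$out_dir <- NULL  # location is not part of the scientific config
  manifest <- list(config_hash = config_hash(hashed),
                   package = as.character(utils::packageVersion("lincnet")),
                   seed = config$seed, outputs = as.list(sort(paths)))
  yaml::write_yaml(manifest, file.path(out, "run_manifest.yaml"))

  invisible(list(de = de, de_recovery = rec, verdicts = verdicts,
                 network = net, targets = targets, triads = triads,
                 enrichment = enr, truth = list(counts = sim$truth,
                                                coexpr = csim$truth,
                                                annotation = ann$truth,
                                                cerna = cefx),
                 out_dir = out, files = sort(paths)))
}
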