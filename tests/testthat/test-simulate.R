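test_that("count simulation plants exactly the configured DE fraction", {
  cfg <- sim_config(seed = 3, n_lncrna = 500, n_mirna = 100, n_mrna = 400,
                    n_samples_per_group = 2, de_fraction = 0.1)
  sim <- simulate_counts(cfg)
  expect_equal(nrow(sim$truth$de), 100)         # 50 + 10 + 40
  expect_equal(sort(unique(abs(sim$truth$de$log2fc))), 2)
  expect_equal(nrow(sim$counts$counts), 1000)
})

test_that("zero planted effect gives an empty DE manifest", {
  cfg <- sim_config(seed = 3, n_lncrna = 20, n_mirna = 5, n_mrna = 20,
                    de_fraction = 0.2, planted_log2fc = 0)
  expect_equal(nrow(simulate_counts(cfg)$truth$de), 0)
})

test_that("the generator is deterministic and restores the RNG state", {
  cfg <- sim_config(seed = 9, n_lncrna = 10, n_mirna = 5, n_mrna = 10)
  set.seed(77)
  before <- .Random.seed
  s1 <- simulate_counts(cfg)
  expect_identical(.Random.seed, before)  # caller RNG untouched
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth$de, s2$truth$de)
})

test_that("fixed_library_size is recorded instead of panel sums", {
  cfg <- sim_config(seed = 4, n_lncrna = 5, n_mirna = 2, n_mrna = 5,
                    fixed_library_size = 1e6)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$counts$samples$library_size == 1e6))
  cfg2 <- sim_config(seed = 4, n_lncrna = 5, n_mirna = 2, n_mrna = 5)
  sim2 <- simulate_counts(cfg2)
  expect_equal(sim2$counts$samples$library_size,
               unname(colSums(sim2$counts$counts)))
})

test_that("configuration errors are reported as such", {
  expect_error(sim_config(de_fraction = 1.5), "configuration error")
  expect_error(sim_config(nb_dispersion = -1), "configuration error")
  expect_error(sim_config(baseline_mean = 0), "configuration error")
  expect_error(sim_config(fixed_library_size = -5), "configuration error")
  expect_error(sim_config(module_specs = list(list(size = 0,
                                                   latent_correlation = 0.9))),
               "configuration error")
  expect_error(sim_config(module_specs = list(list(size = 5,
                                                   latent_correlation = 1))),
               "configuration error")
  expect_error(sim_config(site_specs = list(list(mirna = "m", transcript = "t",
                                                 site_type = "9mer"))),
               "configuration error")
  expect_error(simulate_counts(sim_config(
    n_lncrna = 2, n_mrna = 3, de_fraction = 1,
    module_specs = list(list(size = 3, latent_correlation = 0.9)))),
    "configuration error")
})

test_that("annotation plants cis pairs at the requested gaps", {
  cfg <- sim_config(seed = 2, cis_pair_specs = list(list(gap_bp = 5000),
                                                    list(gap_bp = 15000)))
  ann <- simulate_annotation(cfg)
  tp <- ann$truth$cis_pairs
  expect_equal(tp$gap_bp, c(5000, 15000))
  expect_equal(tp$planted_positive, c(TRUE, FALSE))  # 15000 > 10-kb window
  # realized genomic gap equals the requested one
  f <- ann$features
  for (i in seq_len(nrow(tp))) {
    linc <- f[f$id == tp$linc_id[i], ]
    gene <- f[f$id == tp$gene_id[i], ]
    expect_equal(gene$start - linc$end, tp$gap_bp[i])
  }
  # background features are isolated beyond the window from everything
  empty <- simulate_annotation(sim_config(seed = 2))
  expect_equal(nrow(empty$truth$cis_pairs), 0)
})

test_that("annotation round-trips through GTF", {
  cfg <- sim_config(seed = 2, cis_pair_specs = list(list(gap_bp = 800)))
  ann <- simulate_annotation(cfg)
  path <- tempfile(fileext = ".gtf")
  write_annotation_gtf(ann$features, path)
  back <- read_annotation_gtf(path)
  m <- match(ann$features$id, back$id)
  expect_false(anyNA(m))
  expect_equal(back$start[m], ann$features$start)
  expect_equal(back$end[m], ann$features$end)
  expect_equal(back$strand[m], ann$features$strand)
  expect_equal(back$biotype[m], ann$features$biotype)
  expect_error(read_annotation_gtf(tempfile(fileext = ".gtf")), "not found")
})

test_that("too small a genome is a configuration error", {
  cfg <- sim_config(seed = 2, genome_length = 1000,
                    cis_pair_specs = list(list(gap_bp = 5000)))
  expect_error(simulate_annotation(cfg), "configuration error")
})

test_that("planted seed sites are recovered at their recorded positions", {
  for (type in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    cfg <- sim_config(seed = 6, n_lncrna = 1, n_mirna = 1, n_mrna = 1,
                      transcript_length = 200,
                      site_specs = list(list(mirna = "mir_0001",
                                             transcript = "lnc_0001",
                                             site_type = type)))
    seqs <- simulate_sequences(cfg)
    site <- seqs$truth$sites
    expect_equal(nrow(site), 1)
    expect_equal(site$site_type, type)
    win <- substr(seqs$transcripts[["lnc_0001"]],
                  site$position + 1, site$position + 8)
    expect_equal(classify_seed_site(seqs$mirnas[["mir_0001"]], win), type)
  }
})

test_that("two planted sites on one transcript do not overlap", {
  cfg <- sim_config(seed = 8, n_lncrna = 1, n_mirna = 2, n_mrna = 1,
                    transcript_length = 300,
                    site_specs = list(
                      list(mirna = "mir_0001", transcript = "lnc_0001",
                           site_type = "8mer"),
                      list(mirna = "mir_0002", transcript = "lnc_0001",
                           site_type = "7mer-m8")))
  seqs <- simulate_sequences(cfg)
  s <- seqs$truth$sites
  expect_equal(nrow(s), 2)
  expect_gte(abs(s$position[1] - s$position[2]), 8)
  for (i in 1:2) {
    win <- substr(seqs$transcripts[["lnc_0001"]],
                  s$position[i] + 1, s$position[i] + 8)
    expect_equal(classify_seed_site(seqs$mirnas[[s$mirna[i]]], win),
                 s$site_type[i])
  }
})

test_that("no site_specs means an empty site manifest", {
  cfg <- sim_config(seed = 6, n_lncrna = 2, n_mirna = 2, n_mrna = 2,
                    transcript_length = 60)
  expect_equal(nrow(simulate_sequences(cfg)$truth$sites), 0)
})

test_that("exclude_chance_sites leaves only the planted sites", {
  cfg <- sim_config(seed = 7, n_lncrna = 3, n_mirna = 3, n_mrna = 4,
                    transcript_length = 120, exclude_chance_sites = TRUE,
                    site_specs = list(list(mirna = "mir_0001",
                                           transcript = "lnc_0001",
                                           site_type = "8mer")))
  seqs <- simulate_sequences(cfg)
  planted <- with(seqs$truth$sites, paste(mirna, transcript, position))
  for (mi in names(seqs$mirnas))
    for (ti in names(seqs$transcripts)) {
      hits <- scan_seed_sites(seqs$mirnas[[mi]], seqs$transcripts[[ti]])
      if (nrow(hits) > 0)
        expect_true(all(paste(mi, ti, hits$position) %in% planted))
    }
})

test_that("too short a transcript for a planted site errors cleanly", {
  cfg <- sim_config(seed = 6, n_lncrna = 1, n_mirna = 1, n_mrna = 1,
                    transcript_length = 12,
                    site_specs = list(list(mirna = "mir_0001",
                                           transcript = "lnc_0001",
                                           site_type = "8mer",
                                           supplementary = TRUE)))
  expect_error(simulate_sequences(cfg), "configuration error")
})

test_that("sequences round-trip through FASTA", {
  cfg <- sim_config(seed = 6, n_lncrna = 2, n_mirna = 2, n_mrna = 2,
                    transcript_length = 150)
  seqs <- simulate_sequences(cfg)
  path <- tempfile(fileext = ".fa")
  write_rna_fasta(seqs$transcripts, path)
  expect_identical(read_rna_fasta(path), seqs$transcripts)
  expect_error(read_rna_fasta(tempfile(fileext = ".fa")), "not found")
})

test_that("count matrices round-trip through TSV and pool correctly", {
  cfg <- sim_config(seed = 4, n_lncrna = 5, n_mirna = 2, n_mrna = 5)
  cm <- simulate_counts(cfg)$counts
  cp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  write_counts_tsv(cm, cp, sp)
  back <- read_counts_tsv(cp, sp, cm$features$class, cm$features$length)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$samples, cm$samples)

  pooled <- pool_samples(cm, cm$samples$group)
  expect_equal(unname(pooled$counts[, "case"]),
               unname(rowSums(cm$counts[, cm$samples$group == "case"])))
  expect_equal(sum(pooled$samples$library_size),
               sum(cm$samples$library_size))
  expect_error(pool_samples(cm, rep("p1", ncol(cm$counts))), "mixes")
})

test_that("count_matrix validates its inputs", {
  m <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(count_matrix(m, c("case", "treated"), c("mRNA", "mRNA"),
                            c(10, 10)), "case")
  expect_error(count_matrix(m - 5, c("case", "control"), c("mRNA", "mRNA"),
                            c(10, 10)), "non-negative")
  expect_error(count_matrix(unname(m), c("case", "control"),
                            c("mRNA", "mRNA"), c(10, 10)), "names")
})
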