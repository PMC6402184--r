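linc_row <- function(start, end, id = "linc1")
  data.frame(id = id, chrom = "c1", start = start, end = end, strand = "+",
             stringsAsFactors = FALSE)
gene_rows <- function(starts, ends, ids = sprintf("g%d", seq_along(starts)))
  data.frame(id = ids, chrom = "c1", start = starts, end = ends,
             strand = "+", stringsAsFactors = FALSE)

test_that("cis_neighbors applies the 10-kb rule with correct gaps", {
  linc <- linc_row(5000, 6000)
  inside <- cis_neighbors(linc, gene_rows(15900, 17000), 10000)
  expect_equal(inside$gene_id, "g1")       # 15900 <= 6000 + 10000
  expect_equal(inside$gap_bp, 9900)
  outside <- cis_neighbors(linc, gene_rows(16500, 17000), 10000)
  expect_equal(nrow(outside), 0)           # gap 10500 > 10000
  overlap <- cis_neighbors(linc, gene_rows(5500, 5600), 10000)
  expect_equal(overlap$gap_bp, 0)
  adjacent <- cis_neighbors(linc, gene_rows(6001, 7000), 10000)
  expect_equal(adjacent$gap_bp, 1)
  upstream <- cis_neighbors(linc, gene_rows(1000, 2000), 10000)
  expect_equal(upstream$gap_bp, 3000)
  expect_error(cis_neighbors(linc, gene_rows(1, 2), -1),
               "configuration error")
})

test_that("cis_neighbors equals the all-pairs interval oracle", {
  set.seed(41)
  for (i in 1:200) {
    linc <- linc_row(s <- sample(1e5, 1), s + sample(5000, 1))
    n <- sample(1:8, 1)
    gs <- sample(1e5, n)
    genes <- gene_rows(gs, gs + sample(5000, n, replace = TRUE))
    w <- sample(c(0, 100, 10000), 1)
    got <- cis_neighbors(linc, genes, w)
    expect_setequal(got$gene_id, cis_oracle(linc, genes, w))
    expect_true(all(got$gap_bp <= w))
  }
})

test_that("trans_score matches its closed-form cases", {
  mrna <- strrep("G", 15)
  window <- strrep("G", 30)
  mrna2 <- paste0(strrep("A", 10), window, strrep("A", 10))
  linc <- rna_revcomp(window)              # 30 C's
  ts <- trans_score(linc, mrna2)
  expect_equal(ts$score, 90)               # 30 GC pairs at +3
  expect_equal(ts$mrna_region, c(11, 40))
  expect_equal(ts$linc_region, c(1, 30))
  zero <- trans_score(strrep("A", 20), strrep("A", 20))
  expect_equal(zero$score, 0)              # A:A never pairs
  expect_null(zero$linc_region)
  expect_equal(trans_score("", "ACGU")$score, 0)
})

test_that("trans_score equals the quartic pairing oracle on short RNAs", {
  set.seed(42)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(5:12, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(5:12, 1),
                      replace = TRUE), collapse = "")
    expect_equal(trans_score(a, b)$score, trans_oracle(a, b))
  }
})

test_that("the planted trans fixture scores above threshold in its window", {
  tpf <- trans_pair_fixture(seed = 7)
  ts <- trans_score(tpf$linc_seq, tpf$mrna_seq)
  expect_gte(ts$score, 60)
  # the alignment covers the planted complementary window
  expect_lte(ts$mrna_region[1], tpf$window[1])
  expect_gte(ts$mrna_region[2], tpf$window[2] - 1)
})

test_that("predict_targets finds exactly the planted links", {
  cfg <- sim_config(seed = 2,
                    cis_pair_specs = list(list(gap_bp = 2000),
                                          list(gap_bp = 9900),
                                          list(gap_bp = 9999)),
                    n_background_lincs = 2, n_background_genes = 2)
  ann <- simulate_annotation(cfg)
  lincs <- ann$features[ann$features$biotype == "lincRNA", ]
  genes <- ann$features[ann$features$biotype == "protein_coding", ]
  # two planted trans complements between background lincs and genes
  set.seed(43)
  g1 <- random_rna(200); g2 <- random_rna(200)
  linc_seqs <- c(linc_bg_01 = paste0(random_rna(40),
                                     rna_revcomp(substr(g1, 51, 80)),
                                     random_rna(40)),
                 linc_bg_02 = paste0(random_rna(40),
                                     rna_revcomp(substr(g2, 101, 130)),
                                     random_rna(40)))
  gene_seqs <- c(gene_bg_01 = g1, gene_bg_02 = g2)
  out <- suppressMessages(predict_targets(
    lincs, genes, linc_seqs = linc_seqs, gene_seqs = gene_seqs,
    de_genes = genes$id))
  expect_equal(nrow(out), 5)
  cis <- out[out$mode == "cis", ]
  expect_setequal(paste(cis$linc_id, cis$gene_id),
                  paste(ann$truth$cis_pairs$linc_id,
                        ann$truth$cis_pairs$gene_id))
  expect_setequal(cis$gap_bp, c(2000, 9900, 9999))
  trans <- out[out$mode == "trans", ]
  expect_setequal(paste(trans$linc_id, trans$gene_id),
                  c("linc_bg_01 gene_bg_01", "linc_bg_02 gene_bg_02"))
  expect_true(all(trans$score >= 60))
})

test_that("predict_targets respects the DE restriction and dedups", {
  lincs <- linc_row(5000, 6000)
  genes <- gene_rows(8000, 9000, "gA")
  # empty DE set -> empty table
  expect_equal(nrow(predict_targets(lincs, genes, de_genes = character(0))),
               0)
  # no restriction -> cis link present
  out <- predict_targets(lincs, genes, restrict_to_de = FALSE)
  expect_equal(out$mode, "cis")
  # cis and trans for the same pair collapse to one row
  gseq <- paste0(strrep("A", 50), strrep("G", 30), strrep("A", 50))
  lseq <- rna_revcomp(strrep("G", 30))
  both <- predict_targets(lincs, genes,
                          linc_seqs = c(linc1 = lseq),
                          gene_seqs = c(gA = gseq),
                          restrict_to_de = FALSE)
  expect_equal(nrow(both), 1)
  expect_equal(both$mode, "cis+trans")
  expect_equal(both$gap_bp, 2000)
  expect_equal(both$score, 90)
  # a candidate without a sequence is skipped with a message
  expect_message(predict_targets(lincs, genes,
                                 linc_seqs = c(linc1 = lseq),
                                 gene_seqs = c(other = gseq),
                                 restrict_to_de = FALSE),
                 "no sequence")
})
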