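test_that("classify_seed_site matches the definitional cases", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"            # 22 nt
  m28 <- substr(mir, 2, 8)
  perfect <- paste0(rna_revcomp(m28), "A")
  expect_equal(classify_seed_site(mir, perfect), "8mer")
  no_a <- paste0(rna_revcomp(m28), "C")
  expect_equal(classify_seed_site(mir, no_a), "7mer-m8")
  # break the m8 pair (window position 1) but keep the A
  w <- strsplit(perfect, "")[[1]]
  w[1] <- setdiff(c("A", "C", "G", "U"),
                  c(w[1], chartr("ACGU", "UGCA", substr(mir, 8, 8))))[1]
  expect_equal(classify_seed_site(mir, paste(w, collapse = "")), "7mer-A1")
  w[8] <- "C"
  expect_equal(classify_seed_site(mir, paste(w, collapse = "")), "6mer")
  expect_equal(classify_seed_site(mir, "ACGUACGU"), "none")
  # G:U wobble does not count as a seed match: window position 4 faces
  # miRNA position 5 (a G); replacing the C with U makes a G:U pair there
  wgu <- strsplit(perfect, "")[[1]]
  stopifnot(substr(mir, 5, 5) == "G", wgu[4] == "C")
  wgu[4] <- "U"
  expect_equal(classify_seed_site(mir, paste(wgu, collapse = "")), "none")
  expect_error(classify_seed_site(mir, "ACGU"), "8 nt")
  expect_error(classify_seed_site("ACGU", perfect), ">= 8")
})

test_that("classify_seed_site equals the rule oracle on random windows", {
  set.seed(51)
  mir <- random_rna(22)
  wins <- c(
    vapply(1:300, function(i) random_rna(8), character(1)),
    # near-miss windows: single mutations of the perfect 8mer
    local({
      p <- strsplit(paste0(rna_revcomp(substr(mir, 2, 8)), "A"), "")[[1]]
      unlist(lapply(1:8, function(k) vapply(c("A", "C", "G", "U"),
        function(b) { q <- p; q[k] <- b; paste(q, collapse = "") },
        character(1))))
    }))
  for (w in wins)
    expect_equal(classify_seed_site(mir, w), seed_oracle(mir, w))
})

test_that("scan_seed_sites equals the naive re-scan", {
  set.seed(52)
  mir <- random_rna(22)
  tx <- random_rna(2000)
  expect_equal(scan_seed_sites(mir, tx), scan_oracle(mir, tx))
  # planted site recovered at its position
  p <- 500
  tx2 <- paste0(substr(tx, 1, p),
                paste0(rna_revcomp(substr(mir, 2, 8)), "A"),
                substr(tx, p + 9, 2000))
  hits <- scan_seed_sites(mir, tx2)
  expect_true(any(hits$position == p & hits$site_type == "8mer"))
  expect_equal(nrow(scan_seed_sites(strrep("C", 22), strrep("C", 100))), 0)
  expect_equal(nrow(scan_seed_sites(mir, "ACGU")), 0)
})

test_that("duplex_energy matches its closed-form cases", {
  expect_equal(duplex_energy("G", "C"), 0)   # single pair cannot stack
  expect_equal(duplex_energy("", "GC"), 0)
  # perfect 8-bp helix: seven stacking steps straight from the table
  helix <- "GCGCGCGC"
  nn <- duplex_stack_table()
  steps <- substring(helix, 1:7, 2:8)
  expect_equal(duplex_energy(helix, rna_revcomp(helix)),
               sum(nn[steps]))
  # unpaired ends are free
  expect_equal(duplex_energy(helix, paste0("AAA", rna_revcomp(helix), "AAA")),
               sum(nn[steps]))
})

test_that("duplex_energy is invariant under reverse-complementing both strands", {
  set.seed(53)
  for (i in 1:10) {
    # A/C-only miRNA strand: every possible pair is Watson-Crick, so the
    # complement map preserves pairability
    a <- paste(sample(c("A", "C"), 12, replace = TRUE), collapse = "")
    b <- paste0(random_rna(3), rna_revcomp(a), random_rna(3))
    e1 <- duplex_energy(a, b)
    e2 <- duplex_energy(rna_revcomp(a), rna_revcomp(b))
    expect_equal(e1, e2)
  }
})

test_that("duplex_energy equals the quartic oracle on short RNAs", {
  set.seed(54)
  for (i in 1:20) {
    a <- random_rna(sample(6:12, 1))
    b <- random_rna(sample(6:12, 1))
    expect_equal(duplex_energy(a, b), duplex_oracle(a, b))
  }
})

test_that("au_context follows its truncation contract", {
  tx <- paste0(strrep("A", 30), strrep("G", 8), strrep("U", 30))
  expect_equal(au_context(tx, 30), 1)
  tx2 <- paste0(strrep("G", 30), strrep("A", 8), strrep("C", 30))
  expect_equal(au_context(tx2, 30), 0)
  # site at the transcript start: only the right flank exists
  tx3 <- paste0(strrep("G", 8), strrep("A", 15), strrep("C", 15))
  expect_equal(au_context(tx3, 0), 0.5)
  expect_error(au_context(tx3, 35), "within")
})

test_that("consensus_vote is a k-of-n rule", {
  expect_true(consensus_vote(c(TRUE, TRUE, FALSE), 2))
  expect_false(consensus_vote(c(TRUE, FALSE, FALSE), 2))
  expect_true(consensus_vote(c(TRUE, TRUE, TRUE), 3))
  expect_error(consensus_vote(c(TRUE, FALSE), 0), "configuration error")
  expect_error(consensus_vote(c(TRUE, FALSE), 3), "configuration error")
})

test_that("predict_binding recovers exactly the planted fixture edges", {
  fx <- cerna_fixture(seed = 7)
  lnc <- fx$seqs$transcripts[grep("^lnc_", names(fx$seqs$transcripts))]
  mrna <- fx$seqs$transcripts[grep("^mrna_", names(fx$seqs$transcripts))]
  le <- predict_binding(fx$seqs$mirnas, lnc, k = 2)
  me <- predict_binding(fx$seqs$mirnas, mrna, k = 3)
  sites <- fx$seqs$truth$sites
  planted <- paste(sites$mirna, sites$transcript)
  got <- c(paste(le$mirna[le$consensus], le$transcript[le$consensus]),
           paste(me$mirna[me$consensus], me$transcript[me$consensus]))
  expect_setequal(got, planted)
  # planted sites vote on all three predictors at the planted position
  all_edges <- rbind(le, me)
  for (i in seq_len(nrow(sites))) {
    row <- all_edges[all_edges$mirna == sites$mirna[i] &
                       all_edges$transcript == sites$transcript[i], ]
    expect_equal(row$n_votes, 3L)
    expect_equal(row$best_type, "8mer")
    expect_equal(row$best_position, sites$position[i])
    expect_lte(row$best_energy, -14)
  }
})

toy_de <- function() {
  data.frame(feature_id = c("lncA", "mirX", "m1", "m2", "m3"),
             direction = c("up", "down", "up", "up", "down"),
             stringsAsFactors = FALSE)
}
edge_df <- function(mirna, transcript)
  data.frame(mirna = mirna, transcript = transcript, consensus = TRUE,
             stringsAsFactors = FALSE)

test_that("assemble_triads applies the direction logic", {
  de <- toy_de()
  lnc_edges <- edge_df("mirX", "lncA")
  mrna_edges <- edge_df(rep("mirX", 2), c("m1", "m2"))
  strict <- assemble_triads(de, lnc_edges, mrna_edges, mode = "strict")
  expect_equal(nrow(strict), 2)
  expect_setequal(strict$mrna, c("m1", "m2"))
  expect_true(all(strict$lnc_dir == "up" & strict$mir_dir == "down"))
  # adding a down-mRNA keeps 2 strict triads but 3 permissive
  mrna_edges3 <- edge_df(rep("mirX", 3), c("m1", "m2", "m3"))
  expect_equal(nrow(assemble_triads(de, lnc_edges, mrna_edges3,
                                    mode = "strict")), 2)
  expect_equal(nrow(assemble_triads(de, lnc_edges, mrna_edges3,
                                    mode = "permissive")), 3)
})

test_that("assemble_triads drops ns members and unknown ids", {
  de <- toy_de()
  de$direction[de$feature_id == "lncA"] <- "ns"
  expect_equal(nrow(assemble_triads(de, edge_df("mirX", "lncA"),
                                    edge_df("mirX", "m1"),
                                    mode = "permissive")), 0)
  # empty miRNA DE set -> empty table
  de2 <- toy_de()[-2, ]
  expect_message(
    out <- assemble_triads(de2, edge_df("mirX", "lncA"),
                           edge_df("mirX", "m1"), mode = "permissive"),
    "dropped")
  expect_equal(nrow(out), 0)
  # only consensus edges are used
  e <- edge_df("mirX", "lncA"); e$consensus <- FALSE
  expect_equal(nrow(assemble_triads(toy_de(), e, edge_df("mirX", "m1"),
                                    mode = "permissive")), 0)
})
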