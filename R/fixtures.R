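## Hand-constructed demonstration fixtures used by the pipeline driver,
## the test suite and the acceptance checks.  Everything is built in code
## at run time from a seed; nothing is shipped as data.

#' Six-transcript filter-cascade fixture
#'
#' Builds one transcript engineered to fail each of the five cascade gates
#' plus one that passes all of them, together with the known annotation and
#' coordinates that drive the overlap gate and the domain pattern used by
#' the domain gate.
#'
#' @param model A \code{cp_model} (see \code{\link{toy_cp_training_set}}).
#' @param seed Integer seed for the random backbones.
#' @return \code{list(transcripts, tx_coords, known, patterns, expected)}
#'   where \code{expected} maps transcript id to the intended verdict.
#' @export
novel_cascade_fixture <- function(model, seed = 7) {
  stops <- c("UAA", "UAG", "UGA")
  all_codons <- apply(expand.grid(rep(list(RNA_ALPHABET), 3))[, 3:1],
                      1, paste, collapse = "")
  sense <- setdiff(all_codons, stops)
  with_sim_seed(seed, 0L, {
    ## random backbone guaranteed free of long ORFs and the domain motif:
    ## built from random codons with an in-frame stop every 8 codons
    safe_rna <- function(n_codons) {
      blocks <- replicate(ceiling(n_codons / 8), paste0(
        paste(sample(sense, 7, replace = TRUE), collapse = ""),
        sample(stops, 1)))
      substr(paste(blocks, collapse = ""), 1, n_codons * 3)
    }
    orf <- function(n_codons, pool = sense)
      paste0("AUG", paste(sample(pool, n_codons - 2, replace = TRUE),
                          collapse = ""), sample(stops, 1))
    preferred <- attr(model, "preferred_codons")
    if (is.null(preferred)) preferred <- sense
    tx <- c(
      t_known  = safe_rna(84),                       # 252 nt, overlaps known
      t_short  = safe_rna(50),                       # 150 nt < 200
      t_orf    = paste0(safe_rna(10), orf(102)),     # ORF 306 nt >= 300
      t_domain = paste0(safe_rna(10),                # hexa-His motif hit
                        "AUG", strrep("CAC", 6),
                        paste(sample(sense, 20, replace = TRUE),
                              collapse = ""), "UAA", safe_rna(40)),
      t_coding = paste0(safe_rna(4), orf(90, preferred), safe_rna(4)),
      t_novel  = paste0(safe_rna(30), orf(8), safe_rna(40)))
    coords <- data.frame(
      id = names(tx), chrom = "chrS",
      start = c(1000, 5000, 9000, 13000, 17000, 21000),
      stringsAsFactors = FALSE)
    coords$end <- coords$start + nchar(tx) - 1
    coords$strand <- "+"
    known <- data.frame(id = "known_gene_1", chrom = "chrS",
                        start = 900, end = 1400, strand = "+",
                        biotype = "protein_coding",
                        stringsAsFactors = FALSE)
    list(transcripts = tx, tx_coords = coords, known = known,
         patterns = "HHHHHH",
         expected = c(t_known = "rejected:known",
                      t_short = "rejected:length",
                      t_orf = "rejected:orf",
                      t_domain = "rejected:domain",
                      t_coding = "rejected:cp",
                      t_novel = "novel_lncRNA"))
  })
}

#' Train the packaged toy coding-potential model
#'
#' Convenience wrapper: generates the toy training set and trains the
#' hexamer model, recording the preferred-codon subset so fixtures can
#' build coding-like decoys.
#'
#' @param seed Integer seed.
#' @return A \code{cp_model}.
#' @export
toy_cp_model <- function(seed = 101) {
  ts <- toy_cp_training_set(seed = seed)
  model <- train_cp_model(ts$coding, ts$noncoding)
  ## remember which codons the toy coding class prefers
  first_codons <- table(substring(unlist(lapply(ts$coding, function(s)
    inframe_hexamers(s))), 1, 3))
  attr(model, "preferred_codons") <-
    names(sort(first_codons, decreasing = TRUE))[1:20]
  model
}

#' Planted ceRNA fixture: sequences, directions and the triad truth
#'
#' Three lncRNAs, three miRNAs and four mRNAs with planted differential
#' directions, and five planted strong 8mer sites (3'-supplementary
#' pairing, A/U flanks) wiring three direction-consistent triads:
#' (lnc 1, mir 1, mrna 1), (lnc 1, mir 1, mrna 2), (lnc 2, mir 2, mrna 3).
#' Transcripts are kept short (120 nt) and generated with
#' \code{exclude_chance_sites = TRUE}, so the planted sites are provably the
#' only seed sites and no chance consensus edge can arise.
#'
#' @param seed Integer seed.
#' @return \code{list(config, seqs (simulate_sequences output),
#'   directions (named up/down), planted_triads (data.frame))}.
#' @export
cerna_fixture <- function(seed = 7) {
  cfg <- sim_config(
    seed = seed, n_lncrna = 3, n_mirna = 3, n_mrna = 4,
    transcript_length = 120, exclude_chance_sites = TRUE,
    site_specs = list(
      list(mirna = "mir_0001", transcript = "lnc_0001", site_type = "8mer",
           supplementary = TRUE, au_flank = TRUE),
      list(mirna = "mir_0001", transcript = "mrna_0001", site_type = "8mer",
           supplementary = TRUE, au_flank = TRUE),
      list(mirna = "mir_0001", transcript = "mrna_0002", site_type = "8mer",
           supplementary = TRUE, au_flank = TRUE),
      list(mirna = "mir_0002", transcript = "lnc_0002", site_type = "8mer",
           supplementary = TRUE, au_flank = TRUE),
      list(mirna = "mir_0002", transcript = "mrna_0003", site_type = "8mer",
           supplementary = TRUE, au_flank = TRUE)))
  seqs <- simulate_sequences(cfg)
  directions <- c(lnc_0001 = "up", lnc_0002 = "down", lnc_0003 = "up",
                  mir_0001 = "down", mir_0002 = "up", mir_0003 = "down",
                  mrna_0001 = "up", mrna_0002 = "up", mrna_0003 = "down",
                  mrna_0004 = "down")
  planted <- data.frame(
    lncrna = c("lnc_0001", "lnc_0001", "lnc_0002"),
    mirna = c("mir_0001", "mir_0001", "mir_0002"),
    mrna = c("mrna_0001", "mrna_0002", "mrna_0003"),
    stringsAsFactors = FALSE)
  list(config = cfg, seqs = seqs, directions = directions,
       planted_triads = planted)
}

#' Simulate a count experiment matching a set of planted directions
#'
#' Builds a small pooled two-condition Poisson count matrix whose planted
#' fold changes follow \code{directions}, so DE calling can recover the
#' directions end to end instead of being handed them.
#'
#' @param directions Named vector of "up"/"down" per feature id (ids must
#'   follow the generator's lnc_/mir_/mrna_ naming).
#' @param seed Integer seed.
#' @param log2fc Planted magnitude.
#' @param baseline_mean Baseline expected count.
#' @return A \code{count_matrix}.
#' @export
directed_counts <- function(directions, seed = 7, log2fc = 2,
                            baseline_mean = 100) {
  classes <- ifelse(grepl("^lnc_", names(directions)), "lncRNA",
             ifelse(grepl("^mir_", names(directions)), "miRNA", "mRNA"))
  n_per <- 5L
  with_sim_seed(seed, 3L, {
    lfc <- ifelse(directions == "up", log2fc, -log2fc)
    mu <- matrix(baseline_mean, length(directions), 2 * n_per,
                 dimnames = list(names(directions),
                                 paste0(rep(c("ctrl_", "case_"),
                                            each = n_per),
                                        sprintf("%02d", c(1:n_per,
                                                          1:n_per)))))
    mu[, (n_per + 1):(2 * n_per)] <-
      mu[, (n_per + 1):(2 * n_per)] * 2^lfc
    counts <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu),
                     dimnames = dimnames(mu))
    ## nominal fixed depth: on a 10-feature panel the planted shifts do not
    ## cancel, so normalizing by the panel sum would distort every fold
    ## change (compositional artifact absent at transcriptome scale)
    count_matrix(counts, group = rep(c("control", "case"), each = n_per),
                 feature_class = classes,
                 feature_length = ifelse(classes == "miRNA", 22, 1000),
                 library_size = rep(1e6, ncol(counts)))
  })
}

#' Planted trans-pairing fixture
#'
#' A lincRNA carrying the exact reverse complement of a 30-nt window of an
#' mRNA, so the antiparallel pairing score is at least 60 (30 Watson-Crick
#' pairs at +2 minimum).
#'
#' @param seed Integer seed.
#' @return \code{list(linc_seq, mrna_seq, window = c(start, end))}.
#' @export
trans_pair_fixture <- function(seed = 7) {
  with_sim_seed(seed, 4L, {
    mrna <- random_rna(200)
    win <- c(101, 130)
    linc <- paste0(random_rna(60),
                   rna_revcomp(substr(mrna, win[1], win[2])),
                   random_rna(60))
    list(linc_seq = linc, mrna_seq = mrna, window = win)
  })
}
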