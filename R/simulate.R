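## Synthetic-data generators.  Each generator derives its RNG state from the
## config seed alone (with a fixed per-generator offset so the three outputs
## are mutually independent), and restores the caller's RNG state on exit.

with_sim_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed + offset)
  expr
}

#' Simulate a two-condition count experiment with planted fold changes
#'
#' Draws negative-binomial counts (Poisson when \code{nb_dispersion = 0})
#' for lncRNA, miRNA and mRNA features over \code{n_samples_per_group}
#' case and control samples.  A \code{de_fraction} of each class carries a
#' planted log2 fold change of magnitude \code{planted_log2fc} in the case
#' group (signs alternate up/down).  Planted coexpression modules couple one
#' lncRNA to a block of mRNAs through a shared latent Gaussian factor on the
#' log scale; module members are kept disjoint from the planted DE set so
#' the two ground truths do not confound each other.
#'
#' @param config A \code{\link{sim_config}}.
#' @return \code{list(counts = count_matrix, truth = truth_manifest)}.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  ids <- sim_feature_ids(config)
  manifest <- empty_manifest()

  ## assign planted modules first (1 lncRNA + size mRNAs each, from the
  ## front of the id lists)
  mod_assign <- list()
  lnc_cursor <- 0L; mrna_cursor <- 0L
  for (mi in seq_along(config$module_specs)) {
    mspec <- config$module_specs[[mi]]
    lnc_cursor <- lnc_cursor + 1L
    members_mrna <- ids$mRNA[mrna_cursor + seq_len(mspec$size)]
    mrna_cursor <- mrna_cursor + mspec$size
    if (lnc_cursor > config$n_lncrna || anyNA(members_mrna))
      stop("configuration error: not enough features for module_specs")
    mod_assign[[mi]] <- list(lnc = ids$lncRNA[lnc_cursor],
                             mrna = members_mrna,
                             rho = mspec$latent_correlation)
    manifest$modules <- rbind(manifest$modules, data.frame(
      module = mi,
      feature_id = c(ids$lncRNA[lnc_cursor], members_mrna),
      class = c("lncRNA", rep("mRNA", mspec$size)),
      stringsAsFactors = FALSE))
  }
  module_ids <- manifest$modules$feature_id

  all_ids <- c(ids$lncRNA, ids$miRNA, ids$mRNA)
  all_class <- rep(c("lncRNA", "miRNA", "mRNA"),
                   c(config$n_lncrna, config$n_mirna, config$n_mrna))
  n_feat <- length(all_ids)
  n_per <- config$n_samples_per_group
  n_samp <- 2L * n_per
  group <- rep(c("control", "case"), each = n_per)
  sample_ids <- paste0(rep(c("ctrl_", "case_"), each = n_per),
                       sprintf("%02d", c(seq_len(n_per), seq_len(n_per))))

  with_sim_seed(config$seed, 0L, {
    ## planted DE: per class, round(n * fraction) features sampled from the
    ## features not already claimed by a module; alternating signs
    lfc <- setNames(numeric(n_feat), all_ids)
    for (cl in c("lncRNA", "miRNA", "mRNA")) {
      pool <- setdiff(ids[[cl]], module_ids)
      n_de <- round(length(ids[[cl]]) * config$de_fraction)
      if (n_de > length(pool))
        stop("configuration error: de_fraction incompatible with modules")
      if (n_de > 0 && config$planted_log2fc != 0) {
        de_ids <- sort(sample(pool, n_de))
        signs <- rep(c(1, -1), length.out = n_de)
        lfc[de_ids] <- signs * config$planted_log2fc
        manifest$de <- rbind(manifest$de, data.frame(
          feature_id = de_ids, class = cl, log2fc = signs *
            config$planted_log2fc, stringsAsFactors = FALSE))
      }
    }

    ## expected counts: baseline, latent module factor (log scale,
    ## mean-corrected), then the planted case-group shift
    mu <- matrix(config$baseline_mean, n_feat, n_samp,
                 dimnames = list(all_ids, sample_ids))
    tau <- config$module_log_sd
    for (m in mod_assign) {
      members <- c(m$lnc, m$mrna)
      z <- stats::rnorm(n_samp)
      eps <- matrix(stats::rnorm(length(members) * n_samp),
                    length(members), n_samp)
      lat <- tau * (sqrt(m$rho) * rep(z, each = length(members)) +
                    sqrt(1 - m$rho) * eps) - tau^2 / 2
      mu[members, ] <- mu[members, , drop = FALSE] * exp(lat)
    }
    case_cols <- group == "case"
    mu[, case_cols] <- mu[, case_cols] * 2^lfc

    counts <- if (config$nb_dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), n_feat, n_samp,
             dimnames = dimnames(mu))
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$nb_dispersion),
             n_feat, n_samp, dimnames = dimnames(mu))
    }

    flen <- config$feature_length_bp[all_class]
    lib <- if (is.null(config$fixed_library_size)) NULL else
      rep(config$fixed_library_size, n_samp)
    cm <- count_matrix(counts, group = group, feature_class = all_class,
                       feature_length = flen, library_size = lib)
    list(counts = cm, truth = manifest)
  })
}

#' Simulate a toy genome annotation with planted cis pairs
#'
#' Places one lincRNA/coding-gene pair per \code{cis_pair_specs} entry on a
#' single toy chromosome at exactly the requested gap (gene start minus
#' lincRNA end, in bp), plus isolated background genes and lincRNAs farther
#' than \code{cis_window} from every other feature.  Pairs with
#' \code{gap_bp > cis_window} are recorded as planted negative controls.
#'
#' @param config A \code{\link{sim_config}}.
#' @param feature_bp Length in bp of each placed feature.
#' @return \code{list(features = data.frame(id, chrom, start, end, strand,
#'   biotype), truth = truth_manifest)}.
#' @export
simulate_annotation <- function(config, feature_bp = 1000) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  manifest <- empty_manifest()
  margin <- config$cis_window + feature_bp + 1000  # isolation spacing
  rows <- list()
  cursor <- 1

  with_sim_seed(config$seed, 1L, {
    place <- function(id, start, biotype) {
      data.frame(id = id, chrom = "chrS", start = start,
                 end = start + feature_bp - 1,
                 strand = sample(c("+", "-"), 1), biotype = biotype,
                 stringsAsFactors = FALSE)
    }
    for (k in seq_along(config$cis_pair_specs)) {
      gap <- config$cis_pair_specs[[k]]$gap_bp
      linc_id <- sprintf("linc_cis_%02d", k)
      gene_id <- sprintf("gene_cis_%02d", k)
      linc <- place(linc_id, cursor, "lincRNA")
      gene <- place(gene_id, linc$end + gap, "protein_coding")
      rows <- c(rows, list(linc, gene))
      manifest$cis_pairs <- rbind(manifest$cis_pairs, data.frame(
        linc_id = linc_id, gene_id = gene_id, gap_bp = gap,
        planted_positive = gap <= config$cis_window,
        stringsAsFactors = FALSE))
      cursor <- gene$end + margin
    }
    for (k in seq_len(config$n_background_lincs)) {
      rows <- c(rows, list(place(sprintf("linc_bg_%02d", k), cursor,
                                 "lincRNA")))
      cursor <- cursor + feature_bp + margin
    }
    for (k in seq_len(config$n_background_genes)) {
      rows <- c(rows, list(place(sprintf("gene_bg_%02d", k), cursor,
                                 "protein_coding")))
      cursor <- cursor + feature_bp + margin
    }
    if (cursor > config$genome_length)
      stop(sprintf(
        "configuration error: genome_length %g too small (need %g bp)",
        config$genome_length, cursor))
    list(features = do.call(rbind, rows), truth = manifest)
  })
}

## Build the 8-nt site window (5'->3' on the transcript) implied by a seed
## site type.  Window position k sits opposite miRNA position 9-k
## (antiparallel), so Watson-Crick match at miRNA 2-8 means the window's
## first 7 nt equal revcomp(miRNA[2..8]), and an A opposite miRNA position 1
## means the window ends in A.
seed_site_window <- function(mirna_seq, site_type) {
  m <- strsplit(mirna_seq, "")[[1]]
  if (length(m) < 8) stop("miRNA shorter than 8 nt")
  rc28 <- strsplit(rna_revcomp(paste(m[2:8], collapse = "")), "")[[1]]
  rc27 <- strsplit(rna_revcomp(paste(m[2:7], collapse = "")), "")[[1]]
  not_m8 <- sample(setdiff(RNA_ALPHABET, rna_complement_base(m[8])), 1)
  switch(site_type,
    "8mer"    = c(rc28, "A"),
    "7mer-m8" = c(rc28, sample(c("C", "G", "U"), 1)),
    "7mer-A1" = c(not_m8, rc27, "A"),
    "6mer"    = c(not_m8, rc27, sample(c("C", "G", "U"), 1)),
    stop("configuration error: unknown site_type"))
}

#' Simulate miRNA and transcript sequences with planted seed sites
#'
#' Background sequence is uniform over \{A, C, G, U\}.  Each
#' \code{site_specs} entry overwrites an 8-nt window of the named transcript
#' with the exact pattern implied by its site type, at a recorded (0-based)
#' position.  Optional extensions plant 3'-supplementary complementarity
#' (miRNA positions 13-19, 4-nt loop) upstream of the window and A/U-only
#' 30-nt flanks; these emulate strong, accessible sites and are off by
#' default.
#'
#' @param config A \code{\link{sim_config}}.
#' @param mirna_seqs Optional named character vector of miRNA sequences to
#'   use instead of generated ones.
#' @return \code{list(mirnas, transcripts, truth)}; sequences are named
#'   character vectors over the RNA alphabet.
#' @export
simulate_sequences <- function(config, mirna_seqs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  ids <- sim_feature_ids(config)

  ## One complete draw of the sequence set.  With exclude_chance_sites a
  ## draw can be structurally unresolvable (a chance seed core entirely
  ## inside a planted construct); gen_once signals that with a "chance
  ## seed" configuration error and the caller redraws (rejection
  ## sampling within the same seeded stream, so still deterministic).
  gen_once <- function() {
    manifest <- empty_manifest()
    mirnas <- if (is.null(mirna_seqs)) {
      setNames(vapply(seq_len(config$n_mirna), function(i)
        random_rna(config$mirna_length), character(1)), ids$miRNA)
    } else vapply(mirna_seqs, as_rna, character(1))
    tx_ids <- c(ids$lncRNA, ids$mRNA)
    transcripts <- setNames(vapply(tx_ids, function(i)
      random_rna(config$transcript_length), character(1)), tx_ids)

    occupied <- lapply(transcripts, function(x) integer(0))
    flank <- 30L
    for (s in config$site_specs) {
      if (!s$mirna %in% names(mirnas))
        stop(sprintf("configuration error: unknown miRNA '%s'", s$mirna))
      if (!s$transcript %in% names(transcripts))
        stop(sprintf("configuration error: unknown transcript '%s'",
                     s$transcript))
      supp <- isTRUE(s$supplementary)
      auf <- isTRUE(s$au_flank)
      tx <- strsplit(transcripts[[s$transcript]], "")[[1]]
      L <- length(tx)
      lo <- if (supp) 12L else 1L       # 1-based window start bounds
      hi <- L - 7L
      if (hi < lo)
        stop(sprintf(
          "configuration error: transcript '%s' too short for site",
          s$transcript))
      cand <- if (!is.null(s$position)) s$position + 1L else {
        free <- setdiff(lo:hi, unlist(lapply(occupied[[s$transcript]],
          function(o) (o - 11L):(o + 7L))))
        if (length(free) == 0)
          stop("configuration error: no free position for planted site")
        if (length(free) == 1) free else sample(free, 1)
      }
      st <- cand
      if (st < lo || st > hi)
        stop(sprintf(
          "configuration error: transcript '%s' too short for site at %d",
          s$transcript, st))
      m <- strsplit(mirnas[[s$mirna]], "")[[1]]
      if (auf) {
        fl <- intersect(c((st - flank):(st - 1L), (st + 8L):(st + 7L + flank)),
                        seq_len(L))
        tx[fl] <- sample(c("A", "U"), length(fl), replace = TRUE)
      }
      if (supp) {
        if (length(m) < 19)
          stop("configuration error: miRNA too short for supplementary site")
        rc <- strsplit(rna_revcomp(paste(m[13:19], collapse = "")), "")[[1]]
        tx[(st - 11L):(st - 5L)] <- rc  # pairs miRNA 13-19, 4-nt loop
      }
      tx[st:(st + 7L)] <- seed_site_window(mirnas[[s$mirna]], s$site_type)
      transcripts[[s$transcript]] <- paste(tx, collapse = "")
      occupied[[s$transcript]] <- c(occupied[[s$transcript]], st)
      manifest$sites <- rbind(manifest$sites, data.frame(
        mirna = s$mirna, transcript = s$transcript, position = st - 1L,
        site_type = s$site_type, supplementary = supp, au_flank = auf,
        stringsAsFactors = FALSE))
    }
    if (config$exclude_chance_sites) {
      ## protected spans (1-based) per transcript.  "Hard" positions carry
      ## pairing information (the planted window and any supplementary
      ## span) and must never change.  "Soft" positions are AU-flank bases:
      ## only their A/U composition matters, so an A<->U swap there is
      ## allowed -- it breaks any Watson-Crick seed match at the position
      ## while leaving the flank's AU fraction exactly unchanged.
      hard <- lapply(transcripts, function(x) integer(0))
      soft <- lapply(transcripts, function(x) integer(0))
      if (nrow(manifest$sites) > 0) {
        for (i in seq_len(nrow(manifest$sites))) {
          si <- manifest$sites[i, ]
          st <- si$position + 1L
          span <- st:(st + 7L)
          if (si$supplementary) span <- c((st - 11L):(st - 5L), span)
          L <- nchar(transcripts[[si$transcript]])
          hard[[si$transcript]] <-
            union(hard[[si$transcript]], intersect(span, seq_len(L)))
          if (si$au_flank) {
            fl <- c((st - flank):(st - 1L), (st + 8L):(st + 7L + flank))
            soft[[si$transcript]] <-
              union(soft[[si$transcript]], intersect(fl, seq_len(L)))
          }
        }
        soft <- Map(setdiff, soft, hard)
      }
      planted_key <- if (nrow(manifest$sites) > 0)
        paste(manifest$sites$mirna, manifest$sites$transcript,
              manifest$sites$position) else character(0)
      for (iter in 1:200) {
        clean <- TRUE
        for (tid in names(transcripts)) {
          tx <- strsplit(transcripts[[tid]], "")[[1]]
          for (mid in names(mirnas)) {
            hits <- scan_seed_sites(mirnas[[mid]], transcripts[[tid]])
            if (nrow(hits) == 0) next
            chance <- hits$position[!paste(mid, tid, hits$position) %in%
                                      planted_key]
            for (p in chance) {
              ## every site type needs the 6mer core at window positions
              ## 2-7; break the hit by mutating one random core base.
              ## Randomised minimal disruption avoids the cycles a
              ## deterministic all-positions toggle can fall into.
              core <- intersect((p + 2L):(p + 7L), seq_along(tx))
              cand_free <- setdiff(core, union(hard[[tid]], soft[[tid]]))
              cand_swap <- intersect(core, soft[[tid]])
              if (length(cand_free) == 0 && length(cand_swap) == 0)
                stop(sprintf(paste0("configuration error: chance seed ",
                                    "site inside a planted construct of ",
                                    "'%s' cannot be resampled"), tid))
              clean <- FALSE
              cand <- c(cand_free, cand_swap)
              pos <- cand[sample.int(length(cand), 1)]
              if (pos %in% cand_free) {
                tx[pos] <- sample(setdiff(RNA_ALPHABET, tx[pos]), 1)
              } else {
                if (!tx[pos] %in% c("A", "U"))
                  stop(sprintf(paste0("configuration error: AU flank of ",
                                      "'%s' contains non-A/U bases"), tid))
                tx[pos] <- chartr("AU", "UA", tx[pos])
              }
              transcripts[[tid]] <- paste(tx, collapse = "")
            }
          }
        }
        if (clean) break
        if (iter == 200)
          stop("configuration error: could not exclude chance seed sites")
      }
    }
    list(mirnas = mirnas, transcripts = transcripts, truth = manifest)
  }

  with_sim_seed(config$seed, 2L, {
    result <- NULL
    for (attempt in 1:25) {
      result <- tryCatch(gen_once(), error = function(e) {
        if (grepl("chance seed", conditionMessage(e))) NULL else stop(e)
      })
      if (!is.null(result)) break
    }
    if (is.null(result))
      stop(paste0("configuration error: could not generate a ",
                  "chance-site-free sequence draw in 25 attempts"))
    result
  })
}

#' Write named RNA sequences as FASTA
#' @param seqs Named character vector over \{A,C,G,U\}.
#' @param path Output file.
#' @export
write_rna_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as named RNA character vector
#' @param path FASTA file; T is converted to U with a warning.
#' @export
read_rna_fasta <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input error: FASTA file '%s' not found", path))
  x <- Biostrings::readBStringSet(path)
  setNames(vapply(seq_along(x), function(i)
    as_rna(as.character(x[[i]]), names(x)[i]), character(1)), names(x))
}

#' Write a feature table as GTF
#' @param features data.frame(id, chrom, start, end, strand, biotype).
#' @param path Output file.
#' @export
write_annotation_gtf <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand,
    type = "transcript",
    gene_id = features$id, transcript_id = features$id,
    biotype = features$biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GTF into a feature table
#' @param path GTF file with gene_id/transcript_id/biotype attributes.
#' @return data.frame(id, chrom, start, end, strand, biotype).
#' @export
read_annotation_gtf <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input error: GTF file '%s' not found", path))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[is.na(gr$type) | gr$type == "transcript"]
  data.frame(id = gr$transcript_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             biotype = if (!is.null(gr$biotype)) gr$biotype else NA_character_,
             stringsAsFactors = FALSE)
}
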