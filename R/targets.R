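## lincRNA target prediction: the 10-kb cis window rule and a trans
## base-pairing complementarity score (local alignment of the lincRNA
## against the reversed mRNA, i.e. antiparallel hybridisation).

#' Coding genes within a cis window of a lincRNA
#'
#' Returns genes whose interval intersects
#' \code{[linc_start - window, linc_end + window]} on the same chromosome
#' (strand-agnostic).  The reported gap is 0 for overlapping intervals and
#' otherwise the distance between the facing interval ends (adjacent
#' intervals have gap 1).
#'
#' @param linc One-row data.frame(id, chrom, start, end, ...) with 1-based
#'   closed coordinates.
#' @param genes Feature table of candidate genes (same columns).
#' @param window Window in bp (>= 0) on each side.
#' @return data.frame(linc_id, gene_id, mode = "cis", gap_bp).
#' @export
cis_neighbors <- function(linc, genes, window = 10000) {
  if (window < 0) stop("configuration error: window must be >= 0")
  if (nrow(genes) == 0)
    return(data.frame(linc_id = character(0), gene_id = character(0),
                      mode = character(0), gap_bp = numeric(0),
                      stringsAsFactors = FALSE))
  gl <- GenomicRanges::GRanges(linc$chrom,
                               IRanges::IRanges(linc$start - window,
                                                linc$end + window))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hit <- IRanges::overlapsAny(gg, gl, ignore.strand = TRUE)
  sel <- genes[hit, , drop = FALSE]
  gap <- pmax(0, pmax(sel$start - linc$end, linc$start - sel$end))
  data.frame(linc_id = rep(linc$id, nrow(sel)), gene_id = sel$id,
             mode = rep("cis", nrow(sel)), gap_bp = gap,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default trans base-pairing scores
#' @return Named list: gc, au, gu, mismatch, gap.
#' @export
trans_scoring <- function(gc = 3, au = 2, gu = 1, mismatch = -4, gap = -6) {
  list(gc = gc, au = au, gu = gu, mismatch = mismatch, gap = gap)
}

## Pair score of two bases in antiparallel hybridisation.
pair_score <- function(a, b, scoring) {
  ifelse(is_wc_pair(a, b) & (a %in% c("G", "C")), scoring$gc,
  ifelse(is_wc_pair(a, b), scoring$au,
  ifelse(is_gu_pair(a, b), scoring$gu, scoring$mismatch)))
}

#' Trans-action complementarity score between two RNAs
#'
#' Best local alignment (Smith-Waterman, linear gap) of the lincRNA against
#' the reverse of the mRNA, scoring complementary base pairs (GC +3, AU +2,
#' GU +1 by default) so that a high score marks a stretch where the two
#' molecules can hybridise antiparallel.
#'
#' @param linc_seq,mrna_seq RNA sequences.
#' @param scoring Scores from \code{\link{trans_scoring}}.
#' @return \code{list(score, linc_region = c(start, end), mrna_region =
#'   c(start, end))}; regions are 1-based closed coordinates on the
#'   original (unreversed) sequences, score 0 with NULL regions when no
#'   positive-scoring pairing exists (including empty input).
#' @export
trans_score <- function(linc_seq, mrna_seq, scoring = trans_scoring()) {
  if (nchar(linc_seq) == 0 || nchar(mrna_seq) == 0)
    return(list(score = 0, linc_region = NULL, mrna_region = NULL))
  a <- strsplit(as_rna(linc_seq), "")[[1]]
  b <- rev(strsplit(as_rna(mrna_seq), "")[[1]])   # reversed mRNA
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  best <- 0; best_ij <- c(0L, 0L)
  for (i in seq_len(n)) {
    s_row <- pair_score(a[i], b, scoring)
    for (j in seq_len(m)) {
      h <- max(0,
               H[i, j] + s_row[j],
               H[i, j + 1] + scoring$gap,
               H[i + 1, j] + scoring$gap)
      H[i + 1, j + 1] <- h
      if (h > best) { best <- h; best_ij <- c(i, j) }
    }
  }
  if (best == 0) return(list(score = 0, linc_region = NULL,
                             mrna_region = NULL))
  ## traceback for the matched regions
  i <- best_ij[1]; j <- best_ij[2]
  end_i <- i; end_j <- j
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    h <- H[i + 1, j + 1]
    if (h == H[i, j] + pair_score(a[i], b[j], scoring)) {
      i <- i - 1; j <- j - 1
    } else if (h == H[i, j + 1] + scoring$gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  ## convert reversed-mRNA coordinates back to the original orientation
  list(score = best,
       linc_region = c(i + 1, end_i),
       mrna_region = c(nchar(mrna_seq) - end_j + 1, nchar(mrna_seq) - j))
}

#' Predict lincRNA target genes (cis window union trans pairing)
#'
#' Cis links come from \code{\link{cis_neighbors}} over the annotation;
#' trans links from \code{\link{trans_score}} over the sequences, kept at
#' \code{score >= trans_threshold}.  The candidate gene universe is
#' restricted to differentially expressed mRNAs unless
#' \code{restrict_to_de = FALSE}.  A link found by both modes is collapsed
#' to one row with \code{mode = "cis+trans"} and both evidences kept.
#'
#' @param lincs Feature table of lincRNAs (id, chrom, start, end, strand).
#' @param genes Feature table of coding genes.
#' @param linc_seqs,gene_seqs Named RNA character vectors (genes without a
#'   sequence are skipped for trans with a message).
#' @param de_genes Character vector of DE mRNA ids (the candidate
#'   universe).
#' @param window Cis window in bp.
#' @param trans_threshold Minimum trans score.
#' @param scoring Trans scoring scheme.
#' @param restrict_to_de Keep only DE genes as candidates.
#' @return data.frame(linc_id, gene_id, mode, gap_bp, score).
#' @export
predict_targets <- function(lincs, genes, linc_seqs = NULL,
                            gene_seqs = NULL, de_genes = NULL,
                            window = 10000, trans_threshold = 60,
                            scoring = trans_scoring(),
                            restrict_to_de = TRUE) {
  if (restrict_to_de) {
    if (is.null(de_genes)) de_genes <- character(0)
    genes <- genes[genes$id %in% de_genes, , drop = FALSE]
  }
  empty <- data.frame(linc_id = character(0), gene_id = character(0),
                      mode = character(0), gap_bp = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(genes) == 0 || nrow(lincs) == 0) return(empty)
  cis <- do.call(rbind, lapply(seq_len(nrow(lincs)), function(i)
    cis_neighbors(lincs[i, , drop = FALSE], genes, window)))
  cis$score <- NA_real_
  trans <- empty
  if (!is.null(linc_seqs) && !is.null(gene_seqs)) {
    for (li in intersect(lincs$id, names(linc_seqs))) {
      for (gi in genes$id) {
        if (!gi %in% names(gene_seqs)) {
          message(sprintf("no sequence for candidate '%s'; skipped", gi))
          next
        }
        ts <- trans_score(linc_seqs[[li]], gene_seqs[[gi]], scoring)
        if (ts$score >= trans_threshold)
          trans <- rbind(trans, data.frame(
            linc_id = li, gene_id = gi, mode = "trans", gap_bp = NA_real_,
            score = ts$score, stringsAsFactors = FALSE))
      }
    }
  }
  all_links <- rbind(cis, trans)
  if (nrow(all_links) == 0) return(empty)
  key <- paste(all_links$linc_id, all_links$gene_id)
  merged <- lapply(split(all_links, key), function(d) {
    data.frame(linc_id = d$linc_id[1], gene_id = d$gene_id[1],
               mode = paste(sort(unique(d$mode)), collapse = "+"),
               gap_bp = if (any(!is.na(d$gap_bp))) min(d$gap_bp,
                                                       na.rm = TRUE)
                        else NA_real_,
               score = if (any(!is.na(d$score))) max(d$score, na.rm = TRUE)
                       else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$linc_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
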