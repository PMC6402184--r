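## miRNA site prediction on lncRNAs and mRNAs with three in-repo
## predictors (canonical seed match, hybridisation energy, A/U-context
## accessibility), k-of-n consensus voting exactly as multi-tool
## predictions are combined (>= 2 of 3 for lncRNA-miRNA, >= 3 of 3 for
## miRNA-mRNA), and direction-consistent ceRNA triad assembly.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Classify an 8-nt target window against a miRNA seed
#'
#' The window (5'->3' on the transcript) is aligned antiparallel opposite
#' miRNA positions 1-8: window position k faces miRNA position 9-k.
#' 8mer = Watson-Crick match at miRNA 2-8 plus an A opposite position 1;
#' 7mer-m8 = match at 2-8; 7mer-A1 = match at 2-7 plus the A; 6mer = match
#' at 2-7.  G:U wobble does not count as a seed match.
#'
#' @param mirna miRNA sequence (>= 8 nt, RNA).
#' @param window8 8-nt window (RNA).
#' @return One of \code{"8mer"}, \code{"7mer-m8"}, \code{"7mer-A1"},
#'   \code{"6mer"}, \code{"none"}.
#' @export
classify_seed_site <- function(mirna, window8) {
  if (nchar(window8) != 8) stop("site window must be 8 nt")
  if (nchar(mirna) < 8) stop("miRNA must be >= 8 nt")
  m <- strsplit(as_rna(mirna), "")[[1]]
  w <- strsplit(as_rna(window8), "")[[1]]
  ## w[k] faces m[9-k]; WC match there means w[k] == complement(m[9-k])
  comp <- chartr("ACGU", "UGCA", m[8:2])     # complement of m8..m2
  match28 <- all(w[1:7] == comp)             # miRNA positions 8..2
  match27 <- all(w[2:7] == comp[2:7])        # miRNA positions 7..2
  a1 <- w[8] == "A"
  if (match28 && a1) "8mer"
  else if (match28) "7mer-m8"
  else if (match27 && a1) "7mer-A1"
  else if (match27) "6mer"
  else "none"
}

#' Scan a transcript for miRNA seed sites
#'
#' Slides an 8-nt window along the transcript and reports every window of
#' type 6mer or better (overlapping sites allowed), with the window's
#' 0-based start position.
#'
#' @param mirna miRNA sequence.
#' @param transcript Transcript sequence (>= 8 nt).
#' @return data.frame(position, site_type), possibly empty.
#' @export
scan_seed_sites <- function(mirna, transcript) {
  transcript <- as_rna(transcript)
  mirna <- as_rna(mirna)
  L <- nchar(transcript)
  empty <- data.frame(position = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE)
  if (L < 8) return(empty)
  m <- strsplit(mirna, "")[[1]]
  tx <- strsplit(transcript, "")[[1]]
  comp <- chartr("ACGU", "UGCA", m[8:2])
  n_win <- L - 7L
  ## vectorised window comparison: win_mat[k, s] = transcript[s + k - 1]
  win_mat <- vapply(1:8, function(k) tx[k:(k + n_win - 1)],
                    character(n_win))
  match28 <- rowSums(win_mat[, 1:7, drop = FALSE] ==
                     matrix(comp, n_win, 7, byrow = TRUE)) == 7
  match27 <- rowSums(win_mat[, 2:7, drop = FALSE] ==
                     matrix(comp[2:7], n_win, 6, byrow = TRUE)) == 6
  a1 <- win_mat[, 8] == "A"
  type <- rep(NA_character_, n_win)
  type[match27 & !a1] <- "6mer"
  type[match27 & a1] <- "7mer-A1"
  type[match28 & !a1] <- "7mer-m8"
  type[match28 & a1] <- "8mer"
  hit <- which(!is.na(type))
  data.frame(position = hit - 1L, site_type = type[hit],
             stringsAsFactors = FALSE)
}

## Simplified nearest-neighbour stacking table, kcal/mol.  Keys are the
## 5'->3' dinucleotide step on one strand of a Watson-Crick helix; the ten
## unique values are mirrored onto the reverse-complement step so lookups
## from either strand agree.
NN_STACK <- local({
  base <- c(AA = -0.93, AU = -1.10, UA = -1.33, CU = -2.08, CA = -2.11,
            GU = -2.24, GA = -2.35, CG = -2.36, GG = -3.26, GC = -3.42)
  full <- base
  for (k in names(base)) {
    rc <- chartr("ACGU", "UGCA",
                 paste(rev(strsplit(k, "")[[1]]), collapse = ""))
    full[rc] <- base[[k]]
  }
  full
})

GU_PENALTY <- 1.0
LOOP_PENALTY <- 3.0    # unpaired stretch on both strands between helices
BULGE_PENALTY <- 3.5   # unpaired stretch on one strand only

#' Hybridisation free energy of a miRNA against a site region
#'
#' Pairs the full miRNA against the site region (antiparallel) by dynamic
#' programming over a simplified nearest-neighbour model: stacked adjacent
#' pairs contribute the packaged Watson-Crick stacking energies (G:U pairs
#' stack as their Watson-Crick analogue with a +1.0 kcal/mol penalty per
#' G:U pair), an internal loop costs +3.0 and a bulge +3.5 kcal/mol, and
#' unpaired ends are free.  Returns the minimum free energy; any helix of
#' two or more stacked Watson-Crick pairs gives a value <= 0, and the
#' empty structure gives 0.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param site_region Transcript region (5'->3'), typically the seed site
#'   extended upstream to at least the miRNA length.
#' @return Minimum free energy in kcal/mol (<= 0).
#' @export
duplex_energy <- function(mirna, site_region) {
  if (nchar(site_region) == 0 || nchar(mirna) == 0) return(0.0)
  a <- strsplit(as_rna(mirna), "")[[1]]
  b <- rev(strsplit(as_rna(site_region), "")[[1]])  # antiparallel
  n <- length(a); m <- length(b)
  pairable <- outer(a, b, function(x, y) is_wc_pair(x, y) | is_gu_pair(x, y))
  gu <- outer(a, b, is_gu_pair)
  ## wc-analogue base on the miRNA strand for stacking lookups: for a G:U
  ## pair the stacking uses the same strand letters, penalised separately
  INF <- Inf
  M <- matrix(INF, n, m)        # min energy of structure whose last pair
                                # is (i, j)
  P <- matrix(INF, n, m)        # prefix min of M over [1..i, 1..j]
  colmin <- matrix(INF, n, m)   # min over i' <= i of M[i', j]
  rowmin <- matrix(INF, n, m)   # min over j' <= j of M[i, j']
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (pairable[i, j]) {
        open_e <- GU_PENALTY * gu[i, j]
        e <- open_e                                  # open a new helix
        if (i > 1 && j > 1) {
          if (is.finite(M[i - 1, j - 1]) && pairable[i - 1, j - 1]) {
            step <- paste0(a[i - 1], a[i])
            e <- min(e, M[i - 1, j - 1] + NN_STACK[[step]] + open_e)
          }
          if (i > 2 && j > 2 && is.finite(P[i - 2, j - 2]))
            e <- min(e, P[i - 2, j - 2] + LOOP_PENALTY + open_e)
          if (i > 2 && is.finite(colmin[i - 2, j - 1]))
            e <- min(e, colmin[i - 2, j - 1] + BULGE_PENALTY + open_e)
          if (j > 2 && is.finite(rowmin[i - 1, j - 2]))
            e <- min(e, rowmin[i - 1, j - 2] + BULGE_PENALTY + open_e)
        }
        M[i, j] <- e
      }
      up <- if (i > 1) P[i - 1, j] else INF
      left <- if (j > 1) P[i, j - 1] else INF
      diagp <- if (i > 1 && j > 1) P[i - 1, j - 1] else INF
      P[i, j] <- min(M[i, j], up, left)
      colmin[i, j] <- min(M[i, j], if (i > 1) colmin[i - 1, j] else INF)
      rowmin[i, j] <- min(M[i, j], if (j > 1) rowmin[i, j - 1] else INF)
    }
  }
  e <- min(0, suppressWarnings(min(M)))
  if (!is.finite(e)) 0.0 else e
}

#' A/U fraction of the sequence flanking a site
#'
#' @param transcript Transcript sequence.
#' @param site_start 0-based start of the 8-nt site window.
#' @param site_len Site length in nt.
#' @param flank Flank length in nt on each side (truncated at the
#'   transcript ends).
#' @return Fraction of A/U in the flanks, in \code{[0, 1]} (\code{NaN} if
#'   both flanks are empty).
#' @export
au_context <- function(transcript, site_start, site_len = 8L, flank = 30L) {
  tx <- strsplit(as_rna(transcript), "")[[1]]
  s <- site_start + 1L
  if (s < 1 || s + site_len - 1L > length(tx))
    stop("site not within transcript")
  idx <- intersect(c((s - flank):(s - 1L),
                     (s + site_len):(s + site_len + flank - 1L)),
                   seq_along(tx))
  mean(tx[idx] %in% c("A", "U"))
}

#' k-of-n consensus vote
#'
#' @param votes Logical vector of per-predictor votes.
#' @param k Minimum number of positive votes (>= 1).
#' @return TRUE iff at least \code{k} votes are positive.
#' @export
consensus_vote <- function(votes, k) {
  if (k < 1) stop("configuration error: k must be >= 1")
  if (k > length(votes)) stop("configuration error: k exceeds predictors")
  sum(votes) >= k
}

#' Default thresholds of the three built-in site predictors
#' @return Named list: seed_min (minimum seed type for the seed vote),
#'   energy_max (kcal/mol), context_min_type and context_min_au.
#' @export
predictor_thresholds <- function() {
  list(seed_min = "7mer-A1", energy_max = -14,
       context_min_type = "6mer", context_min_au = 0.5)
}

site_type_rank <- function(type) match(type, c(SITE_TYPES, "none"))

#' Predict miRNA-transcript binding with three predictors and consensus
#'
#' For every miRNA x transcript pair: scans seed sites; votes
#' \code{seed} (a site of at least the minimum seed type exists),
#' \code{energy} (the best hybridisation energy over sites, with each site
#' extended upstream to the miRNA length plus 4 nt, is at or below the
#' threshold) and \code{context} (a site of at least the context type has
#' A/U flank fraction at or above the threshold).  Consensus is a k-of-3
#' vote.
#'
#' @param mirnas,transcripts Named RNA character vectors.
#' @param k Votes required (2 for lncRNA-miRNA edges, 3 for miRNA-mRNA
#'   edges, per the consensus rule).
#' @param thresholds See \code{\link{predictor_thresholds}}.
#' @return data.frame(mirna, transcript, vote_seed, vote_energy,
#'   vote_context, n_votes, consensus, best_position, best_type,
#'   best_energy).
#' @export
predict_binding <- function(mirnas, transcripts, k = 2,
                            thresholds = predictor_thresholds()) {
  rows <- list()
  for (mi in names(mirnas)) {
    lm <- nchar(mirnas[[mi]])
    for (ti in names(transcripts)) {
      tx <- transcripts[[ti]]
      sites <- scan_seed_sites(mirnas[[mi]], tx)
      if (nrow(sites) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          mirna = mi, transcript = ti, vote_seed = FALSE,
          vote_energy = FALSE, vote_context = FALSE, n_votes = 0L,
          consensus = FALSE, best_position = NA_integer_,
          best_type = NA_character_, best_energy = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      sites$rank <- site_type_rank(sites$site_type)
      sites$energy <- vapply(sites$position, function(p) {
        r_end <- p + 8L                       # 1-based end of the window
        r_start <- max(1L, r_end - lm - 4L + 1L)
        duplex_energy(mirnas[[mi]], substr(tx, r_start, r_end))
      }, numeric(1))
      sites$au <- vapply(sites$position, function(p)
        au_context(tx, p), numeric(1))
      v_seed <- any(sites$rank <= site_type_rank(thresholds$seed_min))
      v_energy <- any(sites$energy <= thresholds$energy_max)
      v_context <- any(sites$rank <=
                         site_type_rank(thresholds$context_min_type) &
                       sites$au >= thresholds$context_min_au)
      votes <- c(v_seed, v_energy, v_context)
      best <- sites[order(sites$rank, sites$energy, sites$position), ][1, ]
      rows[[length(rows) + 1]] <- data.frame(
        mirna = mi, transcript = ti, vote_seed = v_seed,
        vote_energy = v_energy, vote_context = v_context,
        n_votes = sum(votes), consensus = consensus_vote(votes, k),
        best_position = best$position, best_type = best$site_type,
        best_energy = best$energy, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble lncRNA-miRNA-mRNA ceRNA triads
#'
#' Joins consensus lncRNA-miRNA and miRNA-mRNA edges on the shared miRNA.
#' All three members must carry a DE direction; \code{strict} mode keeps
#' only triads with \code{sign(lncRNA) = sign(mRNA) = -sign(miRNA)} (the
#' competing-endogenous-RNA direction logic), \code{permissive} keeps all
#' joins.  Edges referencing features absent from the DE table are dropped
#' with a message.
#'
#' @param de_table DE table with feature_id and direction columns.
#' @param lnc_mir_edges data.frame with columns transcript (lncRNA id) and
#'   mirna, consensus edges only are used.
#' @param mir_mrna_edges Same, with transcript = mRNA id.
#' @param mode \code{"strict"} or \code{"permissive"}.
#' @return data.frame(lncrna, mirna, mrna, lnc_dir, mir_dir, mrna_dir),
#'   deduplicated and deterministically sorted.
#' @export
assemble_triads <- function(de_table, lnc_mir_edges, mir_mrna_edges,
                            mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  dir_of <- setNames(de_table$direction, de_table$feature_id)
  take <- function(edges) {
    if (!is.null(edges$consensus))
      edges <- edges[edges$consensus, , drop = FALSE]
    known <- edges$transcript %in% names(dir_of) &
      edges$mirna %in% names(dir_of)
    if (any(!known))
      message(sprintf("%d edge(s) with ids absent from the DE table dropped",
                      sum(!known)))
    edges[known, , drop = FALSE]
  }
  lm <- take(lnc_mir_edges)
  mm <- take(mir_mrna_edges)
  out <- data.frame(lncrna = character(0), mirna = character(0),
                    mrna = character(0), lnc_dir = character(0),
                    mir_dir = character(0), mrna_dir = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(lm) == 0 || nrow(mm) == 0) return(out)
  j <- merge(lm[, c("transcript", "mirna")], mm[, c("mirna", "transcript")],
             by = "mirna", suffixes = c("_lnc", "_mrna"))
  if (nrow(j) == 0) return(out)
  out <- data.frame(lncrna = j$transcript_lnc, mirna = j$mirna,
                    mrna = j$transcript_mrna, stringsAsFactors = FALSE)
  out$lnc_dir <- dir_of[out$lncrna]
  out$mir_dir <- dir_of[out$mirna]
  out$mrna_dir <- dir_of[out$mrna]
  de_dirs <- c("up", "down")
  out <- out[out$lnc_dir %in% de_dirs & out$mir_dir %in% de_dirs &
             out$mrna_dir %in% de_dirs, , drop = FALSE]
  if (mode == "strict") {
    flip <- c(up = "down", down = "up")
    out <- out[out$lnc_dir == out$mrna_dir &
               out$mir_dir == flip[out$lnc_dir], , drop = FALSE]
  }
  out <- unique(out)
  out <- out[order(out$lncrna, out$mirna, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
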