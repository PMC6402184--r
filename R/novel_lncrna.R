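## Five-step novel-lncRNA identification: known-overlap removal, length,
## longest ORF, protein-domain motifs, and a hexamer coding-potential score.

#' Longest open reading frame on the sense strand
#'
#' Scans the three forward frames for AUG..\{UAA, UAG, UGA\}; ORF length is
#' counted from the start codon through the stop codon inclusive.  Ties are
#' broken by the smallest start position.
#'
#' @param seq RNA sequence (character scalar; T converted to U with a
#'   warning).
#' @return \code{list(orf_length_nt, start, frame)} with \code{start}
#'   0-based; length 0 (start/frame \code{NA}) when no ORF exists.
#' @export
find_longest_orf <- function(seq) {
  if (nchar(seq) == 0)
    return(list(orf_length_nt = 0L, start = NA_integer_, frame = NA_integer_))
  seq <- as_rna(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  best <- list(orf_length_nt = 0L, start = NA_integer_, frame = NA_integer_)
  for (f in 0:2) {
    n_cod <- (n - f) %/% 3
    if (n_cod < 2) next
    idx <- f + seq_len(n_cod * 3)
    codons <- paste0(chars[idx[c(TRUE, FALSE, FALSE)]],
                     chars[idx[c(FALSE, TRUE, FALSE)]],
                     chars[idx[c(FALSE, FALSE, TRUE)]])
    starts <- which(codons == "AUG")
    stops <- which(codons %in% c("UAA", "UAG", "UGA"))
    if (length(starts) == 0 || length(stops) == 0) next
    for (s in starts) {
      j <- stops[stops > s]
      if (length(j) == 0) next
      len <- (j[1] - s + 1L) * 3L
      start0 <- f + (s - 1L) * 3L   # 0-based
      if (len > best$orf_length_nt ||
          (len == best$orf_length_nt && start0 < best$start)) {
        best <- list(orf_length_nt = len, start = start0, frame = f)
      }
    }
  }
  best
}

## In-frame hexamer (dicodon) strings of a sequence read from position 1.
inframe_hexamers <- function(seq) {
  n <- nchar(seq)
  if (n < 6) return(character(0))
  starts <- seq(1, n - 5, by = 3)
  substring(seq, starts, starts + 5)
}

#' Train the hexamer coding-potential model
#'
#' Builds a 4096-entry table of log-odds (coding over noncoding) of
#' in-frame hexamer frequencies.  Coding training sequences are read as CDS
#' (frame fixed at position 1, hexamers stepped by codon); noncoding
#' sequences contribute hexamers at every offset.  Additive pseudocounts
#' keep unseen hexamers finite.
#'
#' @param coding_seqs,noncoding_seqs Character vectors of RNA sequences.
#' @param pseudocount Added to every hexamer count before normalising.
#' @param w1 Weight on ORF coverage (ORF nt / transcript nt, centred at
#'   0.5).
#' @param w2 Weight on the mean in-frame hexamer log-odds over the longest
#'   ORF.
#' @return A \code{cp_model}: \code{list(logodds, w1, w2)}.
#' @export
train_cp_model <- function(coding_seqs, noncoding_seqs,
                           pseudocount = 1, w1 = 2, w2 = 4) {
  hexamers <- apply(expand.grid(rep(list(RNA_ALPHABET), 6))[, 6:1],
                    1, paste, collapse = "")
  count_tab <- function(hx) {
    tab <- table(factor(hx, levels = hexamers))
    as.numeric(tab) + pseudocount
  }
  cod <- count_tab(unlist(lapply(coding_seqs, inframe_hexamers)))
  all_hex <- function(s) {
    n <- nchar(s)
    if (n < 6) return(character(0))
    substring(s, 1:(n - 5), 6:n)
  }
  non <- count_tab(unlist(lapply(noncoding_seqs, all_hex)))
  logodds <- setNames(log(cod / sum(cod)) - log(non / sum(non)), hexamers)
  structure(list(logodds = logodds, w1 = w1, w2 = w2), class = "cp_model")
}

#' Generate a toy coding/noncoding training set
#'
#' Coding sequences are CDSs drawn from a deliberately skewed codon-usage
#' distribution (start codon, biased sense codons, one stop); noncoding
#' sequences are uniform random RNA.  Used to train the packaged toy
#' coding-potential model at run time.
#'
#' @param n_each Sequences per class.
#' @param n_codons Codons per coding sequence (noncoding sequences get the
#'   matching nt length).
#' @param seed Integer seed.
#' @return \code{list(coding, noncoding)} character vectors.
#' @export
toy_cp_training_set <- function(n_each = 60, n_codons = 150, seed = 101) {
  stops <- c("UAA", "UAG", "UGA")
  all_codons <- apply(expand.grid(rep(list(RNA_ALPHABET), 3))[, 3:1],
                      1, paste, collapse = "")
  sense <- setdiff(all_codons, stops)
  ## skewed usage: a 20-codon "preferred" subset carries 90% of the mass
  with_sim_seed(seed, 0L, {
    preferred <- sample(sense, 20)
    w <- ifelse(sense %in% preferred, 0.9 / 20, 0.1 / length(sense))
    coding <- vapply(seq_len(n_each), function(i) {
      paste0("AUG", paste(sample(sense, n_codons - 2, replace = TRUE,
                                 prob = w), collapse = ""),
             sample(stops, 1))
    }, character(1))
    noncoding <- vapply(seq_len(n_each), function(i)
      random_rna(n_codons * 3), character(1))
    list(coding = coding, noncoding = noncoding)
  })
}

#' Coding-potential score of a transcript
#'
#' \code{w1 * (ORF coverage - 0.5) + w2 * mean in-frame hexamer log-odds
#' over the longest ORF}.  Higher is more coding-like; a transcript with no
#' ORF scores \code{-w1/2} (hexamer term 0).  This is an explicit,
#' configurable stand-in for SVM-based coding-potential software; the
#' decision threshold used by the cascade stays at -1.
#'
#' @param seq RNA sequence.
#' @param model A \code{cp_model} from \code{\link{train_cp_model}}.
#' @return Numeric score (deterministic; independent of sequence id or
#'   FASTA line wrapping).
#' @export
coding_potential_score <- function(seq, model) {
  if (!inherits(model, "cp_model"))
    stop("configuration error: untrained coding-potential model")
  seq <- as_rna(seq)
  orf <- find_longest_orf(seq)
  cov <- orf$orf_length_nt / nchar(seq)
  hex_term <- 0
  if (orf$orf_length_nt >= 6) {
    orf_seq <- substr(seq, orf$start + 1, orf$start + orf$orf_length_nt)
    hx <- inframe_hexamers(orf_seq)
    hex_term <- mean(model$logodds[hx])
  }
  model$w1 * (cov - 0.5) + model$w2 * hex_term
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: permutes a sequence while preserving its exact
#' dinucleotide counts (random Eulerian walk on the dinucleotide graph).
#'
#' @param seq RNA sequence.
#' @param seed Integer seed.
#' @return Shuffled sequence (character scalar).
#' @export
dinucleotide_shuffle <- function(seq, seed = 1) {
  s <- strsplit(as_rna(seq), "")[[1]]
  n <- length(s)
  if (n < 3) return(paste(s, collapse = ""))
  with_sim_seed(seed, 0L, {
    verts <- unique(s)
    edges <- split(s[-1], factor(s[-n], levels = verts))
    last <- s[n]
    repeat {
      ## pick one kept "final" out-edge per non-terminal vertex; accept if
      ## the kept edges connect every vertex to the terminal one
      kept <- lapply(verts, function(v) {
        if (v == last || length(edges[[v]]) == 0) NA_character_
        else sample(edges[[v]], 1)
      })
      names(kept) <- verts
      reach <- function(v, depth = 0) {
        if (depth > length(verts)) return(FALSE)
        if (v == last) return(TRUE)
        if (is.na(kept[[v]])) return(FALSE)
        reach(kept[[v]], depth + 1)
      }
      if (all(vapply(verts, function(v)
        length(edges[[v]]) == 0 || reach(v), logical(1)))) break
    }
    shuffled <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (is.na(kept[[v]])) return(sample(e))
      i <- match(kept[[v]], e)
      c(sample(e[-i]), e[i])
    })
    names(shuffled) <- verts
    ptr <- setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1] <- s[1]
    v <- s[1]
    for (i in 2:n) {
      nxt <- shuffled[[v]][ptr[[v]]]
      ptr[[v]] <- ptr[[v]] + 1L
      out[i] <- nxt
      v <- nxt
    }
    paste(out, collapse = "")
  })
}

#' Five-step novel-lncRNA filter cascade
#'
#' Applies, in order: (1) removal of transcripts with same-strand genomic
#' overlap (>= 1 bp) with a known annotation, (2) length >= 200 nt,
#' (3) longest ORF < 300 nt, (4) no protein-domain motif hit in any of the
#' three forward-frame translations, (5) coding-potential score < -1.
#' Evaluation is short-circuited: a transcript failing step k is not
#' evaluated at later steps (unevaluated fields are NA), and the verdict
#' records the first failing step.
#'
#' @param transcripts Named character vector of RNA sequences.
#' @param model A \code{cp_model}.
#' @param tx_coords Optional data.frame(id, chrom, start, end, strand) of
#'   the transcripts' genomic intervals (needed for step 1; transcripts
#'   without coordinates are treated as non-overlapping).
#' @param known Optional feature table of known transcripts
#'   (data.frame(id, chrom, start, end, strand, ...)).
#' @param min_length Minimum length in nt (inclusive; set
#'   \code{exclusive_length = TRUE} for a strict > comparison).
#' @param max_orf ORF gate: longest ORF must be < this many nt.
#' @param cp_threshold Coding-potential gate: score must be < this.
#' @param patterns Character vector of protein motif regular expressions
#'   (empty = gate passes, the default).
#' @param exclusive_length Use strictly-greater-than for the length gate.
#' @return Verdict data.frame (one row per transcript) with per-step
#'   pass columns and a \code{verdict} of \code{"novel_lncRNA"} or
#'   \code{"rejected:<step>"}; the evaluation order is recorded in the
#'   \code{"evaluation_log"} attribute.
#' @export
filter_cascade <- function(transcripts, model, tx_coords = NULL,
                           known = NULL, min_length = 200, max_orf = 300,
                           cp_threshold = -1, patterns = character(0),
                           exclusive_length = FALSE) {
  if (is.null(names(transcripts)) || any(names(transcripts) == ""))
    stop("transcripts must be named")
  overlap_ids <- character(0)
  if (!is.null(tx_coords) && !is.null(known) && nrow(known) > 0) {
    gq <- GenomicRanges::GRanges(tx_coords$chrom,
                                 IRanges::IRanges(tx_coords$start,
                                                  tx_coords$end),
                                 strand = tx_coords$strand)
    gk <- GenomicRanges::GRanges(known$chrom,
                                 IRanges::IRanges(known$start, known$end),
                                 strand = known$strand)
    hit <- GenomicRanges::countOverlaps(gq, gk, minoverlap = 1L,
                                        ignore.strand = FALSE) > 0
    overlap_ids <- tx_coords$id[hit]
  }
  steps <- c("known", "length", "orf", "domain", "cp")
  log_env <- new.env()
  rows <- lapply(names(transcripts), function(id) {
    seq <- as_rna(transcripts[[id]], id)
    evaluated <- character(0)
    row <- data.frame(transcript_id = id, known_overlap = NA,
                      length_nt = NA_integer_, longest_orf_nt = NA_integer_,
                      domain_hit = NA, cp_score = NA_real_,
                      pass_known = NA, pass_length = NA, pass_orf = NA,
                      pass_domain = NA, pass_cp = NA,
                      verdict = NA_character_, stringsAsFactors = FALSE)
    fail <- NULL
    for (step in steps) {
      evaluated <- c(evaluated, step)
      ok <- switch(step,
        known = {
          row$known_overlap <- id %in% overlap_ids
          row$pass_known <- !row$known_overlap
          row$pass_known
        },
        length = {
          row$length_nt <- nchar(seq)
          row$pass_length <- if (exclusive_length) row$length_nt > min_length
                             else row$length_nt >= min_length
          row$pass_length
        },
        orf = {
          row$longest_orf_nt <- find_longest_orf(seq)$orf_length_nt
          row$pass_orf <- row$longest_orf_nt < max_orf
          row$pass_orf
        },
        domain = {
          row$domain_hit <- length(patterns) > 0 &&
            any(vapply(translate_frames(seq), function(aa)
              any(vapply(patterns, grepl, logical(1), x = aa)),
              logical(1)))
          row$pass_domain <- !row$domain_hit
          row$pass_domain
        },
        cp = {
          row$cp_score <- coding_potential_score(seq, model)
          row$pass_cp <- row$cp_score < cp_threshold
          row$pass_cp
        })
      if (!ok) { fail <- step; break }
    }
    assign(id, evaluated, envir = log_env)
    row$verdict <- if (is.null(fail)) "novel_lncRNA"
                   else paste0("rejected:", fail)
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "evaluation_log") <- as.list(log_env)
  out
}

## Translations of the three forward frames (stops as '*').
translate_frames <- function(seq) {
  n <- nchar(seq)
  vapply(0:2, function(f) {
    len <- ((n - f) %/% 3) * 3
    if (len < 3) return("")
    as.character(Biostrings::translate(
      Biostrings::RNAString(substr(seq, f + 1, f + len)),
      if.fuzzy.codon = "X"))
  }, character(1))
}
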