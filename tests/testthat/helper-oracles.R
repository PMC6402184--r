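## Independent test oracles.  Each re-derives the quantity under test from
## a different formulation (closed-form tails, subset enumeration, quartic
## dynamic programs, naive scans) so agreement is evidence of correctness
## rather than of shared bugs.

## Audic-Claverie two-sided p via negative-binomial tails: the conditional
## distribution of y given x is NB(size = x + 1, prob = N1 / (N1 + N2)).
ac_oracle <- function(x, y, N1, N2) {
  pr <- N1 / (N1 + N2)
  lower <- sum(stats::dnbinom(0:y, size = x + 1, prob = pr))
  ## upper tail via the survival function; the complement-of-a-sum form
  ## loses all precision when the tail is ~1e-15
  upper <- if (y == 0) 1 else
    stats::pnbinom(y - 1, size = x + 1, prob = pr, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

## Benjamini-Hochberg step-up by hand.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  q <- numeric(n)
  q[o] <- pmin(1, adj)
  q
}

## Hypergeometric upper tail by enumeration of every size-n subset of an
## N-element universe whose first K elements form the gene set.
hyper_enum_oracle <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

## Cis-window membership straight from the interval condition.
cis_oracle <- function(linc, genes, window) {
  sel <- genes$chrom == linc$chrom &
    genes$end >= linc$start - window &
    genes$start <= linc$end + window
  genes$id[sel]
}

## Seed-site classification from the pairing geometry, written
## independently: window position k faces miRNA position 9 - k.
seed_oracle <- function(mirna, window8) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  m <- strsplit(mirna, "")[[1]]
  w <- strsplit(window8, "")[[1]]
  wc <- vapply(1:8, function(k) identical(w[k], comp[[m[9 - k]]]),
               logical(1))
  s27 <- all(wc[2:7])   # miRNA positions 2-7
  s8 <- wc[1]           # miRNA position 8
  a1 <- w[8] == "A"
  if (s27 && s8 && a1) "8mer"
  else if (s27 && s8) "7mer-m8"
  else if (s27 && a1) "7mer-A1"
  else if (s27) "6mer"
  else "none"
}

## Naive seed-site scan: classify every window individually.
scan_oracle <- function(mirna, transcript) {
  L <- nchar(transcript)
  if (L < 8) return(data.frame(position = integer(0),
                               site_type = character(0),
                               stringsAsFactors = FALSE))
  types <- vapply(1:(L - 7), function(s)
    seed_oracle(mirna, substr(transcript, s, s + 7)), character(1))
  hit <- which(types != "none")
  data.frame(position = hit - 1L, site_type = types[hit],
             stringsAsFactors = FALSE)
}

## Best local antiparallel pairing score by a quartic DP over predecessor
## pairs (every gap run priced per skipped base on either strand).
trans_oracle <- function(linc_seq, mrna_seq, scoring = trans_scoring()) {
  a <- strsplit(linc_seq, "")[[1]]
  b <- rev(strsplit(mrna_seq, "")[[1]])
  pscore <- function(x, y) {
    d <- paste0(x, y)
    if (d %in% c("GC", "CG")) scoring$gc
    else if (d %in% c("AU", "UA")) scoring$au
    else if (d %in% c("GU", "UG")) scoring$gu
    else scoring$mismatch
  }
  n <- length(a); m <- length(b)
  H <- matrix(-Inf, n, m)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- pscore(a[i], b[j])
    h <- s
    if (i > 1 && j > 1)
      for (i2 in 1:(i - 1)) for (j2 in 1:(j - 1))
        if (is.finite(H[i2, j2]))
          h <- max(h, H[i2, j2] + s +
                     scoring$gap * ((i - i2 - 1) + (j - j2 - 1)))
    H[i, j] <- h
    best <- max(best, h)
  }
  max(0, best)
}

## Duplex minimum free energy by a quartic DP over predecessor pairs,
## re-deriving the transition taxonomy (stack / internal loop / bulge)
## from the gap widths on each strand.
duplex_stack_table <- function() {
  base <- c(AA = -0.93, AU = -1.10, UA = -1.33, CU = -2.08, CA = -2.11,
            GU = -2.24, GA = -2.35, CG = -2.36, GG = -3.26, GC = -3.42)
  full <- base
  for (k in names(base)) {
    rc <- chartr("ACGU", "UGCA",
                 paste(rev(strsplit(k, "")[[1]]), collapse = ""))
    full[rc] <- base[[k]]
  }
  full
}

duplex_oracle <- function(mirna, site_region) {
  if (nchar(mirna) == 0 || nchar(site_region) == 0) return(0)
  a <- strsplit(mirna, "")[[1]]
  b <- rev(strsplit(site_region, "")[[1]])
  nn <- duplex_stack_table()
  is_wc <- function(x, y) paste0(x, y) %in% c("AU", "UA", "GC", "CG")
  is_gu <- function(x, y) paste0(x, y) %in% c("GU", "UG")
  n <- length(a); m <- length(b)
  E <- matrix(Inf, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!(is_wc(a[i], b[j]) || is_gu(a[i], b[j]))) next
    open <- 1.0 * is_gu(a[i], b[j])
    e <- open
    if (i > 1 && j > 1)
      for (i2 in 1:(i - 1)) for (j2 in 1:(j - 1))
        if (is.finite(E[i2, j2])) {
          di <- i - i2 - 1
          dj <- j - j2 - 1
          trans <- if (di == 0 && dj == 0) nn[[paste0(a[i2], a[i])]]
                   else if (di >= 1 && dj >= 1) 3.0
                   else 3.5
          e <- min(e, E[i2, j2] + trans + open)
        }
    E[i, j] <- e
  }
  e <- suppressWarnings(min(E))
  if (!is.finite(e)) 0 else min(0, e)
}

## Longest-ORF brute force: every AUG, first in-frame stop.
orf_oracle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best <- 0L; best_start <- NA_integer_
  i <- 1
  while (i + 2 <= n) {
    if (paste(ch[i:(i + 2)], collapse = "") == "AUG") {
      j <- i + 3
      while (j + 2 <= n) {
        cod <- paste(ch[j:(j + 2)], collapse = "")
        if (cod %in% c("UAA", "UAG", "UGA")) {
          len <- j + 2L - i + 1L
          if (len > best) { best <- len; best_start <- i - 1L }
          break
        }
        j <- j + 3
      }
    }
    i <- i + 1
  }
  list(orf_length_nt = best, start = best_start)
}

## Textbook Pearson correlation (sum formulation).
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

## Textbook Welch statistic.
welch_oracle <- function(case, control) {
  v1 <- stats::var(case) / length(case)
  v2 <- stats::var(control) / length(control)
  tt <- (mean(case) - mean(control)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(case) - 1) +
                         v2^2 / (length(control) - 1))
  list(t = tt, df = df,
       p = 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE))
}

## Dinucleotide count table of a sequence.
dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}

## RPKM-on-log2 expression used by the coexpression stage.
log_rpkm_expr <- function(cm) {
  log2(t(t(cm$counts) / cm$samples$library_size) * 1e9 /
         cm$features$length + 0.1)
}
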