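## Differential expression on pooled sequencing libraries: Audic-Claverie
## exact count test, RPKM fold changes, BH q-values, class-specific
## screening standards.

#' Reads per kilobase per million mapped reads
#'
#' \code{count * 1e9 / (feature_length * library_size)}.
#'
#' @param count Non-negative read count(s).
#' @param feature_length Feature length in bp (> 0).
#' @param library_size Total mapped reads in the library (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, feature_length, library_size) {
  if (any(feature_length <= 0) || any(library_size <= 0))
    stop("feature_length and library_size must be positive")
  count * 1e9 / (feature_length * library_size)
}

## log P(Y = y | x) for the Audic-Claverie conditional distribution with
## library-size ratio r = N2/N1:
##   P(Y=y|x) = r^y * (x+y)! / (x! y!) / (1+r)^(x+y+1)
ac_log_pmf <- function(y, x, log_r, log1p_r) {
  y * log_r + lchoose(x + y, y) - (x + y + 1) * log1p_r
}

#' Audic-Claverie two-sided p-value for a count difference
#'
#' Exact test for a difference between the counts of one feature in two
#' sequencing libraries, based on the conditional distribution of the second
#' count given the first (with the library-size ratio folded in).  Evaluated
#' in log space so counts in the 1e5 range do not overflow.  The two-sided
#' p-value doubles the smaller tail (both tails include the observed count)
#' and is capped at 1.
#'
#' @param x,y Observed counts in library 1 and library 2 (>= 0).
#' @param N1,N2 Library sizes (> 0).
#' @return Two-sided p-value in (0, 1].
#' @export
ac_pvalue <- function(x, y, N1 = 1, N2 = 1) {
  if (length(x) > 1 || length(y) > 1)
    return(mapply(ac_pvalue, x, y, N1, N2))
  stopifnot_scalar_count(x, "x"); stopifnot_scalar_count(y, "y")
  if (N1 <= 0 || N2 <= 0) stop("library sizes must be positive")
  r <- N2 / N1
  log_r <- log(N2) - log(N1)
  log1p_r <- log1p(r)
  ## both tails by direct summation; the upper tail is truncated far past
  ## the distribution mode so the neglected mass is ~0 at double precision
  mode_up <- (x + 1) * r
  ymax <- ceiling(max(y, mode_up) + 12 * sqrt(mode_up * (1 + r) + 10) + 100)
  p_le <- exp(logsumexp(ac_log_pmf(0:y, x, log_r, log1p_r)))
  p_ge <- exp(logsumexp(ac_log_pmf(y:ymax, x, log_r, log1p_r)))
  min(1, 2 * min(p_le, p_ge))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (\code{stats::p.adjust} with \code{method="BH"}),
#' mapped back to input order.
#'
#' @param pvals Vector of p-values in \code{[0, 1]}.
#' @return q-values in input order (empty input gives empty output).
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Default screening standards per feature class
#'
#' lncRNA/mRNA: |log2fc| >= 1 and q < 0.001; miRNA: |log2fc| >= 1 and
#' q < 0.05.
#' @return Named list of \code{list(lfc, q)} per class.
#' @export
de_thresholds <- function() {
  list(lncRNA = list(lfc = 1, q = 0.001),
       mRNA   = list(lfc = 1, q = 0.001),
       miRNA  = list(lfc = 1, q = 0.05))
}

#' Classify a feature as up / down / not significant
#'
#' @param log2fc Log2 fold change (case over control).
#' @param q BH-adjusted q-value.
#' @param class One of \code{"lncRNA"}, \code{"mRNA"}, \code{"miRNA"}.
#' @param thresholds Screening standards as from \code{\link{de_thresholds}}.
#' @return \code{"up"}, \code{"down"} or \code{"ns"} (vectorised).
#' @export
classify_de <- function(log2fc, q, class, thresholds = de_thresholds()) {
  if (!all(class %in% names(thresholds)))
    stop("configuration error: unknown feature class")
  th_lfc <- unname(vapply(thresholds[class], `[[`, numeric(1), "lfc"))
  th_q <- unname(vapply(thresholds[class], `[[`, numeric(1), "q"))
  ifelse(q < th_q & log2fc >= th_lfc, "up",
         ifelse(q < th_q & log2fc <= -th_lfc, "down", "ns"))
}

#' Differential expression on pooled per-group libraries
#'
#' Sums counts (and library sizes) within each group into one pooled case
#' and one pooled control library, applies the Audic-Claverie test per
#' feature, computes the RPKM fold change with a pseudocount, adjusts p to
#' q by Benjamini-Hochberg (within each feature class), and applies the
#' class-specific screening standard.
#'
#' @param cm A \code{\link{count_matrix}}.
#' @param thresholds Screening standards (see \code{\link{de_thresholds}}).
#' @param pseudocount RPKM pseudocount added to both groups before the
#'   ratio (avoids division by zero).
#' @return DE table (data.frame) with one row per feature, sorted by q:
#'   feature_id, class, rpkm_case, rpkm_control, fold_change, log2fc, p, q,
#'   direction.
#' @export
run_de <- function(cm, thresholds = de_thresholds(), pseudocount = 0.1) {
  stopifnot(inherits(cm, "count_matrix"))
  case <- cm$samples$group == "case"
  if (!any(case) || !all(case %in% c(TRUE, FALSE)) || all(case))
    stop("need at least one sample per group")
  miss <- is.na(cm$features$length) | cm$features$length <= 0
  if (any(miss)) {
    warning(sprintf("%d feature(s) without a valid length skipped",
                    sum(miss)))
  }
  keep <- !miss
  x_case <- rowSums(cm$counts[keep, case, drop = FALSE])
  x_ctrl <- rowSums(cm$counts[keep, !case, drop = FALSE])
  n_case <- sum(cm$samples$library_size[case])
  n_ctrl <- sum(cm$samples$library_size[!case])
  len <- cm$features$length[keep]
  rpkm_case <- rpkm(x_case, len, n_case)
  rpkm_ctrl <- rpkm(x_ctrl, len, n_ctrl)
  fc <- (rpkm_case + pseudocount) / (rpkm_ctrl + pseudocount)
  p <- ac_pvalue(x_ctrl, x_case, n_ctrl, n_case)
  cls <- cm$features$class[keep]
  q <- stats::ave(p, cls, FUN = bh_adjust)
  out <- data.frame(feature_id = cm$features$feature_id[keep],
                    class = cls,
                    rpkm_case = rpkm_case, rpkm_control = rpkm_ctrl,
                    fold_change = fc, log2fc = log2(fc),
                    p = p, q = q,
                    direction = classify_de(log2(fc), q, cls, thresholds),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$q, out$p, out$feature_id), , drop = FALSE]
}

#' Compare DE calls with a planted truth manifest
#'
#' @param de_table Output of \code{\link{run_de}}.
#' @param truth A \code{truth_manifest} (its \code{de} slot).
#' @return \code{list(sensitivity, fdr, n_called, n_true)}; sensitivity is
#'   the fraction of planted DE features called in the planted direction,
#'   FDR the fraction of calls that are not planted.
#' @export
de_recovery <- function(de_table, truth) {
  planted <- truth$de
  called <- de_table[de_table$direction != "ns", , drop = FALSE]
  dir_truth <- setNames(ifelse(planted$log2fc > 0, "up", "down"),
                        planted$feature_id)
  hit <- called$feature_id %in% planted$feature_id &
    called$direction == dir_truth[called$feature_id]
  list(sensitivity = if (nrow(planted)) sum(hit) / nrow(planted) else NA_real_,
       fdr = if (nrow(called)) mean(!called$feature_id %in%
                                      planted$feature_id) else 0,
       n_called = nrow(called), n_true = nrow(planted))
}
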