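## Small statistics behind the wet-lab validation readouts: relative qPCR
## quantification (Livak 2^-ddCt), Welch two-group comparison, and Spearman
## correlation of a biomarker against a clinical activity score.

#' Relative expression by the 2^-ddCt method
#'
#' Per-sample delta-Ct (target minus reference Ct) is referenced to the
#' mean delta-Ct of the control group:
#' \code{fold = 2^-(dCt_sample - mean(dCt_control))}.
#'
#' @param records data.frame(sample_id, group, target_ct, reference_ct)
#'   with group in case/control and positive Ct values.
#' @return data.frame(sample_id, group, dct, fold_change).
#' @export
ddct_fold_change <- function(records) {
  stopifnot(all(c("sample_id", "group", "target_ct", "reference_ct") %in%
                  names(records)))
  if (any(records$target_ct <= 0 | records$reference_ct <= 0))
    stop("Ct values must be positive")
  ctrl <- records$group == "control"
  if (!any(ctrl)) stop("need at least one control sample")
  dct <- records$target_ct - records$reference_ct
  ddct <- dct - mean(dct[ctrl])
  data.frame(sample_id = records$sample_id, group = records$group,
             dct = dct, fold_change = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of the (average-tie) ranks; two-sided p from the t
#' transform with n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return \code{list(rho, p)}; constant input gives \code{rho = NA} and a
#'   \code{reason}.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("vectors must have equal length")
  if (n < 3) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, reason = "constant input"))
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, reason = NA_character_)
}

#' Two-group comparison of a continuous variable
#'
#' Welch's unequal-variance t test by default; \code{pooled = TRUE} gives
#' the classical equal-variance test.
#'
#' @param case,control Numeric vectors, each n >= 2.
#' @param pooled Use the pooled-variance (Student) test.
#' @return \code{list(t, p, df)} (two-sided).
#' @export
two_group_test <- function(case, control, pooled = FALSE) {
  if (length(case) < 2 || length(control) < 2)
    stop("need at least 2 observations per group")
  ht <- stats::t.test(case, control, var.equal = pooled)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}
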