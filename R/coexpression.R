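## lincRNA x mRNA Pearson coexpression network with an |r| threshold
## screen.  The correlation threshold (default 0.85) is the only screen;
## p-values are reported but not used for filtering.

#' Pearson correlation and t-based p-value for one feature pair
#'
#' @param x,y Equal-length expression vectors (n >= 3), non-constant.
#' @return \code{list(r, p)}; \code{p} is two-sided from the t transform
#'   with n - 2 degrees of freedom.  Constant input gives \code{r = NA}
#'   with reason \code{"constant profile"}.
#' @export
pearson_edge <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("vectors must have equal length")
  if (n < 3) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, reason = "constant profile"))
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, reason = NA_character_)
}

#' Build the bipartite lincRNA-mRNA coexpression network
#'
#' Computes all pairwise Pearson correlations between the rows of the two
#' expression matrices (matching sample columns) and retains edges with
#' \code{|r| >= threshold}.  Absolute value is used so negative
#' co-expression survives the screen.  Nodes with no retained edge are
#' excluded from the degree summary.
#'
#' @param linc_expr,mrna_expr Numeric matrices, features x samples, with
#'   rownames; identical column (sample) sets.
#' @param threshold Correlation screen (default 0.85).
#' @return \code{list(edges, degrees, n_positive, n_negative)}; edges is a
#'   data.frame(linc_id, mrna_id, r, p, sign).
#' @export
build_network <- function(linc_expr, mrna_expr, threshold = 0.85) {
  if (ncol(linc_expr) != ncol(mrna_expr) ||
      !setequal(colnames(linc_expr), colnames(mrna_expr)))
    stop("input error: sample columns do not match")
  mrna_expr <- mrna_expr[, colnames(linc_expr), drop = FALSE]
  n <- ncol(linc_expr)
  ok_l <- apply(linc_expr, 1, stats::sd) > 0
  ok_m <- apply(mrna_expr, 1, stats::sd) > 0
  R <- stats::cor(t(linc_expr[ok_l, , drop = FALSE]),
                  t(mrna_expr[ok_m, , drop = FALSE]))
  hit <- which(abs(R) >= threshold, arr.ind = TRUE)
  edges <- data.frame(
    linc_id = rownames(R)[hit[, 1]],
    mrna_id = colnames(R)[hit[, 2]],
    r = R[hit], stringsAsFactors = FALSE)
  edges$p <- vapply(edges$r, function(r) {
    if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    }
  }, numeric(1))
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  edges <- edges[order(edges$linc_id, edges$mrna_id), , drop = FALSE]
  rownames(edges) <- NULL
  deg <- c(table(edges$linc_id), table(edges$mrna_id))
  list(edges = edges,
       degrees = data.frame(node = names(deg), degree = as.integer(deg),
                            stringsAsFactors = FALSE),
       n_positive = sum(edges$sign == "positive"),
       n_negative = sum(edges$sign == "negative"))
}

#' Write an edge list in SIF format
#' @param edges data.frame whose first two columns are node ids.
#' @param path Output file.
#' @param relation Interaction label.
#' @export
write_sif <- function(edges, path, relation = "coexpr") {
  lines <- if (nrow(edges) == 0) character(0)
           else paste(edges[[1]], relation, edges[[2]])
  writeLines(lines, path)
  invisible(path)
}
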