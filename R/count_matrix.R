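#' Construct a count matrix container
#'
#' Holds non-negative integer counts (features x samples) together with the
#' per-sample group labels and library sizes and the per-feature class and
#' length needed for RPKM.  Library sizes may be externally supplied (e.g.
#' total mapped reads); by default they are the column sums.
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param group Character/factor vector, one of \code{"case"}/\code{"control"}
#'   per sample.
#' @param feature_class Character vector per feature
#'   (\code{"lncRNA"/"miRNA"/"mRNA"}).
#' @param feature_length Numeric vector of feature lengths in bp.
#' @param library_size Optional positive numeric vector per sample; defaults
#'   to \code{colSums(counts)}.
#' @return An object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, group, feature_class, feature_length,
                         library_size = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature and sample names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("feature and sample ids must be unique")
  group <- as.character(group)
  if (length(group) != ncol(counts))
    stop("group must have one entry per sample")
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (is.null(library_size)) library_size <- colSums(counts)
  if (any(library_size <= 0)) stop("library sizes must be positive")
  stopifnot(length(feature_class) == nrow(counts),
            length(feature_length) == nrow(counts))
  structure(list(
    counts = counts,
    samples = data.frame(sample_id = colnames(counts), group = group,
                         library_size = as.numeric(library_size),
                         stringsAsFactors = FALSE),
    features = data.frame(feature_id = rownames(counts),
                          class = as.character(feature_class),
                          length = as.numeric(feature_length),
                          stringsAsFactors = FALSE)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%d case, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$group == "case"),
              sum(x$samples$group == "control")))
  cat("classes:", paste(sprintf("%s=%d", names(table(x$features$class)),
                                table(x$features$class)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Pool samples into sequencing libraries
#'
#' Sums counts (and library sizes) of samples assigned to the same pool,
#' emulating a design where RNA from several subjects is mixed and sequenced
#' as one library.  Groups must be homogeneous within a pool.
#'
#' @param cm A \code{count_matrix}.
#' @param pools Vector (one entry per sample) naming the pool each sample
#'   belongs to.
#' @return A pooled \code{count_matrix} with one column per pool.
#' @export
pool_samples <- function(cm, pools) {
  pools <- as.character(pools)
  if (length(pools) != ncol(cm$counts))
    stop("pools must have one entry per sample")
  gr <- tapply(cm$samples$group, pools, unique)
  if (any(lengths(gr) != 1))
    stop("a pool mixes case and control samples")
  pool_ids <- unique(pools)  # keep first-appearance order
  pooled <- vapply(pool_ids, function(p)
    rowSums(cm$counts[, pools == p, drop = FALSE]),
    numeric(nrow(cm$counts)))
  libsz <- vapply(pool_ids, function(p)
    sum(cm$samples$library_size[pools == p]), numeric(1))
  count_matrix(pooled, group = unlist(gr[pool_ids]),
               feature_class = cm$features$class,
               feature_length = cm$features$length,
               library_size = libsz)
}

#' Write counts and the sample sheet as TSV
#' @param cm A \code{count_matrix}.
#' @param counts_path,samples_path Output files.
#' @export
write_counts_tsv <- function(cm, counts_path, samples_path = NULL) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(samples_path))
    utils::write.table(cm$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(counts_path)
}

#' Read a counts TSV plus sample sheet back into a count matrix
#' @param counts_path TSV with a \code{feature_id} column plus one column
#'   per sample.
#' @param samples_path TSV with columns sample_id, group, library_size.
#' @param feature_class,feature_length Per-feature metadata vectors (in file
#'   order).
#' @export
read_counts_tsv <- function(counts_path, samples_path,
                            feature_class, feature_length) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$feature_id
  ss <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  counts <- counts[, ss$sample_id, drop = FALSE]
  count_matrix(counts, group = ss$group, feature_class = feature_class,
               feature_length = feature_length,
               library_size = ss$library_size)
}
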