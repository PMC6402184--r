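## Hypergeometric over-representation of a query gene set against a
## GMT-style gene-set collection; the p < 0.05 screen is the default flag.

#' Upper-tail hypergeometric p-value
#'
#' \code{P(X >= k)} for the overlap of a size-\code{n} query with a
#' size-\code{K} set in a universe of \code{N} genes, summed in log space.
#'
#' @param k Observed overlap.
#' @param K Gene-set size.
#' @param n Query size.
#' @param N Universe size.
#' @return Upper-tail p-value.
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  i <- k:min(K, n)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, exp(logsumexp(lp)))
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param path GMT file.
#' @return Named list of character vectors (the description is kept as the
#'   \code{"description"} attribute of each set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    structure(unique(f[-(1:2)]), description = f[2])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  if (any(!nzchar(names(sets)))) stop("empty set name in GMT")
  sets
}

#' Write gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    paste(c(nm, if (is.null(desc)) "" else desc, sets[[nm]]),
          collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Over-representation analysis of a query gene set
#'
#' One hypergeometric upper-tail test per set; sets are trimmed to the
#' universe, query ids outside the universe are dropped with a message.
#' Rows with \code{p < alpha} are flagged significant (the screening
#' standard); a BH q-value is reported alongside but not used for the
#' flag.
#'
#' @param query Character vector of gene ids.
#' @param sets Named list of character vectors (e.g. \code{read_gmt}).
#' @param universe Character vector of all genes; defaults to the union of
#'   the sets.
#' @param alpha Significance screen on the raw p-value.
#' @return data.frame(set, k, K, n, N, p, q, significant) sorted by p
#'   ascending, ties by set name.
#' @export
enrich <- function(query, sets, universe = NULL, alpha = 0.05) {
  if (length(sets) == 0)
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  if (is.null(universe)) universe <- unique(unlist(sets))
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0)
    message(sprintf("%d query id(s) outside the universe dropped",
                    length(outside)))
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  res <- do.call(rbind, lapply(sort(names(sets)), function(nm) {
    members <- intersect(sets[[nm]], universe)
    k <- length(intersect(query, members))
    data.frame(set = nm, k = k, K = length(members), n = n, N = N,
               p = hypergeom_p(k, length(members), n, N),
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_adjust(res$p)
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
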