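## Internal helpers shared across modules.

## log(sum(exp(x))) without overflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

RNA_ALPHABET <- c("A", "C", "G", "U")

## Reverse complement of an RNA string (character scalar).
rna_revcomp <- function(seq) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

rna_complement_base <- function(b) chartr("ACGU", "UGCA", b)

## Coerce DNA-alphabet input to RNA with a warning, and validate.
as_rna <- function(seq, id = "<sequence>") {
  seq <- toupper(seq)
  if (grepl("T", seq, fixed = TRUE)) {
    warning(sprintf("sequence '%s' contains T; converting to U (RNA)", id))
    seq <- chartr("T", "U", seq)
  }
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), RNA_ALPHABET)
  if (length(bad) > 0)
    stop(sprintf("sequence '%s' contains non-RNA characters: %s",
                 id, paste(bad, collapse = ",")))
  seq
}

## Draw a uniform random RNA string of length n.
random_rna <- function(n, alphabet = RNA_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

is_gu_pair <- function(a, b) {
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x != floor(x))
    stop(sprintf("%s must be a single non-negative integer", name))
}
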