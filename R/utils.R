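#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq width
NULL

# reverse complement of a plain character vector
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  All stochastic package code funnels through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# stable text key for a normalized SHIMMER pair; hashes are 53-bit integers
# stored exactly in doubles, so %.0f is lossless
pair_key <- function(hash_a, hash_b) {
  sprintf("%.0f_%.0f", hash_a, hash_b)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
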