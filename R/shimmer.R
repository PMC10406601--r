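#' Canonical strand-symmetric k-mer hash
#'
#' Hashes each k-mer by the lexicographically smaller of its forward and
#' reverse-complement forms, so a k-mer and its reverse complement always
#' receive the same hash.  The reported strand is 0 when the forward form is
#' canonical (palindromes included) and 1 when the reverse complement is.
#'
#' @param kmers character vector of DNA k-mers over `{A,C,G,T}`.
#' @return data.frame with columns `hash` (numeric, exact 53-bit integers)
#'   and `strand` (0/1).
#' @examples
#' kmerHash(c("ACGT", "AAAC", "GTTT"))
#' @export
kmerHash <- function(kmers) {
  res <- .kmer_hash_cpp(as.character(kmers))
  data.frame(hash = res$hash, strand = res$strand)
}

#' Level-0 symmetric minimizers of a sequence
#'
#' Scans a sequence and, for every window of `w` consecutive valid k-mers,
#' selects the k-mer of minimal canonical hash (leftmost on ties).
#' K-mers overlapping non-ACGT bases are skipped: a run of ambiguous bases
#' splits the sequence into independently scanned blocks.  A sequence (or
#' block) holding fewer than `w` valid k-mers yields no minimizers;
#' sequences shorter than `k` yield an empty result.
#'
#' @param seq a single character string or `DNAString`/length-1
#'   `DNAStringSet`.
#' @param w window size in k-mers.
#' @param k k-mer length in bases.
#' @return data.frame with columns `pos` (0-based start of the k-mer on the
#'   forward strand), `hash`, `strand`, sorted by `pos`.
#' @export
minimizers <- function(seq, w, k) {
  seq <- toupper(as.character(seq)[1L])
  res <- .minimizer_scan_cpp(seq, as.integer(w), as.integer(k))
  data.frame(pos = res$pos, hash = res$hash, strand = res$strand)
}

#' Hierarchical reduction of a minimizer list
#'
#' Applies `levels - 1` window-minimum passes of window `r` over the hash
#' sequence of the previous level, producing sparse hierarchical minimizers
#' (SHIMMERs).  Ties go to the leftmost element and consecutive duplicate
#' selections are collapsed.  With `r = 1` or `levels = 1` the input is
#' returned unchanged; lists shorter than `r` pass through a reduction
#' level untouched.
#'
#' @param mins data.frame of minimizers (`pos`, `hash`, `strand`) sorted by
#'   `pos`, as returned by [minimizers()].
#' @param r reduction window (count of previous-level minimizers).
#' @param levels total number of levels including level 0.
#' @return data.frame of the same shape, a subset of the input rows.
#' @export
hierarchicalReduce <- function(mins, r, levels = 2) {
  r <- as.integer(r); levels <- as.integer(levels)
  if (r <= 1L || levels <= 1L) return(mins)
  for (pass in seq_len(levels - 1L)) {
    if (nrow(mins) < r) next
    idx <- .window_min_idx_cpp(mins$hash, r) + 1L
    mins <- mins[idx, , drop = FALSE]
    rownames(mins) <- NULL
  }
  mins
}

#' Enforce a minimum span between anchors
#'
#' Thins anchors so no two survivors lie closer than `min_span` bases,
#' suppressing anchor pile-ups in simple-sequence and tandem-repeat
#' context.  The default `"symmetric"` heuristic repeatedly removes, among
#' all anchors involved in a spacing violation, the one with the largest
#' hash; because canonical hashes and the gap structure are mirror images
#' under reverse complement, the surviving anchor multiset is
#' strand-invariant.  The `"greedy"` alternative is a left-to-right scan
#' (keep the first anchor, drop any closer than `min_span` to the last
#' kept one); it is cheaper but breaks strand symmetry.
#'
#' @param mins data.frame of minimizers sorted by `pos`.
#' @param min_span minimum allowed distance in bases (0 = no-op).
#' @param method `"symmetric"` (default) or `"greedy"`.
#' @return thinned data.frame.
#' @export
enforceMinSpan <- function(mins, min_span, method = c("symmetric", "greedy")) {
  method <- match.arg(method)
  min_span <- as.integer(min_span)
  if (min_span <= 0L || nrow(mins) <= 1L) return(mins)
  if (method == "symmetric") {
    keep <- .min_span_thin_cpp(as.integer(mins$pos), mins$hash, min_span) + 1L
    out <- mins[keep, , drop = FALSE]
  } else {
    pos <- mins$pos
    keep <- logical(length(pos))
    keep[1L] <- TRUE
    last <- pos[1L]
    for (i in seq_along(pos)[-1L]) {
      if (pos[i] - last >= min_span) { keep[i] <- TRUE; last <- pos[i] }
    }
    out <- mins[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' SHIMMER anchors of a sequence
#'
#' Full pipeline: level-0 symmetric minimizers, hierarchical reduction by
#' factor `r` for `levels - 1` passes, then minimum-span thinning.  With
#' `r = 1` and `min_span = 0` this is exactly the plain minimizer set.
#'
#' @param seq sequence as in [minimizers()].
#' @param params a [ShimmerParams-class] object.
#' @return data.frame (`pos`, `hash`, `strand`).
#' @export
shimmers <- function(seq, params = ShimmerParams()) {
  m <- minimizers(seq, params@w, params@k)
  m <- hierarchicalReduce(m, params@r, params@levels)
  enforceMinSpan(m, params@min_span)
}

#' Neighboring SHIMMER pairs of a sequence
#'
#' Each pair of consecutive SHIMMERs delimits a sequence segment
#' `[pos_p, pos_{p+1} + k)` (0-based half-open).  The pair key is
#' normalized as `(min(hash), max(hash))`; `orientation` is 1 when the
#' normalization swapped the two hashes, else 0.
#'
#' @param seq sequence as in [minimizers()].
#' @param params a [ShimmerParams-class] object.
#' @param shm optional precomputed SHIMMER data.frame for `seq`.
#' @return data.frame with columns `hash_a`, `hash_b` (normalized), `begin`,
#'   `end`, `orientation`; zero rows when the sequence has fewer than two
#'   SHIMMERs.
#' @export
shimmerPairs <- function(seq, params = ShimmerParams(), shm = NULL) {
  if (is.null(shm)) shm <- shimmers(seq, params)
  n <- nrow(shm)
  empty <- data.frame(hash_a = numeric(0), hash_b = numeric(0),
                      begin = integer(0), end = integer(0),
                      orientation = integer(0))
  if (n < 2L) return(empty)
  h1 <- shm$hash[-n]; h2 <- shm$hash[-1L]
  swap <- h1 > h2
  data.frame(
    hash_a = ifelse(swap, h2, h1),
    hash_b = ifelse(swap, h1, h2),
    begin = shm$pos[-n],
    end = shm$pos[-1L] + params@k,
    orientation = as.integer(swap))
}
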