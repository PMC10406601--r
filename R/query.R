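#' Look up raw anchors for a query sequence
#'
#' Computes the query's neighboring SHIMMER pairs and returns one anchor per
#' (query pair occurrence x database occurrence) of every shared key.  The
#' anchor orientation is the XOR of the pair-key orientations on query and
#' target: 0 = same strand, 1 = opposite.
#'
#' Queries should be long enough to contain at least two SHIMMER anchors;
#' regions larger than about 20 kb are recommended at default parameters.
#'
#' @param db a [SeqIndexDB-class].
#' @param query single character string / `DNAString`, or a precomputed
#'   pair data.frame via `query_pairs`.
#' @param query_pairs optional data.frame from [shimmerPairs()].
#' @return data.frame of anchors: `q_begin`, `q_end`, `t_seq_id`,
#'   `t_begin`, `t_end`, `orientation`.
#' @export
lookupAnchors <- function(db, query, query_pairs = NULL) {
  if (is.null(query_pairs))
    query_pairs <- shimmerPairs(query, db@params)
  empty <- data.frame(q_begin = integer(0), q_end = integer(0),
                      t_seq_id = integer(0), t_begin = integer(0),
                      t_end = integer(0), orientation = integer(0))
  if (nrow(query_pairs) < 1L) {
    warnf("query contains fewer than 2 SHIMMER anchors; no lookup possible")
    return(empty)
  }
  keys <- pair_key(query_pairs$hash_a, query_pairs$hash_b)
  out <- vector("list", nrow(query_pairs))
  for (i in seq_len(nrow(query_pairs))) {
    rows <- get0(keys[i], envir = db@pairIndex, inherits = FALSE)
    if (is.null(rows)) next
    occ <- db@pairs[rows, , drop = FALSE]
    out[[i]] <- data.frame(
      q_begin = query_pairs$begin[i], q_end = query_pairs$end[i],
      t_seq_id = occ$seq_id, t_begin = occ$begin, t_end = occ$end,
      orientation = bitwXor(query_pairs$orientation[i], occ$orientation))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Maximum-cardinality monotone chain over one (target, orientation) group,
# as a weighted longest-increasing-subsequence dynamic program (compiled
# inner loop).  Ties in chain size are broken toward the smaller total
# gap.  Returns row indices of the best chain.
chain_group <- function(a, max_gap) {
  ord <- order(a$q_begin, a$t_begin)
  a <- a[ord, , drop = FALSE]
  same <- a$orientation[1L] == 0L
  dp <- .chain_dp_cpp(a$q_begin, a$q_end, a$t_begin, a$t_end, same,
                      as.double(max_gap))
  best <- which(dp$len == max(dp$len))
  best <- best[which.min(dp$gap[best])]
  chain <- integer(0); i <- best
  while (i != 0L) { chain <- c(i, chain); i <- dp$pred[i] }
  ord[chain]
}

#' Chain anchors by sparse dynamic programming
#'
#' Within each (target sequence, orientation) group, finds
#' maximum-cardinality chains of anchors monotone in both query and target
#' coordinates with consecutive gaps at most `max_gap`, by a weighted
#' longest-increasing-subsequence dynamic program (ties broken toward the
#' smaller total gap).  Chains are extracted greedily (best chain first,
#' its anchors removed, repeat); chains with fewer than `min_chain` anchors
#' are discarded.
#'
#' @param anchors data.frame from [lookupAnchors()].
#' @param max_gap maximum allowed gap in bases between consecutive chain
#'   anchors (query or target side).
#' @param min_chain minimum number of anchors per reported chain.
#' @return list of data.frames, each one chain of anchors sorted by
#'   `q_begin`.
#' @export
chainAnchors <- function(anchors, max_gap = 100000, min_chain = 2) {
  if (nrow(anchors) == 0L) return(list())
  chains <- list()
  groups <- split(anchors, list(anchors$t_seq_id, anchors$orientation),
                  drop = TRUE)
  for (g in groups) {
    g <- unique(g)
    while (nrow(g) >= min_chain) {
      sel <- chain_group(g, max_gap)
      if (length(sel) < min_chain) break
      chains[[length(chains) + 1L]] <- g[sort(sel), , drop = FALSE]
      g <- g[-sel, , drop = FALSE]
    }
  }
  chains
}

#' Merge chained hits into homologous ranges
#'
#' Per (target sequence, orientation), chains whose target spans are within
#' `merge_range_tol` bases of each other are unioned; anchor counts are
#' summed and the query span becomes the union of the constituent query
#' spans.  This keeps a hit contiguous across a polymorphic middle that
#' fragments the anchor chains.
#'
#' @param chains list of chains from [chainAnchors()].
#' @param merge_range_tol merge tolerance in bases (>= 0).
#' @param query_name label recorded in the output.
#' @param db optional [SeqIndexDB-class] to resolve target names/sources.
#' @return data.frame of hit ranges: `query_name`, `q_begin`, `q_end`,
#'   `t_source`, `t_name`, `t_seq_id`, `t_begin`, `t_end`, `orientation`,
#'   `n_anchors`.
#' @export
mergeRanges <- function(chains, merge_range_tol = 100000,
                        query_name = "query", db = NULL) {
  if (merge_range_tol < 0) stopf("merge_range_tol must be >= 0")
  empty <- data.frame(query_name = character(0), q_begin = integer(0),
                      q_end = integer(0), t_source = character(0),
                      t_name = character(0), t_seq_id = integer(0),
                      t_begin = integer(0), t_end = integer(0),
                      orientation = integer(0), n_anchors = integer(0))
  if (!length(chains)) return(empty)
  spans <- do.call(rbind, lapply(chains, function(ch) data.frame(
    t_seq_id = ch$t_seq_id[1L], orientation = ch$orientation[1L],
    q_begin = min(ch$q_begin), q_end = max(ch$q_end),
    t_begin = min(ch$t_begin), t_end = max(ch$t_end),
    n_anchors = nrow(ch))))
  out <- list()
  for (g in split(spans, list(spans$t_seq_id, spans$orientation), drop = TRUE)) {
    g <- g[order(g$t_begin, g$t_end), , drop = FALSE]
    cur <- g[1L, , drop = FALSE]
    flush <- function(x) out[[length(out) + 1L]] <<- x
    for (i in seq_len(nrow(g))[-1L]) {
      if (g$t_begin[i] - cur$t_end <= merge_range_tol) {
        cur$t_end <- max(cur$t_end, g$t_end[i])
        cur$t_begin <- min(cur$t_begin, g$t_begin[i])
        cur$q_begin <- min(cur$q_begin, g$q_begin[i])
        cur$q_end <- max(cur$q_end, g$q_end[i])
        cur$n_anchors <- cur$n_anchors + g$n_anchors[i]
      } else { flush(cur); cur <- g[i, , drop = FALSE] }
    }
    flush(cur)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$query_name <- query_name
  if (!is.null(db)) {
    i <- match(res$t_seq_id, db@records$seq_id)
    res$t_name <- db@records$name[i]
    res$t_source <- db@records$source[i]
  } else {
    res$t_name <- as.character(res$t_seq_id)
    res$t_source <- NA_character_
  }
  res[, c("query_name", "q_begin", "q_end", "t_source", "t_name", "t_seq_id",
          "t_begin", "t_end", "orientation", "n_anchors")]
}

#' Query an index for homologous regions
#'
#' Convenience wrapper running [lookupAnchors()], [chainAnchors()] and
#' [mergeRanges()] for one query sequence.
#'
#' @inheritParams lookupAnchors
#' @inheritParams chainAnchors
#' @inheritParams mergeRanges
#' @return data.frame of hit ranges (see [mergeRanges()]).
#' @export
queryIndex <- function(db, query, merge_range_tol = 100000,
                       max_gap = 100000, min_chain = 2,
                       query_name = "query") {
  anchors <- lookupAnchors(db, query)
  chains <- chainAnchors(anchors, max_gap = max_gap, min_chain = min_chain)
  mergeRanges(chains, merge_range_tol = merge_range_tol,
              query_name = query_name, db = db)
}

#' Extract the sequences of hit ranges
#'
#' @param db a [SeqIndexDB-class].
#' @param hits data.frame from [mergeRanges()]/[queryIndex()].
#' @param padding bases added on both sides, clamped to the contig.
#' @return a [Biostrings::DNAStringSet]; records with `orientation == 1`
#'   are reverse-complemented, and names encode
#'   `source::contig:begin-end:orientation`.
#' @export
fetchHitSequences <- function(db, hits, padding = 0) {
  if (!all(hits$t_seq_id %in% db@records$seq_id))
    stopf("hit references unknown seq_id(s): %s",
          paste(setdiff(hits$t_seq_id, db@records$seq_id), collapse = ", "))
  res <- character(nrow(hits)); nms <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ri <- match(hits$t_seq_id[i], db@records$seq_id)
    len <- db@records$length[ri]
    b <- max(0L, hits$t_begin[i] - padding)
    e <- min(len, hits$t_end[i] + padding)
    s <- as.character(Biostrings::subseq(db@sequences[[ri]], b + 1L, e))
    if (hits$orientation[i] == 1L) s <- revcomp_chr(s)
    res[i] <- s
    nms[i] <- sprintf("%s::%s:%d-%d:%d", db@records$source[ri],
                      db@records$name[ri], b, e, hits$orientation[i])
  }
  out <- Biostrings::DNAStringSet(res)
  names(out) <- nms
  out
}

#' Write / read a hit table
#'
#' Tab-separated with a header line, columns in [mergeRanges()] order.
#'
#' @param hits data.frame of hit ranges.
#' @param path output file.
#' @return `path` invisibly (write) or the hit data.frame (read).
#' @export
writeHitTable <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHitTable
#' @export
readHitTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "character", "integer",
                                   "integer", "integer", "integer",
                                   "integer"))
}
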