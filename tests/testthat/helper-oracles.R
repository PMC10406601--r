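# independent oracles and fixture helpers shared across the suite

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# brute-force level-0 minimizer oracle: enumerate every window of w
# consecutive valid k-mers, take the leftmost minimal hash
oracle_minimizers <- function(seq, w, k) {
  n <- nchar(seq)
  if (n < k) return(data.frame(pos = integer(0), hash = numeric(0)))
  starts <- 0:(n - k)
  km <- substring(seq, starts + 1L, starts + k)
  valid <- !grepl("[^ACGT]", km)
  hashes <- rep(NA_real_, length(km))
  if (any(valid)) hashes[valid] <- kmerHash(km[valid])$hash
  picks <- integer(0)
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  for (ri in seq_along(r$values)) {
    if (!r$values[ri]) next
    b <- begins[ri]; e <- ends[ri]
    if (e - b + 1L < w) next
    for (j in b:(e - w + 1L)) {
      win <- j:(j + w - 1L)
      picks <- c(picks, win[which.min(hashes[win])])
    }
  }
  picks <- sort(unique(picks))
  data.frame(pos = picks - 1L, hash = hashes[picks])
}

# brute-force window-minimum oracle over a plain hash vector (the
# hierarchical reduction step); lists shorter than the window pass through
oracle_window_min <- function(hash, w) {
  if (length(hash) < w) return(seq_along(hash))
  sel <- integer(0)
  for (j in 1:(length(hash) - w + 1L)) {
    win <- j:(j + w - 1L)
    sel <- c(sel, win[which.min(hash[win])])
  }
  sort(unique(sel))
}

# exhaustive best monotone chain over <= ~15 anchors: maximum cardinality,
# ties by smaller total gap; returns the best size
oracle_best_chain_size <- function(a, max_gap) {
  n <- nrow(a)
  same <- a$orientation[1L] == 0L
  best_len <- 0L
  for (mask in 1:(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(sel) <= best_len) next
    s <- a[sel, , drop = FALSE]
    s <- s[order(s$q_begin), , drop = FALSE]
    ok <- TRUE
    if (nrow(s) > 1L) {
      for (i in 2:nrow(s)) {
        okq <- s$q_begin[i - 1L] < s$q_begin[i]
        okt <- if (same) s$t_begin[i - 1L] < s$t_begin[i]
               else s$t_begin[i - 1L] > s$t_begin[i]
        gq <- s$q_begin[i] - s$q_end[i - 1L]
        gt <- if (same) s$t_begin[i] - s$t_end[i - 1L]
              else s$t_begin[i - 1L] - s$t_end[i]
        if (!okq || !okt || max(gq, gt) > max_gap) { ok <- FALSE; break }
      }
    }
    if (ok) best_len <- length(sel)
  }
  best_len
}

interval_jaccard <- function(b1, e1, b2, e2) {
  i <- max(0, min(e1, e2) - max(b1, b2))
  i / ((e1 - b1) + (e2 - b2) - i)
}

# edge lookup helper: is the bidirected edge (u,ou)->(v,ov) present?
has_edge <- function(g, u, ou, v, ov) {
  e <- graphEdges(g)
  key <- panmap:::canonical_edge(u, ou, v, ov)
  ek <- mapply(panmap:::canonical_edge, e$v_from, e$o_from, e$v_to, e$o_to)
  key %in% ek
}

# small hand-built MapGraph for traversal tests: vertices with given
# weights, undirected edges (forward orientation both ends)
toy_graph <- function(weights, edges) {
  n <- length(weights)
  vs <- data.frame(vertex_id = seq_len(n) - 1L,
                   hash_a = as.numeric(seq_len(n) * 1000),
                   hash_b = as.numeric(seq_len(n) * 1000 + 1),
                   weight = as.integer(weights))
  # one frag row per unit of weight
  vid <- rep(seq_len(n) - 1L, weights)
  frags <- data.frame(vertex_id = vid, seq_id = rep(0L, length(vid)),
                      begin = rep(0L, length(vid)),
                      end = rep(1L, length(vid)),
                      orientation = rep(0L, length(vid)))
  frags$frag_id <- seq_len(nrow(frags)) - 1L
  ne <- nrow(edges)
  ed <- data.frame(v_from = as.integer(edges[, 1]),
                   o_from = rep(0L, ne),
                   v_to = as.integer(edges[, 2]),
                   o_to = rep(0L, ne), support = rep(1L, ne))
  new("MapGraph", vertices = vs, frags = frags, edges = ed,
      paths = list(), records = data.frame(seq_id = 0L, name = "toy",
                                           source = "memory", length = 1L),
      sequences = Biostrings::DNAStringSet("A"),
      params = ShimmerParams())
}

# canonical decomposition settings for the palindrome fixture: singleton
# vertices are noise when the unit occurs six times, and segments below
# 1 kb are below the repeat scale of interest
palindrome_decomp <- function(g) {
  decomposeGraph(g, min_cov = 2, min_branch_size = 8,
                 bundle_length_cutoff = 1000, bundle_merge_distance = 1000)
}

fixture_params <- function() ShimmerParams(w = 48, k = 56, r = 8,
                                           min_span = 12)
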