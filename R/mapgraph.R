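#' Build a minimizer-anchored pangenome graph
#'
#' Scans every sequence's neighboring-SHIMMER-pair walk.  Each distinct
#' normalized pair key becomes a vertex (holding all fragments that share
#' the key); an edge joins two vertices whenever some sequence traverses
#' them consecutively.  The graph is bidirected: each edge endpoint records
#' whether the traversal passes the canonical vertex forward (0) or flipped
#' (1), and an edge observed in both directions is stored once with summed
#' support.  Vertex ids are assigned in first-encounter order.
#'
#' @param x a [SeqIndexDB-class], or a named `DNAStringSet`/character
#'   vector of sequences.
#' @param params a [ShimmerParams-class]; ignored when `x` is an index.
#' @return A [MapGraph-class] object.
#' @examples
#' set.seed(7)
#' s <- paste(sample(c("A","C","G","T"), 20000, TRUE), collapse = "")
#' g <- buildMapGraph(c(h1 = s, h2 = s),
#'                    ShimmerParams(w = 24, k = 16, r = 2, min_span = 0))
#' g
#' @export
buildMapGraph <- function(x, params = ShimmerParams()) {
  db <- if (is(x, "SeqIndexDB")) x else buildIndexFromSeqs(x, params = params)
  params <- db@params
  n_seq <- nrow(db@records)
  key2id <- new.env(hash = TRUE, parent = emptyenv())
  v_key_a <- numeric(0); v_key_b <- numeric(0)
  n_vertices <- 0L
  paths <- vector("list", n_seq)
  names(paths) <- db@records$name
  frag_rows <- vector("list", n_seq)
  edge_env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n_seq)) {
    pr <- db@pairs[db@pairs$seq_id == db@records$seq_id[i], , drop = FALSE]
    if (nrow(pr) < 1L) {
      warnf("sequence '%s' has fewer than 2 SHIMMERs; skipped",
            db@records$name[i])
      paths[[i]] <- data.frame(vertex_id = integer(0), orientation = integer(0),
                               begin = integer(0), end = integer(0))
      next
    }
    vid <- integer(nrow(pr))
    for (j in seq_len(nrow(pr))) {
      id <- get0(pr$key[j], envir = key2id, inherits = FALSE)
      if (is.null(id)) {
        id <- n_vertices
        n_vertices <- n_vertices + 1L
        assign(pr$key[j], id, envir = key2id)
        v_key_a[n_vertices] <- pr$hash_a[j]
        v_key_b[n_vertices] <- pr$hash_b[j]
      }
      vid[j] <- id
    }
    paths[[i]] <- data.frame(vertex_id = vid, orientation = pr$orientation,
                             begin = pr$begin, end = pr$end)
    frag_rows[[i]] <- data.frame(vertex_id = vid, seq_id = pr$seq_id,
                                 begin = pr$begin, end = pr$end,
                                 orientation = pr$orientation)
    if (nrow(pr) >= 2L) {
      for (j in seq_len(nrow(pr) - 1L)) {
        ek <- canonical_edge(vid[j], pr$orientation[j],
                             vid[j + 1L], pr$orientation[j + 1L])
        cnt <- get0(ek, envir = edge_env, inherits = FALSE)
        assign(ek, if (is.null(cnt)) 1L else cnt + 1L, envir = edge_env)
      }
    }
  }
  frags <- do.call(rbind, frag_rows[!vapply(frag_rows, is.null, logical(1))])
  if (is.null(frags))
    frags <- data.frame(vertex_id = integer(0), seq_id = integer(0),
                        begin = integer(0), end = integer(0),
                        orientation = integer(0))
  rownames(frags) <- NULL
  frags$frag_id <- seq_len(nrow(frags)) - 1L
  frags <- frags[, c("frag_id", "vertex_id", "seq_id", "begin", "end",
                     "orientation")]
  weight <- integer(n_vertices)
  if (nrow(frags)) {
    tab <- table(factor(frags$vertex_id, levels = seq_len(n_vertices) - 1L))
    weight <- as.integer(tab)
  }
  vertices <- data.frame(vertex_id = seq_len(n_vertices) - 1L,
                         hash_a = v_key_a[seq_len(n_vertices)],
                         hash_b = v_key_b[seq_len(n_vertices)],
                         weight = weight)
  ekeys <- ls(edge_env)
  if (length(ekeys)) {
    parts <- do.call(rbind, strsplit(ekeys, "|", fixed = TRUE))
    edges <- data.frame(v_from = as.integer(parts[, 1]),
                        o_from = as.integer(parts[, 2]),
                        v_to = as.integer(parts[, 3]),
                        o_to = as.integer(parts[, 4]),
                        support = vapply(ekeys, function(k)
                          get(k, envir = edge_env), integer(1),
                          USE.NAMES = FALSE))
    edges <- edges[order(edges$v_from, edges$v_to, edges$o_from, edges$o_to), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(v_from = integer(0), o_from = integer(0),
                        v_to = integer(0), o_to = integer(0),
                        support = integer(0))
  }
  new("MapGraph", vertices = vertices, frags = frags, edges = edges,
      paths = paths, records = db@records, sequences = db@sequences,
      params = params)
}

# Canonical form of a bidirected edge: traversing (u,ou) -> (v,ov) is the
# same edge as (v, 1-ov) -> (u, 1-ou); keep the lexicographically smaller
# representation.
canonical_edge <- function(u, ou, v, ov) {
  a <- c(u, ou, v, ov)
  b <- c(v, 1L - ov, u, 1L - ou)
  keep_a <- (a[1] < b[1]) || (a[1] == b[1] && (a[3] < b[3] ||
              (a[3] == b[3] && (a[2] < b[2] ||
                (a[2] == b[2] && a[4] <= b[4])))))
  x <- if (keep_a) a else b
  paste(x, collapse = "|")
}

#' @rdname graphVertices
#' @export
setGeneric("graphVertices", function(g) standardGeneric("graphVertices"))

#' Accessors for MAP-graph components
#'
#' @param g a [MapGraph-class].
#' @return `graphVertices`: data.frame of vertices with weights;
#'   `graphEdges`: data.frame of canonical bidirected edges with support;
#'   `graphPaths`: named list of per-sequence vertex paths;
#'   `vertexWeights`: named numeric vector of vertex weights.
#' @export
setMethod("graphVertices", "MapGraph", function(g) g@vertices)

#' @rdname graphVertices
#' @export
setGeneric("graphEdges", function(g) standardGeneric("graphEdges"))

#' @rdname graphVertices
#' @export
setMethod("graphEdges", "MapGraph", function(g) g@edges)

#' @rdname graphVertices
#' @export
setGeneric("graphPaths", function(g) standardGeneric("graphPaths"))

#' @rdname graphVertices
#' @export
setMethod("graphPaths", "MapGraph", function(g) g@paths)

#' @rdname graphVertices
#' @export
setGeneric("vertexWeights", function(g) standardGeneric("vertexWeights"))

#' @rdname graphVertices
#' @export
setMethod("vertexWeights", "MapGraph", function(g) {
  stats::setNames(g@vertices$weight, g@vertices$vertex_id)
})

#' Relabel vertices canonically
#'
#' Reassigns vertex ids by sorted pair key `(hash_a, hash_b)` so that two
#' graphs built from the same sequences in different input order compare
#' equal.
#'
#' @param g a [MapGraph-class].
#' @return A relabeled [MapGraph-class].
#' @export
canonicalizeVertexIds <- function(g) {
  ord <- order(g@vertices$hash_a, g@vertices$hash_b)
  # new id of old vertex id
  newid <- integer(nrow(g@vertices))
  newid[ord] <- seq_len(nrow(g@vertices)) - 1L
  map <- function(v) newid[v + 1L]
  g@vertices <- g@vertices[ord, , drop = FALSE]
  g@vertices$vertex_id <- seq_len(nrow(g@vertices)) - 1L
  rownames(g@vertices) <- NULL
  g@frags$vertex_id <- map(g@frags$vertex_id)
  if (nrow(g@edges)) {
    ek <- mapply(canonical_edge, map(g@edges$v_from), g@edges$o_from,
                 map(g@edges$v_to), g@edges$o_to)
    parts <- do.call(rbind, strsplit(ek, "|", fixed = TRUE))
    g@edges$v_from <- as.integer(parts[, 1]); g@edges$o_from <- as.integer(parts[, 2])
    g@edges$v_to <- as.integer(parts[, 3]); g@edges$o_to <- as.integer(parts[, 4])
    g@edges <- g@edges[order(g@edges$v_from, g@edges$v_to, g@edges$o_from,
                             g@edges$o_to), , drop = FALSE]
    rownames(g@edges) <- NULL
  }
  g@paths <- lapply(g@paths, function(p) { p$vertex_id <- map(p$vertex_id); p })
  g
}

# representative (first-observed) fragment sequence of each vertex, in
# canonical vertex direction
vertex_rep_seq <- function(g, vertex_ids) {
  vapply(vertex_ids, function(v) {
    fr <- g@frags[g@frags$vertex_id == v, , drop = FALSE][1L, ]
    ri <- match(fr$seq_id, g@records$seq_id)
    s <- as.character(Biostrings::subseq(g@sequences[[ri]], fr$begin + 1L,
                                         fr$end))
    if (fr$orientation == 1L) s <- revcomp_chr(s)
    s
  }, character(1))
}

#' Write a MAP-graph as GFA v1
#'
#' One `S` line per vertex carrying a representative fragment sequence (the
#' first observed occurrence, in canonical vertex direction) with an
#' `LN:i:` tag, and one `L` line per bidirected edge with endpoint
#' orientations and a `0M` overlap.
#'
#' @param g a [MapGraph-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGFA <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("H\tVN:Z:1.0", con)
  if (nrow(g@vertices)) {
    seqs <- vertex_rep_seq(g, g@vertices$vertex_id)
    writeLines(sprintf("S\t%d\t%s\tLN:i:%d", g@vertices$vertex_id, seqs,
                       nchar(seqs)), con)
  }
  if (nrow(g@edges)) {
    o2c <- function(o) ifelse(o == 0L, "+", "-")
    writeLines(sprintf("L\t%d\t%s\t%d\t%s\t0M", g@edges$v_from,
                       o2c(g@edges$o_from), g@edges$v_to, o2c(g@edges$o_to)),
               con)
  }
  invisible(path)
}

#' Parse a GFA v1 file written by [writeGFA()]
#'
#' @param path GFA file.
#' @return list with `segments` (data.frame: `name`, `length`) and `links`
#'   (data.frame: `from`, `from_orient`, `to`, `to_orient`, `overlap`).
#' @export
readGFA <- function(path) {
  ln <- readLines(path)
  sl <- strsplit(ln[startsWith(ln, "S\t")], "\t", fixed = TRUE)
  ll <- strsplit(ln[startsWith(ln, "L\t")], "\t", fixed = TRUE)
  segments <- data.frame(
    name = vapply(sl, `[`, "", 2L),
    length = vapply(sl, function(x) nchar(x[3L]), 1L))
  links <- data.frame(
    from = vapply(ll, `[`, "", 2L), from_orient = vapply(ll, `[`, "", 3L),
    to = vapply(ll, `[`, "", 4L), to_orient = vapply(ll, `[`, "", 5L),
    overlap = vapply(ll, `[`, "", 6L))
  list(segments = segments, links = links)
}

#' Write the fragment sidecar index of a MAP-graph
#'
#' Text file describing the vertices of the companion GFA: a `K` line with
#' the SHIMMER parameters `w k r min_span`, one `C` line per contig
#' (`contig_identifier, contig_name, contig_source, contig_length`) and one
#' `F` line per fragment (`frag_unique_identifier, frag_numeric_identifier
#' (= vertex id), contig_identifier, start, end, orientation`).
#'
#' @param g a [MapGraph-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFragIndex <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  p <- g@params
  writeLines(sprintf("K\t%d\t%d\t%d\t%d", p@w, p@k, p@r, p@min_span), con)
  writeLines(sprintf("C\t%d\t%s\t%s\t%d", g@records$seq_id, g@records$name,
                     g@records$source, g@records$length), con)
  if (nrow(g@frags))
    writeLines(sprintf("F\t%d\t%d\t%d\t%d\t%d\t%d", g@frags$frag_id,
                       g@frags$vertex_id, g@frags$seq_id, g@frags$begin,
                       g@frags$end, g@frags$orientation), con)
  invisible(path)
}

#' Parse a fragment sidecar index written by [writeFragIndex()]
#'
#' @param path sidecar file.
#' @return list with `params` (named integer vector), `contigs`
#'   (data.frame) and `frags` (data.frame).
#' @export
readFragIndex <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln[startsWith(ln, "K\t")][1L], "\t", fixed = TRUE)[[1L]]
  cl <- strsplit(ln[startsWith(ln, "C\t")], "\t", fixed = TRUE)
  fl <- strsplit(ln[startsWith(ln, "F\t")], "\t", fixed = TRUE)
  list(
    params = stats::setNames(as.integer(kv[2:5]),
                             c("w", "k", "r", "min_span")),
    contigs = data.frame(
      seq_id = vapply(cl, function(x) as.integer(x[2L]), 1L),
      name = vapply(cl, `[`, "", 3L),
      source = vapply(cl, `[`, "", 4L),
      length = vapply(cl, function(x) as.integer(x[5L]), 1L)),
    frags = data.frame(
      frag_id = vapply(fl, function(x) as.integer(x[2L]), 1L),
      vertex_id = vapply(fl, function(x) as.integer(x[3L]), 1L),
      seq_id = vapply(fl, function(x) as.integer(x[4L]), 1L),
      begin = vapply(fl, function(x) as.integer(x[5L]), 1L),
      end = vapply(fl, function(x) as.integer(x[6L]), 1L),
      orientation = vapply(fl, function(x) as.integer(x[7L]), 1L)))
}
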