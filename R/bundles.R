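# undirected adjacency over a vertex subset: named list mapping vertex id
# (as character) to sorted integer vector of distinct neighbors; self-loops
# tracked separately for degree accounting
adj_structure <- function(g, alive) {
  alive <- sort(alive)
  nb <- stats::setNames(vector("list", length(alive)), as.character(alive))
  selfloop <- stats::setNames(logical(length(alive)), as.character(alive))
  e <- g@edges
  keep <- e$v_from %in% alive & e$v_to %in% alive
  e <- e[keep, , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    u <- e$v_from[i]; v <- e$v_to[i]
    if (u == v) { selfloop[as.character(u)] <- TRUE; next }
    nb[[as.character(u)]] <- c(nb[[as.character(u)]], v)
    nb[[as.character(v)]] <- c(nb[[as.character(v)]], u)
  }
  nb <- lapply(nb, function(x) sort(unique(x)))
  list(alive = alive, nb = nb, selfloop = selfloop)
}

#' Weight-prioritized DFS forest of a MAP-graph
#'
#' Depth-first traversal over the undirected view of the graph.  Roots are
#' chosen as the globally highest-weight unvisited vertex (repeating until
#' all vertices are visited); at each step the unvisited neighbor of
#' highest weight is taken, ties going to the smaller vertex id.  High
#' weight marks paths most pangenome sequences traverse, so the deep spine
#' of each tree follows the conserved backbone while rare haplotype bubbles
#' hang off it as short branches.
#'
#' @param g a [MapGraph-class].
#' @param min_cov vertices with weight below this are excluded before the
#'   traversal.
#' @param alive optional integer vector of vertex ids to restrict to.
#' @return data.frame with columns `vertex`, `parent` (NA for roots) and
#'   `root`, in visit order; zero rows for an empty graph.
#' @export
weightedDfsForest <- function(g, min_cov = 0, alive = NULL) {
  if (is.null(alive))
    alive <- g@vertices$vertex_id[g@vertices$weight >= min_cov]
  if (!length(alive))
    return(data.frame(vertex = integer(0), parent = integer(0),
                      root = integer(0)))
  adj <- adj_structure(g, alive)
  w <- stats::setNames(g@vertices$weight, as.character(g@vertices$vertex_id))
  visited <- stats::setNames(logical(length(adj$alive)),
                             as.character(adj$alive))
  # visit order: weight desc, then id asc
  global_order <- adj$alive[order(-w[as.character(adj$alive)], adj$alive)]
  res_v <- integer(0); res_p <- integer(0); res_r <- integer(0)
  for (root in global_order) {
    rk <- as.character(root)
    if (visited[rk]) next
    stack <- root
    parent <- stats::setNames(NA_integer_, rk)
    visited[rk] <- TRUE
    res_v <- c(res_v, root); res_p <- c(res_p, NA_integer_)
    res_r <- c(res_r, root)
    while (length(stack)) {
      cur <- stack[length(stack)]
      nbs <- adj$nb[[as.character(cur)]]
      nbs <- nbs[!visited[as.character(nbs)]]
      if (!length(nbs)) { stack <- stack[-length(stack)]; next }
      nxt <- nbs[order(-w[as.character(nbs)], nbs)][1L]
      visited[as.character(nxt)] <- TRUE
      res_v <- c(res_v, nxt); res_p <- c(res_p, cur); res_r <- c(res_r, root)
      stack <- c(stack, nxt)
    }
  }
  data.frame(vertex = res_v, parent = res_p, root = res_r)
}

# one pruning pass: vertex ids of short DFS branches.  A branch is the
# chain from a leaf up to (not including) the nearest branching ancestor.
# Branches whose leaf ends at a true graph dead end are kept regardless of
# size (they are contig ends, not detours); branches whose leaf stopped at
# an already-visited vertex (a bubble or loop closing back on the spine)
# are deleted when shorter than min_branch_size.
short_branch_vertices <- function(forest, min_branch_size, adj) {
  if (!nrow(forest) || min_branch_size <= 0L) return(integer(0))
  kids <- split(forest$vertex, factor(forest$parent,
                                      levels = forest$vertex))
  n_kids <- vapply(kids, length, integer(1))
  names(n_kids) <- as.character(forest$vertex)
  parent_of <- stats::setNames(forest$parent, as.character(forest$vertex))
  leaves <- forest$vertex[n_kids[as.character(forest$vertex)] == 0L]
  drop <- integer(0)
  for (leaf in leaves) {
    branch <- leaf
    v <- leaf
    repeat {
      p <- parent_of[[as.character(v)]]
      if (is.na(p)) break                       # reached a root
      if (n_kids[[as.character(p)]] != 1L) break  # p is a branching point
      branch <- c(branch, p)
      v <- p
    }
    if (length(branch) >= min_branch_size) next
    attach <- parent_of[[as.character(v)]]
    nbrs <- adj$nb[[as.character(leaf)]]
    dead_end <- all(nbrs %in% c(branch, attach))
    if (!dead_end) drop <- c(drop, branch)
  }
  unique(drop)
}

#' Remove short DFS-tree branches from a MAP-graph
#'
#' Leaf-terminated branch subtrees of the weight-prioritized DFS forest
#' holding fewer than `min_branch_size` vertices are deleted from the
#' graph; the traversal and pruning are iterated to a fixpoint.  Short
#' branches typically correspond to rare-haplotype bubbles or loops
#' closing back on the conserved backbone; branches whose leaf is a true
#' graph dead end (a contig terminus) are retained regardless of size.
#'
#' @param g a [MapGraph-class].
#' @param min_branch_size branches with fewer vertices than this are
#'   removed (0 = no-op).
#' @param min_cov minimum vertex weight retained (applied before the first
#'   traversal).
#' @return A pruned [MapGraph-class] (vertex ids are preserved, not
#'   relabeled).
#' @export
pruneShortBranches <- function(g, min_branch_size = 8, min_cov = 0) {
  alive <- g@vertices$vertex_id[g@vertices$weight >= min_cov]
  repeat {
    forest <- weightedDfsForest(g, alive = alive)
    adj <- adj_structure(g, alive)
    drop <- short_branch_vertices(forest, min_branch_size, adj)
    if (!length(drop)) break
    alive <- setdiff(alive, drop)
    if (!length(alive)) break
  }
  subgraphVertices(g, alive)
}

#' Vertex-induced subgraph
#'
#' @param g a [MapGraph-class].
#' @param keep integer vector of vertex ids to retain (ids are preserved).
#' @return A [MapGraph-class] restricted to `keep`.
#' @export
subgraphVertices <- function(g, keep) {
  g@vertices <- g@vertices[g@vertices$vertex_id %in% keep, , drop = FALSE]
  rownames(g@vertices) <- NULL
  g@frags <- g@frags[g@frags$vertex_id %in% keep, , drop = FALSE]
  rownames(g@frags) <- NULL
  g@edges <- g@edges[g@edges$v_from %in% keep & g@edges$v_to %in% keep, ,
                     drop = FALSE]
  rownames(g@edges) <- NULL
  g@paths <- lapply(g@paths, function(p)
    p[p$vertex_id %in% keep, , drop = FALSE])
  g
}

#' Extract principal bundles from a pruned MAP-graph
#'
#' Converts the graph to its undirected view, removes vertices with more
#' than three incident edges, then removes any residual vertex of degree
#' three or more so the remainder is provably a union of simple paths
#' (self-loops count two toward the degree).  Each maximal simple path is
#' one principal bundle; an isolated cycle is opened at its smallest vertex
#' id.  Bundles are ranked by vertex count (descending; ties by smallest
#' vertex id) and `bundle_id` is the 0-based rank.  Each bundle is oriented
#' so that index 0 is the endpoint with the lexicographically smaller pair
#' key.
#'
#' @param g a pruned [MapGraph-class] (see [pruneShortBranches()]).
#' @param strict_simple_paths when `TRUE` (default) the second removal pass
#'   runs, guaranteeing simple paths; `FALSE` applies only the literal
#'   degree-greater-than-three rule.
#' @return A [BundleDecomposition-class] with empty `segments` (see
#'   [projectBundles()]).
#' @export
extractPrincipalBundles <- function(g, strict_simple_paths = TRUE) {
  alive <- g@vertices$vertex_id
  decomp_params <- list(strict_simple_paths = strict_simple_paths)
  repeat_pass <- function(alive, cutoff) {
    if (!length(alive)) return(alive)
    adj <- adj_structure(g, alive)
    deg <- vapply(as.character(adj$alive), function(k)
      length(adj$nb[[k]]) + 2L * adj$selfloop[[k]], integer(1))
    alive[deg <= cutoff]
  }
  alive <- repeat_pass(alive, 3L)   # drop > 3 undirected edges
  if (strict_simple_paths) {
    repeat {
      adj <- adj_structure(g, alive)
      deg <- vapply(as.character(adj$alive), function(k)
        length(adj$nb[[k]]) + 2L * adj$selfloop[[k]], integer(1))
      bad <- adj$alive[deg >= 3L]
      if (!length(bad)) break
      alive <- setdiff(alive, bad)
    }
  }
  paths <- list()
  if (length(alive)) {
    adj <- adj_structure(g, alive)
    nb <- adj$nb
    unvisited <- stats::setNames(rep(TRUE, length(adj$alive)),
                                 as.character(adj$alive))
    deg <- vapply(as.character(adj$alive), function(k) length(nb[[k]]),
                  integer(1))
    walk_from <- function(start) {
      path <- start
      unvisited[as.character(start)] <<- FALSE
      cur <- start
      repeat {
        nxt <- nb[[as.character(cur)]]
        nxt <- nxt[unvisited[as.character(nxt)]]
        if (!length(nxt)) break
        cur <- nxt[1L]
        unvisited[as.character(cur)] <<- FALSE
        path <- c(path, cur)
      }
      path
    }
    # path components first (endpoints have degree <= 1), then cycles
    for (start in adj$alive[order(deg[as.character(adj$alive)],
                                  adj$alive)]) {
      if (!unvisited[as.character(start)]) next
      paths[[length(paths) + 1L]] <- walk_from(start)
    }
  }
  # rank by vertex count desc, tie by smallest vertex id
  if (length(paths)) {
    ord <- order(-vapply(paths, length, 1L),
                 vapply(paths, min, 1))
    paths <- paths[ord]
  }
  key_of <- function(v) {
    i <- match(v, g@vertices$vertex_id)
    c(g@vertices$hash_a[i], g@vertices$hash_b[i])
  }
  bundles <- lapply(paths, function(p) {
    if (length(p) > 1L) {
      ka <- key_of(p[1L]); kb <- key_of(p[length(p)])
      if (kb[1L] < ka[1L] || (kb[1L] == ka[1L] && kb[2L] < ka[2L]))
        p <- rev(p)
    }
    i <- match(p, g@vertices$vertex_id)
    data.frame(vertex_id = p, hash_a = g@vertices$hash_a[i],
               hash_b = g@vertices$hash_b[i])
  })
  vm <- if (length(bundles)) do.call(rbind, lapply(seq_along(bundles),
    function(b) data.frame(vertex_id = bundles[[b]]$vertex_id,
                           bundle_id = b - 1L,
                           idx = seq_len(nrow(bundles[[b]])) - 1L)))
  else data.frame(vertex_id = integer(0), bundle_id = integer(0),
                  idx = integer(0))
  new("BundleDecomposition", bundles = bundles,
      segments = empty_segments(), vertexMap = vm, params = decomp_params)
}

empty_segments <- function() {
  data.frame(contig_name = character(0), begin = integer(0), end = integer(0),
             bundle_id = integer(0), bundle_vertex_count = integer(0),
             orientation = integer(0), begin_vertex = integer(0),
             end_vertex = integer(0), repeat_flag = character(0))
}

#' Project contigs onto principal bundles as BED segments
#'
#' Scans each contig's vertex path: maximal runs of consecutive vertices
#' belonging to one bundle with a consistent traversal direction become
#' segments (orientation 0 when bundle vertex indices increase).  Segments
#' of the same bundle and orientation within `bundle_merge_distance` bases
#' are merged, segments shorter than `bundle_length_cutoff` are dropped,
#' and the repeat flag is `R` when the same bundle occurs two or more
#' times on a contig (else `U`).  Path vertices in no bundle leave gaps.
#'
#' @param g the [MapGraph-class] the contigs traverse.
#' @param decomp a [BundleDecomposition-class] from
#'   [extractPrincipalBundles()].
#' @param bundle_length_cutoff minimum segment length in bases.
#' @param bundle_merge_distance merge distance in bases.
#' @param contigs optional character vector restricting the projection.
#' @return The decomposition with its `segments` slot filled.
#' @export
projectBundles <- function(g, decomp, bundle_length_cutoff = 100,
                           bundle_merge_distance = 1000, contigs = NULL) {
  vm <- decomp@vertexMap
  nver <- vapply(decomp@bundles, nrow, integer(1))
  if (is.null(contigs)) contigs <- names(g@paths)
  missing <- setdiff(contigs, names(g@paths))
  if (length(missing))
    stopf("contig(s) absent from the graph: %s", paste(missing, collapse = ", "))
  segs <- list()
  add_seg <- function(x) segs[[length(segs) + 1L]] <<- x
  for (cn in contigs) {
    p <- g@paths[[cn]]
    if (!nrow(p)) next
    mi <- match(p$vertex_id, vm$vertex_id)
    bid <- vm$bundle_id[mi]; bidx <- vm$idx[mi]
    run_start <- NA_integer_; run_dir <- 0L
    flush <- function(s, e) {
      if (is.na(run_start)) return()
      add_seg(data.frame(
        contig_name = cn, begin = p$begin[s], end = p$end[e],
        bundle_id = bid[s], bundle_vertex_count = nver[bid[s] + 1L],
        orientation = if (run_dir < 0L) 1L else 0L,
        begin_vertex = bidx[s], end_vertex = bidx[e]))
    }
    i_prev <- NA_integer_
    for (i in seq_len(nrow(p))) {
      if (is.na(bid[i])) {
        flush(run_start, i_prev); run_start <- NA_integer_; run_dir <- 0L
        i_prev <- NA_integer_
        next
      }
      if (is.na(run_start)) {
        run_start <- i; run_dir <- 0L; i_prev <- i
        next
      }
      step <- if (bid[i] == bid[i_prev]) sign(bidx[i] - bidx[i_prev]) else NA
      ok <- !is.na(step) && step != 0L &&
        (run_dir == 0L || step == run_dir)
      if (ok) {
        run_dir <- step; i_prev <- i
      } else {
        flush(run_start, i_prev)
        run_start <- i; run_dir <- 0L; i_prev <- i
      }
    }
    flush(run_start, i_prev)
  }
  if (!length(segs)) { decomp@segments <- empty_segments(); return(decomp) }
  segments <- do.call(rbind, segs)
  # Merge same-bundle same-orientation neighbors within the merge
  # distance, but only when the bundle vertex indices continue in the run
  # direction: fragments of one interrupted traversal resume at a later
  # (orientation 0) or earlier (orientation 1) index, whereas a second
  # tandem copy wraps around and must stay a separate segment.
  merged <- list()
  for (grp in split(segments,
                    list(segments$contig_name, segments$bundle_id,
                         segments$orientation), drop = TRUE)) {
    grp <- grp[order(grp$begin), , drop = FALSE]
    cur <- grp[1L, , drop = FALSE]
    for (i in seq_len(nrow(grp))[-1L]) {
      continues <- if (cur$orientation == 0L)
        grp$begin_vertex[i] >= cur$end_vertex
      else grp$begin_vertex[i] <= cur$end_vertex
      if (continues && grp$begin[i] - cur$end <= bundle_merge_distance) {
        cur$end <- max(cur$end, grp$end[i])
        if (cur$orientation == 0L) {
          cur$end_vertex <- max(cur$end_vertex, grp$end_vertex[i])
          cur$begin_vertex <- min(cur$begin_vertex, grp$begin_vertex[i])
        } else {
          cur$end_vertex <- min(cur$end_vertex, grp$end_vertex[i])
          cur$begin_vertex <- max(cur$begin_vertex, grp$begin_vertex[i])
        }
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- grp[i, , drop = FALSE]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  segments <- do.call(rbind, merged)
  segments <- segments[segments$end - segments$begin >= bundle_length_cutoff, ,
                       drop = FALSE]
  segments <- segments[order(segments$contig_name, segments$begin), ,
                       drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments)) {
    cnt <- stats::ave(segments$bundle_id,
                      segments$contig_name, segments$bundle_id,
                      FUN = length)
    segments$repeat_flag <- ifelse(cnt >= 2L, "R", "U")
  } else segments$repeat_flag <- character(0)
  decomp@segments <- segments
  decomp
}

#' Principal-bundle decomposition of a MAP-graph
#'
#' Full pipeline: weight-prioritized DFS, short-branch pruning to a
#' fixpoint, branching-vertex removal, simple-path extraction and
#' projection of every contig onto the bundles.
#'
#' @param g a [MapGraph-class].
#' @param min_cov minimum vertex weight retained.
#' @param min_branch_size DFS branches smaller than this are pruned.
#' @param bundle_length_cutoff minimum projected segment length (bases).
#' @param bundle_merge_distance merge distance for same-bundle segments
#'   (bases).
#' @param strict_simple_paths see [extractPrincipalBundles()].
#' @param contigs optional contig restriction for the projection.
#' @return A [BundleDecomposition-class] with `segments` filled.
#' @export
decomposeGraph <- function(g, min_cov = 0, min_branch_size = 8,
                           bundle_length_cutoff = 100,
                           bundle_merge_distance = 1000,
                           strict_simple_paths = TRUE, contigs = NULL) {
  pruned <- pruneShortBranches(g, min_branch_size = min_branch_size,
                               min_cov = min_cov)
  decomp <- extractPrincipalBundles(pruned,
                                    strict_simple_paths = strict_simple_paths)
  decomp@params <- c(decomp@params,
                     list(min_cov = min_cov,
                          min_branch_size = min_branch_size,
                          bundle_length_cutoff = bundle_length_cutoff,
                          bundle_merge_distance = bundle_merge_distance))
  projectBundles(g, decomp, bundle_length_cutoff = bundle_length_cutoff,
                 bundle_merge_distance = bundle_merge_distance,
                 contigs = contigs)
}

#' @rdname bundleSegments
#' @export
setGeneric("bundleSegments", function(x) standardGeneric("bundleSegments"))

#' Segments and bundles of a decomposition
#'
#' @param x a [BundleDecomposition-class].
#' @return `bundleSegments`: the BED-style segment data.frame;
#'   `principalBundles`: the ordered list of bundle vertex tables.
#' @export
setMethod("bundleSegments", "BundleDecomposition", function(x) x@segments)

#' @rdname bundleSegments
#' @export
setGeneric("principalBundles", function(x) standardGeneric("principalBundles"))

#' @rdname bundleSegments
#' @export
setMethod("principalBundles", "BundleDecomposition", function(x) x@bundles)

#' Write a principal-bundle decomposition as BED
#'
#' Four-column BED whose fourth column is the six-field
#' `bundle_id:vertex_count:orientation:begin_vertex:end_vertex:flag`
#' specification.
#'
#' @param segments segment data.frame (see [projectBundles()]) or a
#'   [BundleDecomposition-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBundleBed <- function(segments, path) {
  if (is(segments, "BundleDecomposition")) segments <- segments@segments
  lines <- sprintf("%s\t%d\t%d\t%d:%d:%d:%d:%d:%s",
                   segments$contig_name, segments$begin, segments$end,
                   segments$bundle_id, segments$bundle_vertex_count,
                   segments$orientation, segments$begin_vertex,
                   segments$end_vertex, segments$repeat_flag)
  writeLines(lines, path)
  invisible(path)
}

#' Read a principal-bundle BED written by [writeBundleBed()]
#'
#' @param path BED file.
#' @return segment data.frame in [projectBundles()] layout.
#' @export
readBundleBed <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (!length(ln)) return(empty_segments())
  parts <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 4L)
  if (length(bad)) stopf("malformed BED line %d in %s", bad[1L], path)
  spec <- strsplit(vapply(parts, `[`, "", 4L), ":", fixed = TRUE)
  bad <- which(vapply(spec, length, 1L) != 6L)
  if (length(bad)) stopf("malformed bundle specification on line %d in %s",
                         bad[1L], path)
  data.frame(
    contig_name = vapply(parts, `[`, "", 1L),
    begin = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    bundle_id = as.integer(vapply(spec, `[`, "", 1L)),
    bundle_vertex_count = as.integer(vapply(spec, `[`, "", 2L)),
    orientation = as.integer(vapply(spec, `[`, "", 3L)),
    begin_vertex = as.integer(vapply(spec, `[`, "", 4L)),
    end_vertex = as.integer(vapply(spec, `[`, "", 5L)),
    repeat_flag = vapply(spec, `[`, "", 6L))
}

#' Per-contig bundle summary table
#'
#' @param segments segment data.frame or [BundleDecomposition-class].
#' @param path optional output TSV path.
#' @return data.frame with per-contig `n_segments`, `covered_bases` and
#'   `n_bundles` (distinct bundle ids).
#' @export
contigSummary <- function(segments, path = NULL) {
  if (is(segments, "BundleDecomposition")) segments <- segments@segments
  out <- do.call(rbind, lapply(split(segments, segments$contig_name),
    function(s) data.frame(
      contig_name = s$contig_name[1L],
      n_segments = nrow(s),
      covered_bases = sum(s$end - s$begin),
      n_bundles = length(unique(s$bundle_id)))))
  rownames(out) <- NULL
  if (is.null(out))
    out <- data.frame(contig_name = character(0), n_segments = integer(0),
                      covered_bases = integer(0), n_bundles = integer(0))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write the principal-bundle graph as GFA v1
#'
#' One `S` line per bundle (sequence omitted, `LN:i:` = total representative
#' fragment length) and one `L` line for every pair of bundles traversed
#' consecutively by some contig.
#'
#' @param g the [MapGraph-class].
#' @param decomp a projected [BundleDecomposition-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBundleGFA <- function(g, decomp, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("H\tVN:Z:1.0", con)
  segs <- decomp@segments
  for (b in seq_along(decomp@bundles)) {
    len <- sum(segs$end[segs$bundle_id == b - 1L] -
               segs$begin[segs$bundle_id == b - 1L])
    writeLines(sprintf("S\t%d\t*\tLN:i:%d", b - 1L, as.integer(len)), con)
  }
  links <- character(0)
  o2c <- function(o) ifelse(o == 0L, "+", "-")
  for (cn in unique(segs$contig_name)) {
    s <- segs[segs$contig_name == cn, , drop = FALSE]
    s <- s[order(s$begin), , drop = FALSE]
    if (nrow(s) < 2L) next
    links <- c(links, sprintf("L\t%d\t%s\t%d\t%s\t0M",
                              s$bundle_id[-nrow(s)], o2c(s$orientation[-nrow(s)]),
                              s$bundle_id[-1L], o2c(s$orientation[-1L])))
  }
  writeLines(unique(links), con)
  invisible(path)
}

#' One-call pangenome decomposition to files
#'
#' Builds the MAP-graph from a FASTA (or in-memory sequences), runs the
#' principal-bundle decomposition and writes the five-file manifest:
#' `<prefix>.bed`, `<prefix>.ctg.summary.tsv`, `<prefix>.mapg.gfa`,
#' `<prefix>.mapg.idx` and `<prefix>.pmapg.gfa`.
#'
#' @param seqs FASTA path(s) or a named `DNAStringSet`/character vector.
#' @param prefix output path prefix.
#' @param params a [ShimmerParams-class].
#' @param include optional file with one contig name per line; only those
#'   contigs are projected.
#' @inheritParams decomposeGraph
#' @return invisibly, a list with the `graph`, the `decomposition` and the
#'   output `files`.
#' @export
decomposePangenome <- function(seqs, prefix,
                               params = ShimmerParams(w = 48, k = 56, r = 8,
                                                      min_span = 12),
                               min_cov = 0, min_branch_size = 8,
                               bundle_length_cutoff = 100,
                               bundle_merge_distance = 1000,
                               include = NULL) {
  db <- if (is.character(seqs) && all(file.exists(seqs)))
    buildIndex(seqs, params) else buildIndexFromSeqs(seqs, params = params)
  g <- buildMapGraph(db)
  contigs <- NULL
  if (!is.null(include)) {
    contigs <- readLines(include)
    contigs <- contigs[nzchar(contigs)]
  }
  decomp <- decomposeGraph(g, min_cov = min_cov,
                           min_branch_size = min_branch_size,
                           bundle_length_cutoff = bundle_length_cutoff,
                           bundle_merge_distance = bundle_merge_distance,
                           contigs = contigs)
  files <- c(bed = paste0(prefix, ".bed"),
             summary = paste0(prefix, ".ctg.summary.tsv"),
             mapg = paste0(prefix, ".mapg.gfa"),
             idx = paste0(prefix, ".mapg.idx"),
             pmapg = paste0(prefix, ".pmapg.gfa"))
  writeBundleBed(decomp, files[["bed"]])
  contigSummary(decomp, files[["summary"]])
  writeGFA(g, files[["mapg"]])
  writeFragIndex(g, files[["idx"]])
  writeBundleGFA(g, decomp, files[["pmapg"]])
  invisible(list(graph = g, decomposition = decomp, files = files))
}
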