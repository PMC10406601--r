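#' Equilibrium distribution of a lazy random walk on a MAP-graph
#'
#' Builds the vertex adjacency matrix `A` (entry = number of sequence
#' traversals supporting the edge, symmetrized as `A + t(A)` over the
#' undirected view), the weighted degree matrix `D` and iterates the lazy
#' walk `v <- (v + A D^-1 v) / 2` from the all-ones vector until either the
#' change falls below `tol` or `N` (vertex count) iterations have run.  The
#' result is normalized to the distribution `P` (sums to 1).  On connected
#' graphs the lazy walk converges to the stationary distribution
#' `p_i = d_i / sum(d)`; the laziness guarantees convergence on bipartite
#' graphs where the pure power iteration oscillates.
#'
#' @param g a [MapGraph-class], or a base `matrix`/`Matrix` adjacency
#'   (support counts; it is symmetrized internally).
#' @param tol convergence tolerance on the max absolute change of the
#'   unnormalized iterate.
#' @param lazy set `FALSE` to iterate the pure (non-lazy) walk
#'   `v <- A D^-1 v` instead.
#' @param max_iter iteration budget; the default `NULL` uses the vertex
#'   count `N` (a cheap approximation adequate for well-connected graphs).
#'   Raise it when the exact stationary limit is wanted on slowly mixing
#'   (chain-like) graphs.
#' @return list with `P` (normalized distribution), `N` (vertex count),
#'   `entropy` (bits), `rep_score` (mean of the top `min(32, N)` entries
#'   of `N * P`), `iterations` used, `isolated` (0-based ids or indices of
#'   zero-degree vertices, whose mass decays from the initial condition
#'   only) and the symmetrized `A`.
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 3] <- 1   # 3-vertex path
#' diffusionWeights(A)$P                            # (0.25, 0.5, 0.25)
#' @export
diffusionWeights <- function(g, tol = 1e-10, lazy = TRUE, max_iter = NULL) {
  if (is(g, "MapGraph")) {
    n <- nrow(g@vertices)
    if (n < 1L) stopf("graph has no vertices")
    e <- g@edges
    A <- Matrix::sparseMatrix(i = e$v_from + 1L, j = e$v_to + 1L,
                              x = as.numeric(e$support), dims = c(n, n))
    ids <- g@vertices$vertex_id
  } else {
    A <- Matrix::Matrix(as.matrix(g), sparse = TRUE)
    n <- nrow(A)
    if (n < 1L) stopf("adjacency has no vertices")
    ids <- seq_len(n) - 1L
  }
  A <- A + Matrix::t(A)
  d <- Matrix::rowSums(A)
  isolated <- ids[d == 0]
  dinv <- ifelse(d > 0, 1 / d, 0)
  if (is.null(max_iter)) max_iter <- n
  v <- rep(1, n)
  iters <- 0L
  for (i in seq_len(max_iter)) {
    step <- as.numeric(A %*% (dinv * v))
    vn <- if (lazy) (v + step) / 2 else step
    iters <- i
    if (max(abs(vn - v)) < tol) { v <- vn; break }
    v <- vn
  }
  P <- v / sum(v)
  list(P = P, N = n, entropy = diffusionEntropy(P),
       rep_score = maxRepeatWeight(P, n), iterations = iters,
       isolated = isolated, A = A)
}

#' Diffusion entropy of an equilibrium distribution
#'
#' `S = -sum(p_i * log2(p_i))` with `0 * log(0) := 0`.  Higher values
#' indicate a more polymorphic (bubblier) graph; a uniform distribution
#' over `N` vertices gives `log2(N)` bits.
#'
#' @param P numeric distribution summing to 1 (checked to 1e-9).
#' @return entropy in bits.
#' @export
diffusionEntropy <- function(P) {
  if (abs(sum(P) - 1) > 1e-9) stopf("P is not normalized (sum = %g)", sum(P))
  nz <- P[P > 0]
  -sum(nz * log2(nz))
}

#' Repetitiveness score from diffusion weights
#'
#' Mean of the largest `min(32, N)` entries of the unnormalized vector
#' `N * P`; a proxy for the copy number of the most repeated graph regions.
#'
#' @param P normalized distribution.
#' @param N vertex count.
#' @param top number of top entries averaged (default 32).
#' @return the score.
#' @export
maxRepeatWeight <- function(P, N = length(P), top = 32) {
  np <- sort(N * P, decreasing = TRUE)
  mean(np[seq_len(min(top, length(np)))])
}

#' Binary haplotype-by-vertex matrix over principal bundles
#'
#' Rows are haplotypes, columns the principal-bundle vertices in
#' `(bundle_id, index)` order; entry 1 when the haplotype's path contains
#' the vertex.  Suitable for a standard principal component transformation.
#'
#' @param g a [MapGraph-class].
#' @param decomp a [BundleDecomposition-class].
#' @param contigs optional haplotype subset (must be in the graph).
#' @return binary integer matrix with contig row names and
#'   `b<bundle>.<idx>` column names.
#' @export
haplotypeVertexMatrix <- function(g, decomp, contigs = NULL) {
  if (is.null(contigs)) contigs <- names(g@paths)
  missing <- setdiff(contigs, names(g@paths))
  if (length(missing))
    stopf("haplotype(s) not in graph: %s", paste(missing, collapse = ", "))
  vm <- decomp@vertexMap
  vm <- vm[order(vm$bundle_id, vm$idx), , drop = FALSE]
  M <- matrix(0L, nrow = length(contigs), ncol = nrow(vm),
              dimnames = list(contigs,
                              sprintf("b%d.%d", vm$bundle_id, vm$idx)))
  for (i in seq_along(contigs)) {
    vs <- unique(g@paths[[contigs[i]]]$vertex_id)
    M[i, vm$vertex_id %in% vs] <- 1L
  }
  M
}

#' Principal components of haplotype bundle-vertex vectors
#'
#' Centers the binary matrix columns and projects onto the top singular
#' axes.
#'
#' @param M matrix from [haplotypeVertexMatrix()].
#' @param n_components number of components returned.
#' @return list with `scores` (haplotype x component), `sdev` and the
#'   `prcomp` object.
#' @export
haplotypePCA <- function(M, n_components = 2) {
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       sdev = pc$sdev, prcomp = pc)
}

# per-contig token table: one row per segment in coordinate order with a
# length weight
bundle_tokens <- function(segments) {
  lapply(split(segments, segments$contig_name), function(s) {
    s <- s[order(s$begin), , drop = FALSE]
    data.frame(bundle_id = s$bundle_id, orientation = s$orientation,
               weight = as.numeric(s$end - s$begin))
  })
}

# length-weighted longest common subsequence of two token tables; a match
# requires equal (bundle_id, orientation) and contributes min(w_a, w_b)
weighted_lcs <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (!na || !nb) return(0)
  D <- matrix(0, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      m <- if (a$bundle_id[i] == b$bundle_id[j] &&
               a$orientation[i] == b$orientation[j])
        D[i, j] + min(a$weight[i], b$weight[j]) else 0
      D[i + 1L, j + 1L] <- max(D[i, j + 1L], D[i + 1L, j], m)
    }
  }
  D[na + 1L, nb + 1L]
}

#' Bundle-decomposition distance matrix, dendrogram and Newick tree
#'
#' Each contig becomes an ordered token string of
#' `(bundle_id, orientation)` segments weighted by length; pairwise
#' similarity is the length-weighted longest common subsequence (a sparse
#' alignment of the bundle strings) and the distance is
#' `1 - 2 * W_lcs / (W_a + W_b)`, in `[0, 1]`.  Contigs with no segments
#' sit at distance 1 from everything (with a warning).  Average-linkage
#' agglomerative clustering gives the dendrogram; merge heights become
#' Newick branch lengths.
#'
#' @param segments segment data.frame or [BundleDecomposition-class] with
#'   at least 2 contigs.
#' @param method token similarity: `"lcs"` (default) or `"edit"`
#'   (length-weighted edit distance turned into a similarity).
#' @return list with `dist` (symmetric matrix), `hclust`, `phylo` (an
#'   [ape::phylo] tree) and `newick` (the tree serialized).
#' @export
bundleDistance <- function(segments, method = c("lcs", "edit")) {
  method <- match.arg(method)
  if (is(segments, "BundleDecomposition")) segments <- segments@segments
  toks <- bundle_tokens(segments)
  nms <- names(toks)
  if (length(nms) < 2L) stopf("need at least 2 contigs with segments")
  tw <- vapply(toks, function(t) sum(t$weight), numeric(1))
  if (any(tw == 0))
    warnf("contig(s) with zero bundle segments: %s",
          paste(nms[tw == 0], collapse = ", "))
  n <- length(nms)
  D <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (tw[i] + tw[j] == 0) { D[i, j] <- D[j, i] <- 1; next }
      W <- if (method == "lcs") weighted_lcs(toks[[i]], toks[[j]])
      else weighted_edit_sim(toks[[i]], toks[[j]])
      d <- 1 - 2 * W / (tw[i] + tw[j])
      D[i, j] <- D[j, i] <- min(1, max(0, d))
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  phy <- ape::as.phylo(hc)
  list(dist = D, hclust = hc, phylo = phy,
       newick = ape::write.tree(phy))
}

# weighted-edit similarity: total weight minus edit cost, floored at 0
weighted_edit_sim <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  D <- matrix(0, na + 1L, nb + 1L)
  D[, 1L] <- c(0, cumsum(a$weight))
  D[1L, ] <- c(0, cumsum(b$weight))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      sub <- if (a$bundle_id[i] == b$bundle_id[j] &&
                 a$orientation[i] == b$orientation[j])
        abs(a$weight[i] - b$weight[j]) else a$weight[i] + b$weight[j]
      D[i + 1L, j + 1L] <- min(D[i, j] + sub,
                               D[i, j + 1L] + a$weight[i],
                               D[i + 1L, j] + b$weight[j])
    }
  }
  max(0, (sum(a$weight) + sum(b$weight) - D[na + 1L, nb + 1L]) / 2)
}

#' Write clustering outputs of a bundle decomposition
#'
#' Produces `<prefix>.dist` (TSV: `name_a`, `name_b`, `distance`),
#' `<prefix>.nwk` (Newick) and `<prefix>.ddg` (dendrogram layout for the
#' SVG renderer: `L` lines `L index leaf_y name` in plotted order and `M`
#' lines `M node_id child_a child_b height y` for each merge, children
#' referencing leaves as `L<i>` and merges as `M<i>`).
#'
#' @param bd result of [bundleDistance()].
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
writeDistanceFiles <- function(bd, prefix) {
  files <- c(dist = paste0(prefix, ".dist"),
             nwk = paste0(prefix, ".nwk"),
             ddg = paste0(prefix, ".ddg"))
  D <- bd$dist
  nms <- rownames(D)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  utils::write.table(
    data.frame(name_a = nms[idx[, 1L]], name_b = nms[idx[, 2L]],
               distance = D[idx]),
    files[["dist"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bd$newick, files[["nwk"]])
  hc <- bd$hclust
  ord <- hc$order
  leaf_y <- integer(length(ord)); leaf_y[ord] <- seq_along(ord)
  lines <- sprintf("L\t%d\t%d\t%s", seq_along(hc$labels) - 1L,
                   leaf_y - 1L, hc$labels)
  node_y <- numeric(nrow(hc$merge))
  ref <- function(x) if (x < 0) sprintf("L%d", -x - 1L) else
    sprintf("M%d", x - 1L)
  ypos <- function(x) if (x < 0) leaf_y[-x] - 1L else node_y[x]
  mlines <- character(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1L]; b <- hc$merge[i, 2L]
    node_y[i] <- (ypos(a) + ypos(b)) / 2
    mlines[i] <- sprintf("M\t%d\t%s\t%s\t%.8g\t%.8g", i - 1L, ref(a),
                         ref(b), hc$height[i], node_y[i])
  }
  writeLines(c(lines, mlines), files[["ddg"]])
  invisible(files)
}

#' Read a dendrogram layout written by [writeDistanceFiles()]
#'
#' @param path `.ddg` file.
#' @return list with `leaves` (data.frame `index`, `y`, `name`) and
#'   `merges` (data.frame `id`, `child_a`, `child_b`, `height`, `y`).
#' @export
readDendrogramLayout <- function(path) {
  ln <- readLines(path)
  ll <- strsplit(ln[startsWith(ln, "L\t")], "\t", fixed = TRUE)
  ml <- strsplit(ln[startsWith(ln, "M\t")], "\t", fixed = TRUE)
  list(
    leaves = data.frame(
      index = vapply(ll, function(x) as.integer(x[2L]), 1L),
      y = vapply(ll, function(x) as.integer(x[3L]), 1L),
      name = vapply(ll, `[`, "", 4L)),
    merges = if (length(ml)) data.frame(
      id = vapply(ml, function(x) as.integer(x[2L]), 1L),
      child_a = vapply(ml, `[`, "", 3L),
      child_b = vapply(ml, `[`, "", 4L),
      height = vapply(ml, function(x) as.numeric(x[5L]), 1),
      y = vapply(ml, function(x) as.numeric(x[6L]), 1))
    else data.frame(id = integer(0), child_a = character(0),
                    child_b = character(0), height = numeric(0),
                    y = numeric(0)))
}
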