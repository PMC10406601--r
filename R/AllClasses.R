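#' @useDynLib panmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' SHIMMER index parameters
#'
#' Container for the parameters controlling sparse hierarchical minimizer
#' (SHIMMER) selection: window size `w` (in k-mers), k-mer length `k`
#' (bases), hierarchical reduction factor `r`, the minimum base distance
#' `min_span` between retained anchors, and the total number of hierarchy
#' `levels` (level 0 = plain symmetric minimizers; each further level is one
#' window-minimum reduction pass of factor `r` over the previous level's
#' hash sequence).
#'
#' With `r = 1` and `min_span = 0` the SHIMMER set is exactly the level-0
#' symmetric minimizer set.
#'
#' @slot w integer window size in k-mers.
#' @slot k integer k-mer length in bases.
#' @slot r integer reduction factor per hierarchy level.
#' @slot min_span integer minimum distance in bases between kept anchors.
#' @slot levels integer total number of levels (>= 1); the default 2 means a
#'   single reduction pass.
#' @export
setClass("ShimmerParams",
  representation(w = "integer", k = "integer", r = "integer",
                 min_span = "integer", levels = "integer"),
  prototype(w = 80L, k = 56L, r = 4L, min_span = 64L, levels = 2L))

setValidity("ShimmerParams", function(object) {
  msg <- character()
  if (length(object@w) != 1L || is.na(object@w) || object@w < 1L)
    msg <- c(msg, "w must be a single integer >= 1")
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (length(object@r) != 1L || is.na(object@r) || object@r < 1L)
    msg <- c(msg, "r must be a single integer >= 1")
  if (length(object@min_span) != 1L || is.na(object@min_span) || object@min_span < 0L)
    msg <- c(msg, "min_span must be a single integer >= 0")
  if (length(object@levels) != 1L || is.na(object@levels) || object@levels < 1L)
    msg <- c(msg, "levels must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Create SHIMMER parameters
#'
#' @param w window size in k-mers.
#' @param k k-mer size in bases.
#' @param r hierarchical reduction factor.
#' @param min_span minimum base distance between retained anchors.
#' @param levels total number of hierarchy levels (2 = one reduction pass).
#' @return A [ShimmerParams-class] object.
#' @examples
#' ShimmerParams(w = 48, k = 56, r = 12, min_span = 12)
#' @export
ShimmerParams <- function(w = 80, k = 56, r = 4, min_span = 64, levels = 2) {
  new("ShimmerParams", w = as.integer(w), k = as.integer(k), r = as.integer(r),
      min_span = as.integer(min_span), levels = as.integer(levels))
}

setMethod("show", "ShimmerParams", function(object) {
  cat(sprintf("ShimmerParams(w=%d, k=%d, r=%d, min_span=%d, levels=%d)\n",
              object@w, object@k, object@r, object@min_span, object@levels))
})

#' Sequence index database
#'
#' Sequence store plus a hashmap from normalized neighboring-SHIMMER-pair
#' keys to their occurrences `(seq_id, begin, end, orientation)` across all
#' indexed sequences.  Built with [buildIndex()] and queried with
#' [queryIndex()].
#'
#' @slot params the [ShimmerParams-class] used at build time.
#' @slot records data.frame with columns `seq_id` (0-based integer), `name`,
#'   `source`, `length`.
#' @slot sequences a [Biostrings::DNAStringSet] holding the indexed
#'   sequences in `seq_id` order.
#' @slot shimmers list (one element per sequence) of data.frames with
#'   columns `pos`, `hash`, `strand`.
#' @slot pairs data.frame of all pair occurrences: `key`, `hash_a`,
#'   `hash_b`, `seq_id`, `begin`, `end`, `orientation`.
#' @slot pairIndex environment mapping a pair `key` string to the integer
#'   row indices of its occurrences in `pairs`.
#' @export
setClass("SeqIndexDB",
  representation(params = "ShimmerParams", records = "data.frame",
                 sequences = "DNAStringSet", shimmers = "list",
                 pairs = "data.frame", pairIndex = "environment"))

setMethod("show", "SeqIndexDB", function(object) {
  cat(sprintf("SeqIndexDB: %d sequence(s), %.0f bases, %d SHIMMER pair occurrence(s), %d distinct key(s)\n",
              nrow(object@records), sum(object@records$length),
              nrow(object@pairs), length(ls(object@pairIndex))))
  show(object@params)
})

#' Minimizer-anchored pangenome graph (MAP-graph)
#'
#' Weighted bidirected graph whose vertices are normalized neighboring
#' SHIMMER pairs (each holding every sequence fragment sharing that pair)
#' and whose edges join pairs adjacent on at least one input sequence.
#' Every input sequence corresponds to a path in the graph.
#'
#' @slot vertices data.frame: `vertex_id` (0-based), `hash_a`, `hash_b`
#'   (normalized so `hash_a <= hash_b`), `weight` (number of fragment
#'   occurrences).
#' @slot frags data.frame of fragment occurrences: `frag_id`, `vertex_id`,
#'   `seq_id`, `begin`, `end`, `orientation`.
#' @slot edges data.frame of canonical bidirected edges: `v_from`, `o_from`,
#'   `v_to`, `o_to`, `support` (number of traversals).
#' @slot paths list (one element per sequence) of data.frames
#'   `vertex_id`, `orientation`, `begin`, `end`.
#' @slot records sequence metadata as in [SeqIndexDB-class].
#' @slot sequences the underlying [Biostrings::DNAStringSet].
#' @slot params the [ShimmerParams-class] used.
#' @export
setClass("MapGraph",
  representation(vertices = "data.frame", frags = "data.frame",
                 edges = "data.frame", paths = "list",
                 records = "data.frame", sequences = "DNAStringSet",
                 params = "ShimmerParams"))

setValidity("MapGraph", function(object) {
  msg <- character()
  if (nrow(object@vertices) &&
      !isTRUE(all.equal(sum(object@vertices$weight), nrow(object@frags))))
    msg <- c(msg, "vertex weights must sum to the number of fragment occurrences")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MapGraph", function(object) {
  cat(sprintf("MapGraph: %d vertices, %d edges, %d path(s); total weight %.0f\n",
              nrow(object@vertices), nrow(object@edges), length(object@paths),
              sum(object@vertices$weight)))
})

#' Principal-bundle decomposition
#'
#' The result of relinearizing a [MapGraph-class]: an ordered list of
#' principal bundles (maximal simple paths of the pruned graph, ranked by
#' vertex count) and the projection of every contig onto them as
#' BED-style segments.
#'
#' @slot bundles list of data.frames (one per bundle, in `bundle_id` order)
#'   with columns `vertex_id`, `hash_a`, `hash_b`.
#' @slot segments data.frame of [BundleSegment][projectBundles()] records.
#' @slot vertexMap data.frame mapping `vertex_id` to `bundle_id` and
#'   0-based position `idx` within the bundle.
#' @slot params list of the decomposition tuning parameters used.
#' @export
setClass("BundleDecomposition",
  representation(bundles = "list", segments = "data.frame",
                 vertexMap = "data.frame", params = "list"))

setMethod("show", "BundleDecomposition", function(object) {
  cat(sprintf("BundleDecomposition: %d bundle(s), %d segment(s) on %d contig(s)\n",
              length(object@bundles), nrow(object@segments),
              length(unique(object@segments$contig_name))))
  if (length(object@bundles)) {
    sizes <- vapply(object@bundles, nrow, integer(1))
    cat("  bundle sizes (vertices): ", paste(utils::head(sizes, 10L), collapse = ", "),
        if (length(sizes) > 10L) ", ..." else "", "\n", sep = "")
  }
})
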