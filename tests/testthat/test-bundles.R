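test_that("weight-prioritized DFS follows the spine and hangs bubbles", {
  # linear path: one tree, every vertex chained to the previous
  lin <- toy_graph(rep(5, 6), cbind(0:4, 1:5))
  f <- weightedDfsForest(lin)
  expect_equal(sum(is.na(f$parent)), 1L)
  expect_equal(nrow(f), 6L)
  expect_true(all(f$root == f$root[1]))
  # 10-vertex fixture: weight-10 spine 0..6, weight-1 bubble 7-8-9
  # attached at spine vertices 2 and 4
  g <- toy_graph(c(rep(10, 7), 1, 1, 1),
                 rbind(cbind(0:5, 1:6), c(2, 7), c(7, 8), c(8, 9), c(9, 4)))
  f <- weightedDfsForest(g)
  expect_equal(f$vertex[1:7], 0:6)     # spine explored first, id tiebreak
  bubble <- f[f$vertex %in% 7:9, ]
  # the bubble hangs off the spine (entered from either attachment)
  expect_true(all(bubble$parent %in% c(2, 4, 7, 8, 9)))
  # two disconnected components give two trees
  two <- toy_graph(rep(3, 4), rbind(c(0, 1), c(2, 3)))
  expect_equal(length(unique(weightedDfsForest(two)$root)), 2L)
  # empty graph gives an empty forest
  expect_equal(nrow(weightedDfsForest(toy_graph(integer(0),
    matrix(integer(0), 0, 2)))), 0L)
})

test_that("short branches are pruned by subtree size", {
  g <- toy_graph(c(rep(10, 7), 1, 1),
                 rbind(cbind(0:5, 1:6), c(2, 7), c(7, 8), c(8, 4)))
  pruned <- pruneShortBranches(g, min_branch_size = 8)
  expect_equal(sort(graphVertices(pruned)$vertex_id), 0:6)
  # a branch of exactly min_branch_size vertices is kept
  kept <- pruneShortBranches(g, min_branch_size = 2)
  expect_equal(sort(graphVertices(kept)$vertex_id), 0:8)
  # min_branch_size 0 is a no-op
  expect_equal(nrow(graphVertices(pruneShortBranches(g, 0))), 9L)
})

test_that("principal bundles are simple paths ranked by size", {
  # 20-vertex path: a single bundle covering everything
  lin <- toy_graph(rep(2, 20), cbind(0:18, 1:19))
  d <- extractPrincipalBundles(lin)
  expect_equal(length(principalBundles(d)), 1L)
  expect_equal(nrow(principalBundles(d)[[1]]), 20L)
  # star with 5 spokes of length 6: hub removed, five 6-vertex bundles
  spokes <- do.call(rbind, lapply(0:4, function(s) {
    ids <- 1L + s * 6L + 0:5
    rbind(c(0L, ids[1]), cbind(ids[-6], ids[-1]))
  }))
  star <- toy_graph(rep(1, 31), spokes)
  d <- extractPrincipalBundles(star)
  expect_equal(length(principalBundles(d)), 5L)
  expect_true(all(vapply(principalBundles(d), nrow, 1L) == 6L))
  expect_false(0L %in% d@vertexMap$vertex_id)
})

test_that("every extracted bundle passes a structural audit", {
  pg <- generatePangenome(presetPlan("palindrome3"))
  g <- buildMapGraph(pg$seqs, fixture_params())
  pruned <- pruneShortBranches(g, min_branch_size = 8, min_cov = 2)
  d <- extractPrincipalBundles(pruned)
  e <- graphEdges(pruned)
  el <- e[e$v_from != e$v_to, c("v_from", "v_to")]
  for (b in principalBundles(d)) {
    expect_equal(anyDuplicated(b$vertex_id), 0L)
    if (nrow(b) < 2L) next
    # consecutive bundle vertices are connected in the pruned graph
    for (i in seq_len(nrow(b) - 1L)) {
      u <- b$vertex_id[i]; v <- b$vertex_id[i + 1L]
      expect_true(any((el$v_from == u & el$v_to == v) |
                      (el$v_from == v & el$v_to == u)))
    }
    # interior vertices touch exactly 2 distinct neighbors among survivors
    alive <- d@vertexMap$vertex_id
    el2 <- unique(el[el$v_from %in% alive & el$v_to %in% alive, ])
    interior <- b$vertex_id[-c(1L, nrow(b))]
    ndeg <- vapply(interior, function(v)
      length(unique(c(el2$v_to[el2$v_from == v],
                      el2$v_from[el2$v_to == v]))), integer(1))
    expect_true(all(ndeg == 2L))
  }
})

test_that("contig projection yields the documented BED semantics", {
  set.seed(51)
  s <- rand_dna(30000)
  g <- buildMapGraph(c(h1 = s, h2 = s),
                     ShimmerParams(w = 24, k = 24, r = 2, min_span = 0))
  d <- decomposeGraph(g, min_branch_size = 0)
  segs <- bundleSegments(d)
  seg1 <- segs[segs$contig_name == "h1", ]
  expect_equal(nrow(seg1), 1L)
  n <- seg1$bundle_vertex_count
  expect_equal(seg1$orientation, 0L)
  expect_equal(c(seg1$begin_vertex, seg1$end_vertex), c(0L, n - 1L))
  expect_equal(seg1$repeat_flag, "U")
  # the full-traversal spec string
  path <- tempfile(fileext = ".bed")
  writeBundleBed(d, path)
  ln <- readLines(path)
  expect_match(ln[1], sprintf("^h1\t\\d+\t\\d+\t0:%d:0:0:%d:U$", n, n - 1L))
  expect_equal(readBundleBed(path), segs)
  # summary arithmetic
  sm <- contigSummary(d)
  expect_equal(sm$covered_bases[sm$contig_name == "h1"],
               sum(seg1$end - seg1$begin))
})

test_that("tandem copies are flagged repetitive", {
  tok <- function(u, o = 0L) data.frame(unit = u, orientation = o)
  plan <- pangenomePlan(
    units = c(flankL = 30000L, U = 16000L, flankR = 30000L),
    haplotypes = list(h = rbind(tok("flankL"), tok("U"), tok("U"),
                                tok("flankR"))),
    snp_rate = 0, seed = 7)
  pg <- generatePangenome(plan)
  g <- buildMapGraph(pg$seqs, fixture_params())
  d <- decomposeGraph(g, min_cov = 2, bundle_length_cutoff = 1000)
  segs <- bundleSegments(d)
  rep_segs <- segs[segs$repeat_flag == "R", ]
  expect_equal(nrow(rep_segs), 2L)
  expect_equal(unique(rep_segs$bundle_id), rep_segs$bundle_id[1])
  expect_true(all(rep_segs$orientation == rep_segs$orientation[1]))
  jac <- vapply(seq_len(nrow(pg$truth)), function(i)
    max(vapply(seq_len(nrow(rep_segs)), function(j)
      interval_jaccard(pg$truth$begin[i], pg$truth$end[i],
                       rep_segs$begin[j], rep_segs$end[j]), 1)), 1)
  expect_true(all(jac >= 0.9))
})

test_that("palindromic units project with alternating orientation", {
  pg <- generatePangenome(presetPlan("palindrome3"))
  g <- buildMapGraph(pg$seqs, fixture_params())
  d <- palindrome_decomp(g)
  segs <- bundleSegments(d)
  tab <- table(segs$bundle_id)
  rb <- as.integer(names(tab)[which.max(tab)])
  rep_segs <- segs[segs$bundle_id == rb, ]
  rep_segs <- rep_segs[order(rep_segs$begin), ]
  expect_equal(nrow(rep_segs), 6L)           # 2 segments per palindrome unit
  expect_true(all(diff(rep_segs$orientation) != 0))
  expect_true(all(rep_segs$repeat_flag == "R"))
})

test_that("high-weight backbones absorb most of each contig", {
  pg <- generatePangenome(presetPlan("bubble"))
  g <- buildMapGraph(pg$seqs, fixture_params())
  d <- decomposeGraph(g, min_branch_size = 8)
  segs <- bundleSegments(d)
  for (cn in names(g@paths)) {
    p <- g@paths[[cn]]
    span <- max(p$end) - min(p$begin)
    covered <- sum(segs$end[segs$contig_name == cn] -
                   segs$begin[segs$contig_name == cn])
    expect_gte(covered / span, 0.9)
  }
  # bundle vertices carry at least the mean weight of removed vertices
  in_bundle <- graphVertices(g)$vertex_id %in% d@vertexMap$vertex_id
  w <- graphVertices(g)$weight
  expect_gte(mean(w[in_bundle]), mean(w[!in_bundle]))
})

test_that("projection validates contig names", {
  set.seed(52)
  g <- buildMapGraph(c(h1 = rand_dna(20000)),
                     ShimmerParams(w = 24, k = 24, r = 2, min_span = 0))
  d <- extractPrincipalBundles(pruneShortBranches(g, 0))
  expect_error(projectBundles(g, d, contigs = "missing"),
               "absent from the graph.*missing")
})

test_that("malformed bundle BED lines are rejected with their line number", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("h1\t0\t100\t0:5:0:0:4:U", "h2\t0\t100"), path)
  expect_error(readBundleBed(path), "line 2")
  writeLines(c("h1\t0\t100\t0:5:0"), path)
  expect_error(readBundleBed(path), "specification on line 1")
})
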