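cycle_adj <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, i %% n + 1L] <- 1
  A
}

test_that("diffusion weights reach the closed-form stationary state", {
  # regular 8-cycle: uniform distribution, entropy log2(8), rep score 1
  res <- diffusionWeights(cycle_adj(8))
  expect_equal(res$P, rep(1 / 8, 8), tolerance = 1e-10)
  expect_equal(res$entropy, 3.0, tolerance = 1e-9)
  expect_equal(res$rep_score, 1.0, tolerance = 1e-9)
  # 3-vertex path: p = d / sum(d) = (0.25, 0.5, 0.25), 1.5 bits
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 3] <- 1
  res3 <- diffusionWeights(A)
  expect_equal(res3$P, c(0.25, 0.5, 0.25), tolerance = 1e-10)
  expect_equal(res3$entropy, 1.5, tolerance = 1e-9)
  # single vertex: zero entropy
  expect_equal(diffusionWeights(matrix(0, 1, 1))$entropy, 0)
})

test_that("the lazy walk matches d/sum(d) on random connected graphs", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(5:200, 1L)
    repeat {
      ig <- igraph::sample_gnm(n, min(n * (n - 1) / 2, n + sample(0:n, 1L)))
      if (igraph::is_connected(ig)) break
    }
    A <- as.matrix(igraph::as_adjacency_matrix(ig))
    A[lower.tri(A)] <- 0                     # one direction; symmetrized inside
    res <- diffusionWeights(A, tol = 1e-13, max_iter = 20000)
    d <- Matrix::rowSums(res$A)
    expect_lt(max(abs(res$P - d / sum(d))), 1e-8)
    expect_equal(sum(res$P), 1, tolerance = 1e-12)
    expect_gte(res$entropy, 0)
    expect_lte(res$entropy, log2(res$N) + 1e-9)
  }
})

test_that("entropy and repeat score validate and bound their inputs", {
  expect_error(diffusionEntropy(c(0.5, 0.4)), "not normalized")
  expect_equal(diffusionEntropy(rep(1 / 16, 16)), 4.0)
  # one vertex absorbing half the mass dominates the top-32 mean
  P <- c(0.5, rep(0.5 / 99, 99))
  expect_gte(maxRepeatWeight(P, 100), 50 / 32)
  # fewer than 32 vertices: average over all of them
  expect_equal(maxRepeatWeight(rep(0.1, 10), 10), 1.0)
  # entropy of the stationary state is log2(N) exactly on regular graphs
  for (n in c(4, 6, 12)) {
    expect_equal(diffusionWeights(cycle_adj(n))$entropy, log2(n),
                 tolerance = 1e-9)
  }
})

test_that("isolated vertices are flagged", {
  A <- matrix(0, 3, 3); A[1, 2] <- 1
  res <- diffusionWeights(A)
  expect_equal(res$isolated, 2L)   # 0-based index of the isolated vertex
})

test_that("adding a divergent haplotype never lowers diffusion entropy", {
  tok <- function(u, o = 0L) data.frame(unit = u, orientation = o)
  p <- ShimmerParams(w = 24, k = 24, r = 2, min_span = 0)
  for (seed in 1:10) {
    units <- c(flankL = 12000L, mid = 8000L, alt = 8000L, flankR = 12000L)
    base <- list(
      h1 = rbind(tok("flankL"), tok("mid"), tok("flankR")),
      h2 = rbind(tok("flankL"), tok("mid"), tok("flankR")),
      h3 = rbind(tok("flankL"), tok("mid"), tok("flankR")))
    hom <- generatePangenome(pangenomePlan(units, base, seed = seed))
    div <- generatePangenome(pangenomePlan(units,
      c(base, list(h4 = rbind(tok("flankL"), tok("alt"), tok("flankR")))),
      seed = seed))
    s_hom <- diffusionWeights(buildMapGraph(hom$seqs, p))$entropy
    s_div <- diffusionWeights(buildMapGraph(div$seqs, p))$entropy
    expect_gte(s_div, s_hom)
  }
})

test_that("haplotype vectors reflect path membership", {
  set.seed(62)
  p <- ShimmerParams(w = 24, k = 24, r = 2, min_span = 0)
  sA <- rand_dna(30000); sB <- rand_dna(30000)
  g <- buildMapGraph(c(a1 = sA, a2 = sA, b1 = sB), p)
  d <- decomposeGraph(g, min_branch_size = 0)
  M <- haplotypeVertexMatrix(g, d)
  expect_equal(M["a1", ], M["a2", ])                      # identical rows
  expect_equal(sum(M["a1", ] * M["b1", ]), 0L)            # disjoint bundles
  pc <- haplotypePCA(M)
  expect_lt(abs(pc$scores["a1", 1] - pc$scores["a2", 1]), 1e-8)
  expect_error(haplotypeVertexMatrix(g, d, contigs = "zz"), "not in graph")
})

test_that("planted clusters separate on the first principal component", {
  for (seed in c(42, 7)) {
    pg <- generatePangenome(presetPlan("two_cluster_mhc", seed = seed))
    g <- buildMapGraph(pg$seqs, fixture_params())
    d <- decomposeGraph(g)
    M <- haplotypeVertexMatrix(g, d)
    pc1 <- haplotypePCA(M)$scores[, 1]
    grp <- grepl("^clusterA", names(pc1))
    margin <- min(pc1[grp]) > max(pc1[!grp]) ||
      min(pc1[!grp]) > max(pc1[grp])
    expect_true(margin)
  }
})

test_that("bundle distances behave like a [0,1] dissimilarity", {
  seg <- function(contig, begin, end, bundle, orient) data.frame(
    contig_name = contig, begin = begin, end = end, bundle_id = bundle,
    bundle_vertex_count = 10L, orientation = orient, begin_vertex = 0L,
    end_vertex = 9L, repeat_flag = "U")
  # identical decompositions are at distance zero and merge first
  segs <- rbind(seg("a", 0, 1000, 0L, 0L), seg("a", 1000, 3000, 1L, 0L),
                seg("b", 0, 1000, 0L, 0L), seg("b", 1000, 3000, 1L, 0L),
                seg("c", 0, 4000, 2L, 1L))
  bd <- bundleDistance(segs)
  expect_equal(bd$dist["a", "b"], 0)
  expect_equal(bd$dist["a", "c"], 1)          # token-disjoint
  expect_true(all(diag(bd$dist) == 0))
  expect_equal(bd$dist, t(bd$dist))
  first_merge <- bd$hclust$merge[1, ]
  expect_equal(sort(bd$hclust$labels[-first_merge]), c("a", "b"))
  # A = x.y, B = x.z with equal lengths: distance 1/2 by LCS arithmetic
  ab <- rbind(seg("A", 0, 1000, 0L, 0L), seg("A", 1000, 2000, 1L, 0L),
              seg("B", 0, 1000, 0L, 0L), seg("B", 1000, 2000, 2L, 0L))
  expect_equal(bundleDistance(ab)$dist["A", "B"], 0.5)
  # orientation participates in matching
  flip <- rbind(seg("A", 0, 1000, 0L, 0L), seg("B", 0, 1000, 0L, 1L))
  expect_equal(bundleDistance(flip)$dist["A", "B"], 1)
  expect_error(bundleDistance(seg("solo", 0, 10, 0L, 0L)), "at least 2")
})

test_that("distance outputs serialize to .dist, Newick and .ddg", {
  seg <- function(contig, begin, end, bundle) data.frame(
    contig_name = contig, begin = begin, end = end, bundle_id = bundle,
    bundle_vertex_count = 5L, orientation = 0L, begin_vertex = 0L,
    end_vertex = 4L, repeat_flag = "U")
  segs <- do.call(rbind, lapply(1:4, function(i)
    seg(sprintf("s%d", i), 0, 1000 * i, i %% 2)))
  bd <- bundleDistance(segs)
  prefix <- tempfile()
  files <- writeDistanceFiles(bd, prefix)
  expect_true(all(file.exists(files)))
  dist_tab <- read.table(files[["dist"]], header = TRUE, sep = "\t")
  expect_equal(nrow(dist_tab), choose(4, 2))
  tree <- ape::read.tree(files[["nwk"]])
  expect_setequal(tree$tip.label, sprintf("s%d", 1:4))
  ddg <- readDendrogramLayout(files[["ddg"]])
  expect_equal(nrow(ddg$leaves), 4L)
  expect_equal(nrow(ddg$merges), 3L)
  expect_equal(ddg$merges$height, bd$hclust$height)
})
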