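test_that("canonical k-mer hash is strand-symmetric", {
  h <- kmerHash(c("ACGT", "AAAC", "GTTT"))
  expect_equal(h$hash[2], h$hash[3])          # canonical pair
  expect_equal(h$strand, c(0L, 0L, 1L))       # palindrome reports strand 0
  set.seed(101)
  km <- vapply(1:200, function(i) rand_dna(21), character(1))
  expect_equal(kmerHash(km)$hash, kmerHash(vapply(km, revcomp, ""))$hash)
  expect_error(kmerHash("ACGN"), "invalid alphabet")
})

test_that("level-0 minimizers match the brute-force window oracle", {
  set.seed(202)
  for (i in 1:20) {
    s <- rand_dna(2000)
    m <- minimizers(s, 48, 56)
    o <- oracle_minimizers(s, 48, 56)
    expect_equal(m$pos, o$pos)
    expect_equal(m$hash, o$hash)
  }
  # small parameters exercise dense windows
  for (i in 1:10) {
    s <- rand_dna(300)
    m <- minimizers(s, 5, 7)
    o <- oracle_minimizers(s, 5, 7)
    expect_equal(m$pos, o$pos)
  }
})

test_that("sequences shorter than k or with ambiguity blocks degrade cleanly", {
  expect_equal(nrow(minimizers(rand_dna(55), 10, 56)), 0L)
  # an N run of >= k bases splits the scan into independent blocks
  set.seed(7)
  left <- rand_dna(500); right <- rand_dna(500)
  s <- paste0(left, strrep("N", 60), right)
  m <- minimizers(s, 5, 7)
  o <- oracle_minimizers(s, 5, 7)
  expect_equal(m$pos, o$pos)
  expect_true(all(m$pos <= 493 | m$pos >= 560))
})

test_that("hierarchical reduction applies window minima over hash lists", {
  mins <- data.frame(pos = c(0L, 10L, 20L, 30L, 40L, 50L),
                     hash = c(9, 4, 7, 2, 8, 6), strand = 0L)
  expect_identical(hierarchicalReduce(mins, r = 1), mins)
  expect_identical(hierarchicalReduce(mins, r = 4, levels = 1), mins)
  red <- hierarchicalReduce(mins, r = 3)
  expect_equal(red$hash, c(4, 2))
  set.seed(303)
  for (i in 1:20) {
    h <- runif(50)
    mins <- data.frame(pos = seq(0, by = 10, length.out = 50), hash = h,
                       strand = 0L)
    red <- hierarchicalReduce(mins, r = 4)
    expect_equal(red$hash, h[oracle_window_min(h, 4)])
  }
  # short lists pass through a reduction level untouched
  expect_identical(hierarchicalReduce(mins[1:2, ], r = 4), mins[1:2, ])
})

test_that("minimum-span thinning honors both heuristics", {
  mins <- data.frame(pos = c(0L, 5L, 8L, 20L), hash = c(4, 3, 2, 1),
                     strand = 0L)
  expect_equal(enforceMinSpan(mins, 10, method = "greedy")$pos, c(0L, 20L))
  expect_identical(enforceMinSpan(mins, 0), mins)
  wide <- data.frame(pos = c(0L, 30L, 70L), hash = c(1, 2, 3), strand = 0L)
  expect_identical(enforceMinSpan(wide, 10), wide)
  # symmetric method keeps a valid set and is strand-invariant
  set.seed(404)
  s <- rand_dna(20000)
  p <- ShimmerParams(w = 10, k = 16, r = 2, min_span = 40)
  a <- shimmers(s, p); b <- shimmers(revcomp(s), p)
  expect_true(all(diff(a$pos) >= 40))
  expect_equal(sort(a$hash), sort(b$hash))
  expect_equal(sort(a$pos), sort(20000 - 16 - b$pos))
})

test_that("sparsification is monotone in r and min_span", {
  set.seed(505)
  s <- rand_dna(30000)
  n_r <- vapply(c(1, 2, 4, 8, 12), function(r)
    nrow(shimmers(s, ShimmerParams(w = 24, k = 24, r = r, min_span = 0))),
    integer(1))
  expect_true(all(diff(n_r) <= 0))
  n_ms <- vapply(c(0, 20, 50, 100, 200), function(ms)
    nrow(shimmers(s, ShimmerParams(w = 24, k = 24, r = 2, min_span = ms))),
    integer(1))
  expect_true(all(diff(n_ms) <= 0))
  # r = 1, min_span = 0 reproduces the plain minimizer set
  expect_equal(shimmers(s, ShimmerParams(w = 24, k = 24, r = 1, min_span = 0)),
               minimizers(s, 24, 24))
})

test_that("shimmer pairs delimit normalized half-open segments", {
  k <- 56
  shm <- data.frame(pos = c(100L, 900L), hash = c(5, 9), strand = 0L)
  pr <- shimmerPairs(NULL, ShimmerParams(k = k), shm = shm)
  expect_equal(nrow(pr), 1L)
  expect_equal(c(pr$begin, pr$end), c(100L, 956L))
  expect_equal(pr$orientation, 0L)
  shm2 <- data.frame(pos = c(100L, 900L), hash = c(9, 5), strand = 0L)
  pr2 <- shimmerPairs(NULL, ShimmerParams(k = k), shm = shm2)
  expect_equal(pr2$orientation, 1L)
  expect_equal(pr2$hash_a, 5)
  expect_equal(nrow(shimmerPairs(NULL, ShimmerParams(k = k),
                                 shm = shm[1, ])), 0L)
  # reverse complement yields the same key set with flipped orientations
  set.seed(606)
  s <- rand_dna(30000)
  p <- ShimmerParams(w = 24, k = 24, r = 2, min_span = 0)
  pa <- shimmerPairs(s, p); pb <- shimmerPairs(revcomp(s), p)
  key <- function(x) sort(paste(x$hash_a, x$hash_b))
  expect_equal(key(pa), key(pb))
  m <- merge(pa, pb, by = c("hash_a", "hash_b"))
  distinct <- m$hash_a != m$hash_b
  expect_true(all(m$orientation.x[distinct] != m$orientation.y[distinct]))
})

test_that("parameter validity is enforced", {
  expect_error(ShimmerParams(w = 0), "w must be")
  expect_error(ShimmerParams(min_span = -1), "min_span")
  expect_error(ShimmerParams(levels = 0), "levels")
})
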