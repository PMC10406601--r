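qparams <- ShimmerParams(w = 24, k = 24, r = 2, min_span = 0)

make_db <- function(seed = 21, n = 2, len = 120000) {
  set.seed(seed)
  seqs <- stats::setNames(vapply(seq_len(n), function(i) rand_dna(len), ""),
                          sprintf("t%d", seq_len(n)))
  buildIndexFromSeqs(seqs, params = qparams)
}

test_that("self-queries recall their source region", {
  db <- make_db()
  q <- getSequence(db, "t1", 10000, 110000)      # 100 kb slice
  hits <- queryIndex(db, q)
  h <- hits[hits$t_name == "t1" & hits$orientation == 0L, ]
  expect_equal(nrow(h), 1L)
  expect_gte(h$t_end - h$t_begin, 0.95 * 100000)
  expect_gte(h$t_begin, 9000); expect_lte(h$t_end, 111000)
  # reverse-complement query: same span, flipped orientation
  hits_rc <- queryIndex(db, revcomp(q))
  hrc <- hits_rc[hits_rc$t_name == "t1" & hits_rc$orientation == 1L, ]
  expect_equal(nrow(hrc), 1L)
  expect_lte(abs(hrc$t_begin - h$t_begin), 1000)
  expect_lte(abs(hrc$t_end - h$t_end), 1000)
})

test_that("unrelated queries yield no anchors", {
  db <- make_db(seed = 22)
  for (seed in 1:20) {
    set.seed(1000 + seed)
    q <- rand_dna(50000)
    expect_equal(nrow(lookupAnchors(db, q)), 0L)
  }
})

test_that("short queries warn and return empty", {
  db <- make_db(seed = 23, len = 50000)
  expect_warning(res <- lookupAnchors(db, rand_dna(30)), "fewer than 2")
  expect_equal(nrow(res), 0L)
})

test_that("anchor chaining finds maximum monotone chains", {
  mk <- function(qb, tb, o = 0L) data.frame(
    q_begin = qb, q_end = qb + 100L, t_seq_id = 0L,
    t_begin = tb, t_end = tb + 100L, orientation = o)
  # perfectly collinear anchors form a single chain
  a <- mk(seq(0, 4000, by = 1000), seq(5000, 9000, by = 1000))
  ch <- chainAnchors(a, max_gap = 100000)
  expect_equal(length(ch), 1L)
  expect_equal(nrow(ch[[1]]), 5L)
  # one anchor violating target monotonicity is excluded
  b <- rbind(a, mk(2500L, 100L))
  ch <- chainAnchors(b, max_gap = 100000)
  expect_equal(nrow(ch[[1]]), 5L)
  expect_false(100L %in% ch[[1]]$t_begin)
  # exhaustive cross-check on random small anchor sets
  set.seed(31)
  for (i in 1:15) {
    r <- data.frame(q_begin = sample(0:5000, 8) %/% 10 * 10)
    r$q_end <- r$q_begin + 50L
    r$t_seq_id <- 0L
    r$t_begin <- sample(0:5000, 8)
    r$t_end <- r$t_begin + 50L
    r$orientation <- 0L
    ch <- chainAnchors(r, max_gap = 2000)
    got <- if (length(ch)) max(vapply(ch, nrow, 1L)) else 0L
    want <- oracle_best_chain_size(r, max_gap = 2000)
    if (want < 2L) want <- 0L                 # chains below min_chain dropped
    expect_equal(got, want)
  }
  # clusters separated by more than max_gap split into two chains
  cl <- rbind(mk(seq(0, 2000, by = 1000), seq(0, 2000, by = 1000)),
              mk(seq(500000, 502000, by = 1000), seq(500000, 502000, by = 1000)))
  ch <- chainAnchors(cl, max_gap = 100000)
  expect_equal(length(ch), 2L)
})

test_that("range merging unions nearby chains and is idempotent", {
  mkchain <- function(tb, te, qb = tb, qe = te, o = 0L) data.frame(
    q_begin = qb, q_end = qe, t_seq_id = 0L, t_begin = tb, t_end = te,
    orientation = o)
  two <- list(mkchain(100L, 200L), mkchain(250L, 400L))
  m1 <- mergeRanges(two, merge_range_tol = 100)
  expect_equal(nrow(m1), 1L)
  expect_equal(c(m1$t_begin, m1$t_end), c(100L, 400L))
  expect_equal(m1$n_anchors, 2L)
  m2 <- mergeRanges(two, merge_range_tol = 10)
  expect_equal(nrow(m2), 2L)
  expect_error(mergeRanges(two, merge_range_tol = -1), "merge_range_tol")
  # idempotence: re-merging the merged spans changes nothing
  remerge <- mergeRanges(lapply(seq_len(nrow(m1)), function(i)
    mkchain(m1$t_begin[i], m1$t_end[i], m1$q_begin[i], m1$q_end[i])),
    merge_range_tol = 100)
  expect_equal(remerge[, c("t_begin", "t_end", "orientation")],
               m1[, c("t_begin", "t_end", "orientation")])
})

test_that("a large tolerance bridges a polymorphic middle", {
  set.seed(32)
  flankL <- rand_dna(60000); flankR <- rand_dna(60000)
  target <- paste0(flankL, rand_dna(20000), flankR)
  query <- paste0(flankL, rand_dna(20000), flankR)
  db <- buildIndexFromSeqs(c(t = target), params = qparams)
  hits <- queryIndex(db, query, merge_range_tol = 200000)
  h <- hits[hits$orientation == 0L, ]
  expect_equal(nrow(h), 1L)
  expect_lte(h$t_begin, 2000)
  expect_gte(h$t_end, 138000)     # spans both flanks across the divergence
})

test_that("hit sequences are extracted with orientation and clamping", {
  db <- make_db(seed = 24, n = 1, len = 30000)
  hits <- data.frame(query_name = "q", q_begin = 0L, q_end = 1000L,
                     t_source = "memory", t_name = "t1", t_seq_id = 0L,
                     t_begin = 1000L, t_end = 2000L, orientation = 0L,
                     n_anchors = 5L)
  s <- as.character(fetchHitSequences(db, hits)[[1]])
  expect_equal(s, getSequence(db, "t1", 1000, 2000))
  hits$orientation <- 1L
  expect_equal(as.character(fetchHitSequences(db, hits)[[1]]),
               revcomp(getSequence(db, "t1", 1000, 2000)))
  hits$orientation <- 0L
  clamped <- fetchHitSequences(db, hits, padding = 10^6)
  expect_equal(nchar(as.character(clamped[[1]])), 30000L)
  hits$t_seq_id <- 42L
  expect_error(fetchHitSequences(db, hits), "unknown seq_id")
})

test_that("hit tables round-trip through disk", {
  db <- make_db(seed = 25, n = 1, len = 60000)
  hits <- queryIndex(db, getSequence(db, "t1", 5000, 55000))
  path <- tempfile(fileext = ".hit")
  writeHitTable(hits, path)
  expect_equal(readHitTable(path), hits)
})
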