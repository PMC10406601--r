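#' Build a SHIMMER sequence index from FASTA files
#'
#' Loads every sequence from the given FASTA files (plain or
#' gzip-compressed), assigns stable 0-based `seq_id`s in file order,
#' computes SHIMMER anchors per sequence and populates the hashmap from
#' normalized neighboring-SHIMMER-pair keys to their occurrences.
#'
#' @param fasta_paths character vector of FASTA file paths.
#' @param params a [ShimmerParams-class] object.
#' @return A [SeqIndexDB-class] object.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' set.seed(1)
#' Biostrings::writeXStringSet(Biostrings::DNAStringSet(
#'   c(h1 = paste(sample(c("A","C","G","T"), 5000, TRUE), collapse = ""))), fa)
#' db <- buildIndex(fa, ShimmerParams(w = 12, k = 16, r = 1, min_span = 0))
#' db
#' @export
buildIndex <- function(fasta_paths, params = ShimmerParams()) {
  seqs <- NULL
  sources <- character(0)
  for (fp in fasta_paths) {
    if (!file.exists(fp)) stopf("cannot read FASTA file: %s", fp)
    s <- tryCatch(Biostrings::readDNAStringSet(fp),
                  error = function(e) stopf("failed to parse FASTA '%s': %s",
                                            fp, conditionMessage(e)))
    if (length(s) == 0L) stopf("FASTA file contains no sequences: %s", fp)
    nm <- sub("\\s.*$", "", names(s))
    if (anyDuplicated(nm))
      stopf("duplicate contig name(s) in %s: %s", fp,
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
    names(s) <- nm
    seqs <- if (is.null(seqs)) s else c(seqs, s)
    sources <- c(sources, rep(fp, length(s)))
  }
  buildIndexFromSeqs(seqs, sources, params)
}

#' Build a SHIMMER index from in-memory sequences
#'
#' @param seqs named [Biostrings::DNAStringSet] (or named character vector).
#' @param sources character vector of file-of-origin labels, recycled.
#' @param params a [ShimmerParams-class] object.
#' @return A [SeqIndexDB-class] object.
#' @export
buildIndexFromSeqs <- function(seqs, sources = "memory",
                               params = ShimmerParams()) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs) - 1L)
  sources <- rep_len(sources, length(seqs))
  records <- data.frame(seq_id = seq_along(seqs) - 1L,
                        name = names(seqs),
                        source = sources,
                        length = Biostrings::width(seqs))
  shm_list <- vector("list", length(seqs))
  pair_list <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    shm <- shimmers(as.character(seqs[[i]]), params)
    shm_list[[i]] <- shm
    pr <- shimmerPairs(NULL, params, shm = shm)
    if (nrow(pr)) pr$seq_id <- records$seq_id[i]
    pair_list[[i]] <- pr
  }
  pairs <- do.call(rbind, pair_list[vapply(pair_list, nrow, 1L) > 0L])
  if (is.null(pairs))
    pairs <- data.frame(hash_a = numeric(0), hash_b = numeric(0),
                        begin = integer(0), end = integer(0),
                        orientation = integer(0), seq_id = integer(0))
  rownames(pairs) <- NULL
  pairs$key <- pair_key(pairs$hash_a, pairs$hash_b)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(pairs)) {
    grp <- split(seq_len(nrow(pairs)), pairs$key)
    for (k in names(grp)) assign(k, grp[[k]], envir = idx)
  }
  new("SeqIndexDB", params = params, records = records, sequences = seqs,
      shimmers = shm_list, pairs = pairs, pairIndex = idx)
}

#' @rdname seqInfo
#' @export
setGeneric("seqInfo", function(x) standardGeneric("seqInfo"))

#' Sequence metadata of an index or graph
#'
#' @param x a [SeqIndexDB-class] or [MapGraph-class].
#' @return data.frame with `seq_id`, `name`, `source`, `length`.
#' @export
setMethod("seqInfo", "SeqIndexDB", function(x) x@records)

#' @rdname seqInfo
#' @export
setMethod("seqInfo", "MapGraph", function(x) x@records)

#' @rdname indexParams
#' @export
setGeneric("indexParams", function(x) standardGeneric("indexParams"))

#' SHIMMER parameters of an index or graph
#'
#' @param x a [SeqIndexDB-class] or [MapGraph-class].
#' @return the [ShimmerParams-class] used to build `x`.
#' @export
setMethod("indexParams", "SeqIndexDB", function(x) x@params)

#' @rdname indexParams
#' @export
setMethod("indexParams", "MapGraph", function(x) x@params)

#' Fetch a stored sequence (or subsequence) from an index
#'
#' @param db a [SeqIndexDB-class].
#' @param name contig name.
#' @param begin,end optional 0-based half-open coordinates; clamped to the
#'   contig.
#' @return single character string.
#' @export
getSequence <- function(db, name, begin = 0, end = NA) {
  i <- match(name, db@records$name)
  if (is.na(i)) stopf("unknown contig: %s", name)
  len <- db@records$length[i]
  if (is.na(end)) end <- len
  begin <- max(0, min(begin, len)); end <- max(begin, min(end, len))
  as.character(Biostrings::subseq(db@sequences[[i]], begin + 1L, end))
}

#' SHIMMER anchors stored for one sequence
#'
#' @param db a [SeqIndexDB-class].
#' @param seq_id 0-based sequence identifier.
#' @return data.frame (`pos`, `hash`, `strand`).
#' @export
seqShimmers <- function(db, seq_id) {
  i <- match(seq_id, db@records$seq_id)
  if (is.na(i)) stopf("unknown seq_id: %s", seq_id)
  db@shimmers[[i]]
}

#' Save an index to disk
#'
#' Writes two files: `<prefix>.mdb` holding the pair index (one line per
#' occurrence: `hash_a hash_b seq_id begin end orientation`, with a
#' parameter header) and `<prefix>.midx` holding per-sequence metadata
#' (`seq_id name source length`).  Sequences themselves are not copied; on
#' load they are re-read from their recorded source paths.
#'
#' @param db a [SeqIndexDB-class].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
saveIndex <- function(db, prefix) {
  mdb <- paste0(prefix, ".mdb")
  midx <- paste0(prefix, ".midx")
  p <- db@params
  con <- file(mdb, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("#panmap-mdb\t%d\t%d\t%d\t%d\t%d",
                     p@w, p@k, p@r, p@min_span, p@levels), con)
  if (nrow(db@pairs))
    writeLines(sprintf("%.0f\t%.0f\t%d\t%d\t%d\t%d",
                       db@pairs$hash_a, db@pairs$hash_b, db@pairs$seq_id,
                       db@pairs$begin, db@pairs$end, db@pairs$orientation),
               con)
  writeLines(sprintf("%d\t%s\t%s\t%d", db@records$seq_id, db@records$name,
                     db@records$source, db@records$length), midx)
  invisible(prefix)
}

#' Load an index saved with [saveIndex()]
#'
#' Sequence data are re-read from the source FASTA paths recorded in the
#' `.midx` file; the SHIMMER pair index is taken verbatim from the `.mdb`
#' file, so reloaded queries reproduce the original ones exactly.
#'
#' @param prefix path prefix used at save time.
#' @return A [SeqIndexDB-class].
#' @export
loadIndex <- function(prefix) {
  mdb <- paste0(prefix, ".mdb")
  midx <- paste0(prefix, ".midx")
  if (!file.exists(mdb) || !file.exists(midx))
    stopf("index files not found at prefix: %s", prefix)
  hdr <- readLines(mdb, n = 1L)
  hv <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  if (hv[1] != "#panmap-mdb") stopf("not a panmap index: %s", mdb)
  params <- ShimmerParams(w = as.integer(hv[2]), k = as.integer(hv[3]),
                          r = as.integer(hv[4]), min_span = as.integer(hv[5]),
                          levels = as.integer(hv[6]))
  rec <- utils::read.table(midx, sep = "\t", header = FALSE,
                           col.names = c("seq_id", "name", "source", "length"),
                           colClasses = c("integer", "character", "character",
                                          "integer"))
  seqs <- NULL
  for (fp in unique(rec$source)) {
    if (!file.exists(fp))
      stopf("source FASTA recorded in index not found: %s", fp)
    s <- Biostrings::readDNAStringSet(fp)
    names(s) <- sub("\\s.*$", "", names(s))
    seqs <- if (is.null(seqs)) s else c(seqs, s)
  }
  seqs <- seqs[rec$name]
  pairs <- utils::read.table(mdb, sep = "\t", header = FALSE, skip = 1L,
                             col.names = c("hash_a", "hash_b", "seq_id",
                                           "begin", "end", "orientation"),
                             colClasses = c("numeric", "numeric", "integer",
                                            "integer", "integer", "integer"))
  pairs <- pairs[, c("hash_a", "hash_b", "begin", "end", "orientation",
                     "seq_id")]
  pairs$key <- pair_key(pairs$hash_a, pairs$hash_b)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(pairs)) {
    grp <- split(seq_len(nrow(pairs)), pairs$key)
    for (k in names(grp)) assign(k, grp[[k]], envir = idx)
  }
  shm_list <- lapply(seq_len(nrow(rec)), function(i)
    shimmers(as.character(seqs[[i]]), params))
  new("SeqIndexDB", params = params, records = rec, sequences = seqs,
      shimmers = shm_list, pairs = pairs, pairIndex = idx)
}
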