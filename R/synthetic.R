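#' Define a synthetic pangenome plan
#'
#' A plan holds a library of random DNA units, per-haplotype compositions
#' (ordered unit tokens with orientations), mutation rates and an RNG
#' seed.  [generatePangenome()] turns a plan into FASTA haplotypes plus a
#' truth BED of every planted unit interval.  Units whose id starts with
#' `"flank"` mark the shared flanking sequence and are excluded from the
#' truth BED.
#'
#' @param units named integer vector of unit lengths in bases (the unit
#'   sequences themselves are drawn from the seed), or a named character
#'   vector of explicit sequences.
#' @param haplotypes named list; each element is a data.frame (or list
#'   coercible to one) with columns `unit` (unit id) and `orientation`
#'   (0 forward / 1 reverse complement), in order of concatenation.
#' @param snp_rate substitutions per base applied independently to every
#'   planted copy (0 to 0.2).
#' @param indel_rate small 1-3 bp indels per base (0 to 0.2).
#' @param seed RNG seed; the same seed yields byte-identical FASTA.
#' @return A `pangenomePlan` list object.
#' @export
pangenomePlan <- function(units, haplotypes, snp_rate = 0, indel_rate = 0,
                          seed = 42) {
  if (any(snp_rate < 0, snp_rate > 0.2, indel_rate < 0, indel_rate > 0.2))
    stopf("mutation rates must lie in [0, 0.2]")
  if (is.character(units)) {
    if (any(nchar(units) == 0)) stopf("zero-length unit in plan")
  } else {
    units <- stats::setNames(as.integer(units), names(units))
    if (any(units <= 0L)) stopf("zero-length unit in plan")
  }
  if (is.null(names(units)) || !all(nzchar(names(units))))
    stopf("units must be named")
  haplotypes <- lapply(haplotypes, as.data.frame)
  for (h in haplotypes) {
    if (!all(h$unit %in% names(units)))
      stopf("composition references unknown unit(s): %s",
            paste(setdiff(h$unit, names(units)), collapse = ", "))
  }
  structure(list(units = units, haplotypes = haplotypes,
                 snp_rate = snp_rate, indel_rate = indel_rate, seed = seed),
            class = "pangenomePlan")
}

mutate_seq <- function(s, snp_rate, indel_rate) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  if (snp_rate > 0) {
    hit <- which(stats::runif(n) < snp_rate)
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  if (indel_rate > 0) {
    hit <- which(stats::runif(length(v)) < indel_rate)
    for (i in rev(hit)) {
      if (stats::runif(1) < 0.5) {
        w <- sample(1:3, 1L)
        v <- v[-(i:min(i + w - 1L, length(v)))]
      } else {
        ins <- sample(c("A", "C", "G", "T"), sample(1:3, 1L), replace = TRUE)
        v <- append(v, ins, after = i)
      }
    }
  }
  paste(v, collapse = "")
}

#' Generate a synthetic pangenome from a plan
#'
#' Haplotypes are assembled by concatenating (possibly
#' reverse-complemented, independently mutated) copies of the plan's units;
#' the truth table records every planted non-flank unit interval with its
#' unit id and orientation.  Deterministic in the plan seed.
#'
#' @param plan a [pangenomePlan()].
#' @param out_prefix optional path prefix; writes `<prefix>.fa` and the
#'   truth intervals to `<prefix>.truth.bed`
#'   (`contig begin end unit_id:orientation`).
#' @return list with `seqs` (named `DNAStringSet`) and `truth`
#'   (data.frame `contig`, `begin`, `end`, `unit`, `orientation`), plus
#'   `files` when `out_prefix` is given.
#' @examples
#' plan <- presetPlan("palindrome3")
#' pg <- generatePangenome(plan)
#' pg$truth
#' @export
generatePangenome <- function(plan, out_prefix = NULL) {
  stopifnot(inherits(plan, "pangenomePlan"))
  with_seed(plan$seed, {
    unit_seqs <- if (is.character(plan$units)) plan$units
    else vapply(plan$units, random_dna, character(1))
    haps <- character(length(plan$haplotypes))
    names(haps) <- names(plan$haplotypes)
    truth <- list()
    for (hi in seq_along(plan$haplotypes)) {
      comp <- plan$haplotypes[[hi]]
      parts <- character(nrow(comp))
      pos <- 0L
      for (ti in seq_len(nrow(comp))) {
        u <- comp$unit[ti]
        s <- mutate_seq(unit_seqs[[u]], plan$snp_rate, plan$indel_rate)
        if (comp$orientation[ti] == 1L) s <- revcomp_chr(s)
        parts[ti] <- s
        if (!startsWith(u, "flank"))
          truth[[length(truth) + 1L]] <- data.frame(
            contig = names(plan$haplotypes)[hi], begin = pos,
            end = pos + nchar(s), unit = u,
            orientation = comp$orientation[ti])
        pos <- pos + nchar(s)
      }
      haps[hi] <- paste(parts, collapse = "")
    }
    truth <- if (length(truth)) do.call(rbind, truth)
    else data.frame(contig = character(0), begin = integer(0),
                    end = integer(0), unit = character(0),
                    orientation = integer(0))
    seqs <- Biostrings::DNAStringSet(haps)
    out <- list(seqs = seqs, truth = truth)
    if (!is.null(out_prefix)) {
      fa <- paste0(out_prefix, ".fa")
      bed <- paste0(out_prefix, ".truth.bed")
      Biostrings::writeXStringSet(seqs, fa)
      writeLines(sprintf("%s\t%d\t%d\t%s:%d", truth$contig, truth$begin,
                         truth$end, truth$unit, truth$orientation), bed)
      out$files <- c(fasta = fa, truth = bed)
    }
    out
  })
}

#' Named preset pangenome plans
#'
#' Fixed study designs used throughout the package tests:
#' \describe{
#'   \item{`palindrome3`}{one haplotype with three palindromic repeats:
#'     `flank, 3 x (U forward, U reverse), flank` - six planted copies of
#'     a 16 kb unit with alternating orientation between 30 kb flanks,
#'     SNP rate 1e-3.  Emulates an amylase-locus-style nested palindrome.}
#'   \item{`bubble`}{eight haplotypes sharing 30 kb flanks around one of
#'     two divergent 10 kb middle alleles at frequencies 6:2.}
#'   \item{`big_inversion`}{two haplotypes; the second carries the two
#'     10 kb middle units inverted as a block (`B-`, `A-`), a
#'     segmental-duplication-style large inversion.}
#'   \item{`two_cluster_mhc`}{sixteen haplotypes = two structural alleles
#'     (distinct 15 kb middles) times eight carriers with SNP noise,
#'     mimicking a polymorphic gene-cluster locus with two haplotype
#'     groups.}
#' }
#'
#' @param name one of the preset names.
#' @param seed RNG seed recorded in the plan.
#' @return A [pangenomePlan()].
#' @export
presetPlan <- function(name, seed = 42) {
  tok <- function(unit, orientation = 0L)
    data.frame(unit = unit, orientation = as.integer(orientation))
  switch(name,
    palindrome3 = {
      comp <- rbind(tok("flankL"),
                    do.call(rbind, rep(list(rbind(tok("U"), tok("U", 1L))),
                                       3L)),
                    tok("flankR"))
      pangenomePlan(units = c(flankL = 30000L, U = 16000L, flankR = 30000L),
                    haplotypes = list(hap0 = comp),
                    snp_rate = 1e-3, seed = seed)
    },
    bubble = {
      mk <- function(mid) rbind(tok("flankL"), tok(mid), tok("flankR"))
      haps <- c(rep(list(mk("allele_major")), 6L),
                rep(list(mk("allele_minor")), 2L))
      names(haps) <- sprintf("hap%d", seq_along(haps) - 1L)
      pangenomePlan(units = c(flankL = 30000L, allele_major = 10000L,
                              allele_minor = 10000L, flankR = 30000L),
                    haplotypes = haps, snp_rate = 1e-3, seed = seed)
    },
    big_inversion = {
      fwd <- rbind(tok("flankL"), tok("A"), tok("B"), tok("flankR"))
      inv <- rbind(tok("flankL"), tok("B", 1L), tok("A", 1L), tok("flankR"))
      pangenomePlan(units = c(flankL = 30000L, A = 10000L, B = 10000L,
                              flankR = 30000L),
                    haplotypes = list(hap_fwd = fwd, hap_inv = inv),
                    snp_rate = 1e-3, seed = seed)
    },
    two_cluster_mhc = {
      mk <- function(mid) rbind(tok("flankL"), tok(mid), tok("flankR"))
      haps <- c(rep(list(mk("alleleA")), 8L), rep(list(mk("alleleB")), 8L))
      names(haps) <- c(sprintf("clusterA_h%d", 0:7),
                       sprintf("clusterB_h%d", 0:7))
      pangenomePlan(units = c(flankL = 30000L, alleleA = 15000L,
                              alleleB = 15000L, flankR = 30000L),
                    haplotypes = haps, snp_rate = 2e-3, seed = seed)
    },
    stopf("unknown preset plan: %s", name))
}

#' Read a truth BED written by [generatePangenome()]
#'
#' @param path truth BED file.
#' @return data.frame `contig`, `begin`, `end`, `unit`, `orientation`.
#' @export
readTruthBed <- function(path) {
  ln <- readLines(path)
  parts <- strsplit(ln[nzchar(ln)], "\t", fixed = TRUE)
  spec <- strsplit(vapply(parts, `[`, "", 4L), ":", fixed = TRUE)
  data.frame(
    contig = vapply(parts, `[`, "", 1L),
    begin = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    unit = vapply(spec, `[`, "", 1L),
    orientation = as.integer(vapply(spec, `[`, "", 2L)))
}
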