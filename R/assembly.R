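#' @include snp.R
NULL

readsForAssembly <- function(reads) {
  if (is(reads, "ReadSet")) reads <- readSequences(reads)
  if (is(reads, "DNAStringSet")) return(as.character(reads))
  if (is.character(reads)) return(toupper(reads))
  stop("unsupported read container: ", class(reads)[1L])
}

#' de Bruijn assembly of a read set
#'
#' Builds the de Bruijn graph of the reads (and their reverse
#' complements), drops k-mers below the abundance floor, compacts
#' unbranched paths into unitigs, optionally pops simple two-path
#' bubbles (keeping the higher-coverage branch; coverage ties keep the
#' branch with the lexicographically smaller canonical sequence), and
#' emits contigs of at least 2k bases in canonical orientation.
#'
#' A desk-scale stand-in for production assemblers: no scaffolding,
#' paired-end resolution or repeat resolution.
#'
#' @param reads a [ReadSet-class], [Biostrings::DNAStringSet] or
#'   character vector.
#' @param params an [AssemblyParams] object.
#' @return A [Biostrings::DNAStringSet] of contigs (named
#'   contig_00001, ...) with metadata columns `coverage` (mean k-mer
#'   coverage) and `length`.
#' @export
debruijnAssemble <- function(reads, params = assemblyParams()) {
  rd <- readsForAssembly(reads)
  if (length(rd) == 0L) return(Biostrings::DNAStringSet())
  res <- cpp_debruijn(rd, params@k, params@minKmerCount,
                      params@bubblePolicy == "pop")
  contigs <- Biostrings::DNAStringSet(res$contigs)
  if (length(contigs))
    names(contigs) <- sprintf("contig_%05d", seq_along(contigs))
  S4Vectors::mcols(contigs) <- S4Vectors::DataFrame(
    coverage = res$coverage, length = Biostrings::width(contigs))
  contigs
}

#' Count simple bubbles in the de Bruijn graph
#'
#' A simple bubble is a pair of unitigs that diverge from one unitig
#' and reconverge on another — the structural footprint of an isolated
#' SNP between co-assembled haplotypes. Strand twins are counted once.
#'
#' @inheritParams debruijnAssemble
#' @return integer bubble count.
#' @export
countBubbles <- function(reads, params = assemblyParams()) {
  rd <- readsForAssembly(reads)
  if (length(rd) == 0L) return(0L)
  cpp_count_bubbles(rd, params@k, params@minKmerCount)
}

# map reference (subject) positions to query bases through a hit row
alignedBaseAt <- function(contigChar, hit, positions) {
  seq <- contigChar
  L <- nchar(seq)
  if (hit$strand == "-") {
    seq <- revcompChar(seq)
    q <- L - hit$qend + 1L
  } else {
    q <- hit$qstart
  }
  s <- hit$sstart
  res <- rep(NA_character_, length(positions))
  want <- order(positions)
  wi <- 1L
  ops <- regmatches(hit$cigar, gregexpr("\\d+[MID]", hit$cigar))[[1L]]
  for (op in ops) {
    n <- as.integer(substr(op, 1L, nchar(op) - 1L))
    type <- substr(op, nchar(op), nchar(op))
    if (type == "M") {
      while (wi <= length(want) && positions[want[wi]] < s) wi <- wi + 1L
      while (wi <= length(want) && positions[want[wi]] < s + n) {
        off <- positions[want[wi]] - s
        res[want[wi]] <- substr(seq, q + off, q + off)
        wi <- wi + 1L
      }
      q <- q + n; s <- s + n
    } else if (type == "I") {
      q <- q + n
    } else {
      while (wi <= length(want) && positions[want[wi]] < s + n) wi <- wi + 1L
      s <- s + n
    }
  }
  res
}

# allele matrix of a population at its discriminating sites: focal
# coordinates, one column per genome
discriminatingSites <- function(population) {
  focal <- focalGenome(population)
  refChars <- strsplit(as.character(genomeSeq(focal)), "", fixed = TRUE)[[1L]]
  gs <- genomes(population)
  muts <- lapply(gs, function(g) {
    m <- mutations(g)
    m[m$type == "sub", , drop = FALSE]
  })
  sites <- sort(unique(unlist(lapply(muts, function(m) m$pos))))
  if (length(sites) == 0L)
    return(list(sites = integer(),
                alleles = matrix(character(), 0L, length(gs),
                                 dimnames = list(NULL, names(gs)))))
  alleles <- matrix(refChars[sites], nrow = length(sites),
                    ncol = length(gs), dimnames = list(NULL, names(gs)))
  for (gid in names(gs)) {
    m <- muts[[gid]]
    if (nrow(m) == 0L) next
    idx <- match(m$pos, sites)
    alleles[idx, gid] <- m$alt
  }
  list(sites = sites, alleles = alleles)
}

#' Evaluate contigs against a truth population
#'
#' Aligns contigs to every truth genome and reports (i) per-genome
#' recovery: the fraction of the genome covered by contig alignments at
#' or above `recoveryIdentityPct` identity, and (ii) a per-contig
#' allele table at the population's discriminating SNP sites (positions
#' where any member's mutation record differs from the focal genome),
#' from which consensus chimeras are flagged: a contig is chimeric when
#' it carries alleles from at least two distinct parents and no single
#' parent explains every informative site. Contigs aligning to no truth
#' genome are reported as unassigned.
#'
#' The recovery identity threshold is deliberately high (99\%) so that
#' a consensus collapsing distinct <= 95\%-ANI variants cannot count as
#' recovering the focal genome.
#'
#' @param contigs contigs ([Biostrings::DNAStringSet], character
#'   vector, or path to a FASTA file — external assembler output enters
#'   here).
#' @param population the truth [ViralPopulation-class] whose genomes
#'   carry mutation records.
#' @param recoveryIdentityPct identity threshold for recovery
#'   (default 99).
#' @param alignParams [AlignParams] for contig-genome alignment; the
#'   default widens the band to tolerate small assembly indels.
#' @return An [AssemblyReport-class].
#' @export
evaluateContigs <- function(contigs, population, recoveryIdentityPct = 99,
                            alignParams = virodiv::alignParams(bandPad = 32L)) {
  if (is.character(contigs) && length(contigs) == 1L &&
      file.exists(contigs) && !grepl("^[ACGTNacgtn]+$", contigs)) {
    contigs <- Biostrings::readDNAStringSet(contigs)
  }
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(toupper(contigs))
  if (is.null(names(contigs)) && length(contigs))
    names(contigs) <- sprintf("contig_%05d", seq_along(contigs))

  gs <- genomes(population)
  refs <- vapply(gs, as.character, character(1L))
  lens <- nchar(refs)
  disc <- discriminatingSites(population)

  recovery <- data.frame(genome_id = names(gs),
                         genome_length = as.integer(lens),
                         recovery_fraction = 0, stringsAsFactors = FALSE)
  summaryRows <- list()
  alleleRows <- list()

  if (length(contigs) > 0) {
    cc <- as.character(contigs)
    hits <- alignBatch(unname(cc), unname(refs), alignParams, fullDP = FALSE)
    hits$sseqid <- names(refs)[hits$sidx]
    # recovery per genome from high-identity intervals
    for (gi in seq_along(refs)) {
      h <- hits[hits$sidx == gi & hits$pident >= recoveryIdentityPct, ,
                drop = FALSE]
      if (nrow(h) == 0) next
      covered <- IRanges::reduce(IRanges::IRanges(h$sstart, h$send))
      recovery$recovery_fraction[gi] <-
        sum(IRanges::width(covered)) / lens[gi]
    }
    # allele provenance from the alignment to the focal genome
    focalIdx <- match(focalId(population), names(refs))
    for (ci in seq_along(cc)) {
      chit <- hits[hits$qidx == ci, , drop = FALSE]
      cid <- names(contigs)[ci]
      if (nrow(chit) == 0) {
        summaryRows[[cid]] <- data.frame(
          contig_id = cid, length = nchar(cc[ci]), aligned = FALSE,
          chimeric = NA, n_sites = 0L, matching_parents = "",
          stringsAsFactors = FALSE)
        next
      }
      fhit <- chit[chit$sidx == focalIdx, , drop = FALSE]
      matching <- character()
      nSites <- 0L
      chim <- FALSE
      if (nrow(fhit) > 0 && length(disc$sites) > 0) {
        fbest <- fhit[which.max(fhit$score), , drop = FALSE]
        inSpan <- disc$sites >= fbest$sstart & disc$sites <= fbest$send
        sites <- disc$sites[inSpan]
        if (length(sites) > 0) {
          obs <- alignedBaseAt(cc[ci], fbest, sites)
          ok <- !is.na(obs)
          sites <- sites[ok]; obs <- obs[ok]
          if (length(sites) > 0) {
            alle <- disc$alleles[match(sites, disc$sites), , drop = FALSE]
            matchMat <- alle == obs        # sites x genomes
            informative <- rowSums(matchMat) > 0
            nSites <- sum(informative)
            if (nSites > 0) {
              consistent <- colSums(!matchMat[informative, , drop = FALSE]) == 0
              matching <- names(gs)[consistent]
              chim <- nSites >= 2L && !any(consistent)
            }
            alleleRows[[cid]] <- data.frame(
              contig_id = cid, position = sites, allele = obs,
              parents = apply(matchMat, 1L, function(r)
                paste(names(gs)[r], collapse = ",")),
              stringsAsFactors = FALSE)
          }
        }
      }
      summaryRows[[cid]] <- data.frame(
        contig_id = cid, length = nchar(cc[ci]), aligned = TRUE,
        chimeric = chim, n_sites = nSites,
        matching_parents = paste(matching, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }

  contigSummary <- if (length(summaryRows)) do.call(rbind, summaryRows) else
    data.frame(contig_id = character(), length = integer(),
               aligned = logical(), chimeric = logical(),
               n_sites = integer(), matching_parents = character(),
               stringsAsFactors = FALSE)
  rownames(contigSummary) <- NULL
  alleleTable <- if (length(alleleRows)) do.call(rbind, alleleRows) else
    data.frame(contig_id = character(), position = integer(),
               allele = character(), parents = character(),
               stringsAsFactors = FALSE)
  rownames(alleleTable) <- NULL

  new("AssemblyReport", recovery = recovery, contigSummary = contigSummary,
      alleleTable = alleleTable,
      recoveryIdentityPct = recoveryIdentityPct,
      nContigs = length(contigs))
}
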