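#' @include classes-methods.R
NULL

# shared wrapper around the compiled aligner; queries/subjects are
# character vectors, ids are attached afterwards
alignBatch <- function(queries, subjects, params, fullDP = FALSE) {
  df <- cpp_align_batch(queries, subjects,
                        params@matchScore, params@mismatchPenalty,
                        params@gapOpen, params@gapExtend,
                        params@minAlnScore, params@minAlnLength,
                        params@seedK, params@bandPad, fullDP)
  qlen <- nchar(queries)[df$qidx]
  df$pident <- ifelse(df$length > 0, 100 * df$matches / df$length, 0)
  df$qcovs <- 100 * (df$qend - df$qstart + 1) / qlen
  df
}

# attach ids and order the standard 12 + extras hit-table columns
asHitTable <- function(df, queryIds, subjectIds) {
  out <- data.frame(
    qseqid = queryIds[df$qidx], sseqid = subjectIds[df$sidx],
    pident = df$pident, length = df$length, mismatch = df$mismatch,
    gapopen = df$gapopen, qstart = df$qstart, qend = df$qend,
    sstart = df$sstart, send = df$send, score = df$score,
    qcovs = df$qcovs, strand = df$strand, cigar = df$cigar,
    matches = df$matches, gapcols = df$gapcols,
    stringsAsFactors = FALSE)
  out[order(-out$score, out$qseqid, out$sseqid, out$sstart), , drop = FALSE]
}

#' Local alignment of two nucleotide sequences
#'
#' Smith-Waterman local alignment with affine gaps; the BLAST-style
#' search primitive used throughout the package. Small problems are
#' solved by exhaustive dynamic programming; larger ones by
#' seed-and-extend with a banded matrix (`method = "auto"`). Both
#' strands are searched; reverse-strand hits are reported with
#' `strand == "-"` and subject coordinates on the forward strand.
#' Alignments below `minAlnScore` or `minAlnLength` are suppressed.
#' `N` never counts as a match.
#'
#' @param query,subject sequences (character, [Biostrings::DNAString]
#'   or [Genome-class]).
#' @param params an [AlignParams] object.
#' @param method "auto", "full" (exhaustive DP) or "seed".
#' @return A hit-table data.frame (BLAST tabular dialect: qseqid,
#'   sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#'   send, score, qcovs, plus strand, cigar, matches, gapcols), sorted
#'   by descending score. Zero rows when nothing aligns.
#' @examples
#' alignLocal("ACGTACGTACGTACGTACGTACGTACGTACGT",
#'            "ACGTACGTACGTACGTACGTACGTACGTACGT", alignParams(minAlnScore = 10))
#' @export
alignLocal <- function(query, subject, params = alignParams(),
                       method = c("auto", "full", "seed")) {
  method <- match.arg(method)
  q <- toupper(seqChar(query))
  s <- toupper(seqChar(subject))
  checkNucleotides(q, "query")
  checkNucleotides(s, "subject")
  full <- switch(method, full = TRUE, seed = FALSE,
                 auto = (as.numeric(nchar(q)) * nchar(s) <= 4e6))
  df <- alignBatch(q, s, params, fullDP = full)
  asHitTable(df, seqId(query, "query"), seqId(subject, "subject"))
}

# One direction of fragment ANI: tile `a`, align to `b`. The identity
# a fragment contributes is computed over the whole fragment span:
# unaligned fragment ends count as non-identity columns. A raw local
# alignment trims diverged ends, which biases fragment identity upward
# at high divergence; whole-span identity keeps the statistic linear
# in the substitution rate.
aniOneWay <- function(aChar, bChar, params) {
  fs <- params@fragmentSize
  starts <- seq.int(1L, nchar(aChar) - fs + 1L, by = params@stepSize)
  frags <- substring(aChar, starts, starts + fs - 1L)
  df <- alignBatch(frags, bChar, params@align, fullDP = FALSE)
  idents <- rep(NA_real_, length(frags))
  if (nrow(df) > 0) {
    # best hit per fragment across strands
    df <- df[order(df$qidx, -df$score, df$strand, df$sstart), , drop = FALSE]
    best <- df[!duplicated(df$qidx), , drop = FALSE]
    qspan <- best$qend - best$qstart + 1
    cov <- 100 * qspan / fs
    ok <- cov >= params@minFragmentCoveragePct
    fragIdent <- 100 * best$matches / (best$length + fs - qspan)
    idents[best$qidx[ok]] <- fragIdent[ok]
  }
  list(identities = idents[!is.na(idents)],
       alignedFraction = mean(!is.na(idents)))
}

#' Fragment-based average nucleotide identity
#'
#' Tiles the first genome into fragments (default 100 bp every 50 bp),
#' aligns each fragment locally to the second genome, and averages the
#' best-hit identities of fragments whose best alignment covers at
#' least `minFragmentCoveragePct` of the fragment. Fragments without an
#' accepted hit are excluded from the mean but reported through the
#' aligned fraction. In symmetric mode (the default) the two
#' directional ANIs are averaged.
#'
#' @param genomeA,genomeB sequences ([Genome-class], DNAString or
#'   character), both at least `fragmentSize` long.
#' @param params an [AniParams] object.
#' @param symmetric average both directions (default TRUE).
#' @return An [AniResult-class] object.
#' @examples
#' g <- generateReference(2000, 0.45, seed = 1)
#' aniPct(fragmentANI(g, g))   # 100
#' @export
fragmentANI <- function(genomeA, genomeB, params = aniParams(),
                        symmetric = TRUE) {
  a <- toupper(seqChar(genomeA))
  b <- toupper(seqChar(genomeB))
  if (nchar(a) < params@fragmentSize || nchar(b) < params@fragmentSize)
    stop("genome shorter than fragmentSize (", params@fragmentSize, " bp)")
  fwd <- aniOneWay(a, b, params)
  if (!symmetric) {
    return(new("AniResult",
               aniPct = if (length(fwd$identities)) mean(fwd$identities)
                        else NA_real_,
               alignedFraction = fwd$alignedFraction,
               perFragmentIdentities = fwd$identities, symmetric = FALSE))
  }
  rev <- aniOneWay(b, a, params)
  aniF <- if (length(fwd$identities)) mean(fwd$identities) else NA_real_
  aniR <- if (length(rev$identities)) mean(rev$identities) else NA_real_
  new("AniResult",
      aniPct = mean(c(aniF, aniR), na.rm = FALSE),
      alignedFraction = mean(c(fwd$alignedFraction, rev$alignedFraction)),
      perFragmentIdentities = c(fwd$identities, rev$identities),
      symmetric = TRUE)
}

#' Differences between two related genomes
#'
#' Globally compares two genomes and reports their differences as a
#' substitution/insertion/deletion table with 1-based positions on the
#' first genome. Equal-length genomes are compared position by
#' position after confirming global alignability; unequal lengths go
#' through a global alignment ([Biostrings::pairwiseAlignment]).
#' Insertions are bases present only in `genomeB`, recorded at the
#' position on `genomeA` after which they occur.
#'
#' @param genomeA,genomeB the two genomes ([Genome-class], DNAString
#'   or character).
#' @param params [AniParams] used for the alignability pre-check
#'   (aligned fraction must reach `minAlignedFraction`).
#' @param minAlignedFraction alignability threshold (default 0.5).
#' @return data.frame with columns pos, ref, alt, type
#'   ("sub", "ins", "del").
#' @examples
#' genomeDiff("ACGTACGTACGTACGTACGTACGT", "ACGTACGTACGAACGTACGTACGT",
#'            params = aniParams(fragmentSize = 20L, stepSize = 10L))
#' @export
genomeDiff <- function(genomeA, genomeB, params = aniParams(),
                       minAlignedFraction = 0.5) {
  a <- toupper(seqChar(genomeA))
  b <- toupper(seqChar(genomeB))
  checkNucleotides(a, "genomeA", allow_n = FALSE)
  checkNucleotides(b, "genomeB", allow_n = FALSE)
  if (identical(a, b)) return(emptyMutationTable())

  if (nchar(a) == nchar(b)) {
    av <- strsplit(a, "", fixed = TRUE)[[1L]]
    bv <- strsplit(b, "", fixed = TRUE)[[1L]]
    same <- av == bv
    if (mean(same) >= minAlignedFraction) {
      i <- which(!same)
      return(data.frame(pos = i, ref = av[i], alt = bv[i], type = "sub",
                        stringsAsFactors = FALSE))
    }
  }
  # alignability gate for the general (indel) path
  if (nchar(a) >= params@fragmentSize && nchar(b) >= params@fragmentSize) {
    af <- alignedFraction(fragmentANI(a, b, params, symmetric = TRUE))
    if (is.na(af) || af < minAlignedFraction)
      stop("genomes are too divergent to compare (aligned fraction ",
           signif(af, 3), " < ", minAlignedFraction, ")")
  }
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  out <- emptyMutationTable()
  apos <- 0L
  k <- 1L
  n <- length(pat)
  while (k <= n) {
    pc <- pat[k]; sc <- sub[k]
    if (pc != "-" && sc != "-") {
      apos <- apos + 1L
      if (pc != sc)
        out <- rbind(out, data.frame(pos = apos, ref = pc, alt = sc,
                                     type = "sub"))
      k <- k + 1L
    } else if (pc == "-") {          # insertion relative to genomeA
      j <- k
      while (j <= n && pat[j] == "-") j <- j + 1L
      out <- rbind(out, data.frame(
        pos = apos, ref = "",
        alt = paste(sub[k:(j - 1L)], collapse = ""), type = "ins"))
      k <- j
    } else {                          # deletion: bases of A absent in B
      j <- k
      while (j <= n && sub[j] == "-") j <- j + 1L
      out <- rbind(out, data.frame(
        pos = apos + 1L, ref = paste(pat[k:(j - 1L)], collapse = ""),
        alt = "", type = "del"))
      apos <- apos + (j - k)
      k <- j
    }
  }
  rownames(out) <- NULL
  out
}
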