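#' @include recruit.R
NULL

#' Build a pileup from recruited alignments
#'
#' Accumulates per-position allele counts on one reference from a hit
#' table. Only alignments at or above `minMapIdentityPct` identity and
#' `minReadCoveragePct` query coverage contribute; gap columns
#' contribute nothing. The mapped-base total (aligned read bases of
#' contributing hits) is stored for the SNP-frequency normalization.
#'
#' @param hits hit table from [recruitReads] (or [alignLocal]).
#' @param reads the read set the hits refer to ([ReadSet-class],
#'   [Biostrings::DNAStringSet] or named character).
#' @param reference the reference [Genome-class].
#' @param params a [PileupParams] object.
#' @return A [Pileup-class].
#' @export
buildPileup <- function(hits, reads, reference, params = pileupParams()) {
  stopifnot(is(reference, "Genome"))
  rd <- readsAsChar(reads)
  h <- hits[hits$sseqid == genomeId(reference) &
              hits$pident >= params@minMapIdentityPct &
              hits$qcovs >= params@minReadCoveragePct, , drop = FALSE]
  missing <- setdiff(h$qseqid, names(rd))
  if (length(missing))
    stop("hits reference reads absent from the read set: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  L <- length(reference)
  counts <- if (nrow(h) == 0) {
    matrix(0L, nrow = 4L, ncol = L)
  } else {
    cpp_pileup(L, unname(rd[h$qseqid]), h$qstart, h$qend, h$sstart,
               h$strand, h$cigar)
  }
  rownames(counts) <- c("A", "C", "G", "T")
  new("Pileup", counts = counts, refId = genomeId(reference),
      refSeq = genomeSeq(reference),
      mappedBases = sum(h$qend - h$qstart + 1),
      nReads = length(unique(h$qseqid)), params = params)
}

#' Binomial SNP calling on a pileup
#'
#' At each site the most frequent non-reference allele is tested
#' against a Binomial(depth, errorRate) sequencing-error null; the
#' p-value is the exact upper tail at the observed alternative count.
#' A site is called when depth >= `minCoverage` and p < `maxP`.
#'
#' @param pileup a [Pileup-class].
#' @param params a [SnpCallerParams] object.
#' @param allSites return every covered site (default: only sites with
#'   a non-reference allele observed).
#' @return data.frame: position, depth, A, C, G, T, ref_base, alt_base,
#'   alt_count, p_value, is_snp.
#' @export
callSNPs <- function(pileup, params = snpCallerParams(),
                     allSites = FALSE) {
  if (params@errorRate <= 0 || params@errorRate >= 0.5)
    stop("errorRate must be in (0, 0.5)")
  counts <- alleleCounts(pileup)
  depth <- colSums(counts)
  refChars <- strsplit(as.character(pileup@refSeq), "", fixed = TRUE)[[1L]]
  refIdx <- match(refChars, c("A", "C", "G", "T"))
  L <- ncol(counts)
  altCounts <- counts
  altCounts[cbind(refIdx, seq_len(L))] <- -1L   # mask the reference row
  altIdx <- max.col(t(altCounts), ties.method = "first")
  altCount <- altCounts[cbind(altIdx, seq_len(L))]
  altCount[altCount < 0L] <- 0L
  pval <- stats::pbinom(altCount - 1, depth, params@errorRate,
                        lower.tail = FALSE)
  isSnp <- depth >= params@minCoverage & altCount > 0L & pval < params@maxP
  out <- data.frame(
    position = seq_len(L), depth = as.integer(depth),
    A = counts["A", ], C = counts["C", ], G = counts["G", ],
    T = counts["T", ], ref_base = refChars,
    alt_base = c("A", "C", "G", "T")[altIdx],
    alt_count = as.integer(altCount), p_value = pval, is_snp = isSnp,
    stringsAsFactors = FALSE)
  if (!allSites) out <- out[out$alt_count > 0L & out$depth > 0L, ,
                            drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalized SNP frequency
#'
#' Number of SNPs per kb of effective mapped genome (positions at or
#' above the minimum calling depth) per Mb of mapped read bases.
#'
#' @param calls output of [callSNPs].
#' @param pileup the [Pileup-class] the calls came from.
#' @param mappedReadBases override for the mapped-base total (default:
#'   taken from the pileup).
#' @param params the [SnpCallerParams] (for the effective-depth floor).
#' @return one-row data.frame: n_snps, effective_kb, mapped_mb,
#'   frequency.
#' @export
snpFrequency <- function(calls, pileup, mappedReadBases = NULL,
                         params = snpCallerParams()) {
  mapped <- mappedReadBases %||% mappedBases(pileup)
  if (mapped <= 0) stop("mapped read bases must be > 0")
  effectiveKb <- sum(siteDepth(pileup) >= params@minCoverage) / 1000
  if (effectiveKb == 0)
    stop("no positions at the minimum coverage; SNP frequency undefined")
  nSnps <- sum(calls$is_snp)
  mappedMb <- mapped / 1e6
  data.frame(n_snps = nSnps, effective_kb = effectiveKb,
             mapped_mb = mappedMb,
             frequency = nSnps / effectiveKb / mappedMb)
}

#' Write called SNPs as VCF v4.2
#'
#' Emits one record per called SNP with QUAL = -10 log10(p) and INFO
#' fields DP (depth) and AD (ref,alt allele depths).
#'
#' @param calls output of [callSNPs].
#' @param refId reference sequence name for the CHROM column.
#' @param file output path.
#' @param refLength reference length for the contig header line.
#' @return the file path, invisibly.
#' @export
writeSnpVcf <- function(calls, refId, file, refLength = NA_integer_) {
  snps <- calls[calls$is_snp, , drop = FALSE]
  qual <- ifelse(snps$p_value <= 0, 9999,
                 pmin(9999, -10 * log10(snps$p_value)))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=virodiv",
           if (!is.na(refLength))
             sprintf("##contig=<ID=%s,length=%d>", refId, refLength),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=AD,Number=2,Type=Integer,Description=\"Ref,alt allele depths\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  refDepth <- as.integer(mapply(function(i, b) snps[[b]][i],
                                seq_len(nrow(snps)), snps$ref_base))
  body <- if (nrow(snps) == 0) character() else sprintf(
    "%s\t%d\t.\t%s\t%s\t%.2f\tPASS\tDP=%d;AD=%d,%d",
    refId, snps$position, snps$ref_base, snps$alt_base, qual,
    snps$depth, refDepth, snps$alt_count)
  writeLines(c(hdr, body), file)
  invisible(file)
}
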