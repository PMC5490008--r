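#' @include readsim.R
NULL

# coerce the accepted reference carriers to a named character vector
refsAsChar <- function(references) {
  if (is(references, "ViralPopulation")) {
    gs <- genomes(references)
    return(stats::setNames(vapply(gs, as.character, character(1L)),
                           names(gs)))
  }
  if (is(references, "Genome"))
    return(stats::setNames(as.character(references), genomeId(references)))
  if (is.list(references)) {
    ids <- vapply(references, genomeId, character(1L))
    return(stats::setNames(vapply(references, as.character, character(1L)),
                           ids))
  }
  if (is(references, "DNAStringSet")) {
    x <- as.character(references)
    if (is.null(names(x))) names(x) <- sprintf("ref%d", seq_along(x))
    return(x)
  }
  if (is.character(references)) {
    if (is.null(names(references)))
      names(references) <- sprintf("ref%d", seq_along(references))
    return(toupper(references))
  }
  stop("unsupported reference container: ", class(references)[1L])
}

readsAsChar <- function(reads) {
  if (is(reads, "ReadSet")) reads <- readSequences(reads)
  if (is(reads, "DNAStringSet")) {
    x <- as.character(reads)
    if (is.null(names(x))) names(x) <- sprintf("read%d", seq_along(x))
    return(x)
  }
  if (is.character(reads)) {
    if (is.null(names(reads)))
      names(reads) <- sprintf("read%d", seq_along(reads))
    return(toupper(reads))
  }
  stop("unsupported read container: ", class(reads)[1L])
}

#' Recruit reads against a set of reference genomes
#'
#' Aligns every read (as a single end, both strands) against every
#' reference with the seed-and-extend local aligner, then applies the
#' recruitment filters: identity floor `minIdentityPct`, and removal of
#' hits with query coverage below `minQcovPct`. Assignment modes:
#' `"all"` keeps every passing hit; `"best_hit"` keeps, per read, the
#' single highest-scoring hit (ties broken by genome id, then subject
#' start); `"reciprocal_best_hit"` likewise assigns each read to its
#' single best genome and is operationally identical to best-hit
#' assignment here, since reads are the only query side.
#'
#' @param reads a [ReadSet-class], [Biostrings::DNAStringSet] or named
#'   character vector.
#' @param references a [ViralPopulation-class], list of
#'   [Genome-class], [Biostrings::DNAStringSet] or named character.
#' @param params a [RecruitParams] object.
#' @return A hit-table data.frame (see [alignLocal] for columns).
#' @export
recruitReads <- function(reads, references, params = recruitParams()) {
  refs <- refsAsChar(references)
  if (length(refs) == 0L) stop("reference set is empty")
  rd <- readsAsChar(reads)
  if (length(rd) == 0L)
    return(asHitTable(alignBatch(character(), refs, params@align),
                      character(), names(refs)))

  df <- alignBatch(unname(rd), unname(refs), params@align, fullDP = FALSE)
  df <- df[df$pident >= params@minIdentityPct &
             df$qcovs >= params@minQcovPct, , drop = FALSE]

  if (params@assignmentMode %in% c("best_hit", "reciprocal_best_hit") &&
      nrow(df) > 0) {
    ord <- order(df$qidx, -df$score, names(refs)[df$sidx], df$strand,
                 df$sstart)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df$qidx), , drop = FALSE]
  }
  asHitTable(df, names(rd), names(refs))
}

#' KPKG recruitment statistic per genome
#'
#' Normalized abundance: kilobases of reads recruited per kilobase of
#' genome per gigabase of metagenome. The recruited quantity is the
#' aligned query span (qend - qstart + 1) summed over retained hits at
#' or above the identity cutoff.
#'
#' @param hits hit table from [recruitReads].
#' @param genomeLengths named integer vector of genome lengths (bp);
#'   every genome gets a row, recruiting or not.
#' @param metagenomeBases total metagenome size in bases (> 0).
#' @param identityCutoffPct identity cutoff (e.g. 95 for species level,
#'   70 for genus level).
#' @return data.frame: genome_id, identity_cutoff_pct, recruited_kb,
#'   genome_kb, metagenome_gb, kpkg, n_reads.
#' @examples
#' hits <- data.frame(qseqid = "r1", sseqid = "g", pident = 100,
#'                    qstart = 1, qend = 200)
#' computeKPKG(hits, c(g = 10000), 1e6, 95)$kpkg   # 0.2/10/0.001 = 20
#' @export
computeKPKG <- function(hits, genomeLengths, metagenomeBases,
                        identityCutoffPct) {
  if (metagenomeBases <= 0) stop("metagenomeBases must be > 0")
  if (nrow(hits) > 0 && !all(hits$sseqid %in% names(genomeLengths)))
    stop("hit table references genomes absent from genomeLengths: ",
         paste(setdiff(unique(hits$sseqid), names(genomeLengths)),
               collapse = ", "))
  gb <- metagenomeBases / 1e9
  keep <- hits[hits$pident >= identityCutoffPct, , drop = FALSE]
  res <- lapply(names(genomeLengths), function(g) {
    h <- keep[keep$sseqid == g, , drop = FALSE]
    recruitedKb <- sum(h$qend - h$qstart + 1) / 1000
    genomeKb <- genomeLengths[[g]] / 1000
    data.frame(genome_id = g, identity_cutoff_pct = identityCutoffPct,
               recruited_kb = recruitedKb, genome_kb = genomeKb,
               metagenome_gb = gb, kpkg = recruitedKb / genomeKb / gb,
               n_reads = length(unique(h$qseqid)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Relative recruitment shares
#'
#' Normalizes mean KPKG values of genome sets by their sum, giving the
#' relative recruitment share of each set.
#'
#' @param meanKpkg named numeric vector of mean KPKG per genome set.
#' @return named numeric shares summing to 1.
#' @examples
#' relativeRecruitment(c(a = 2, b = 1, c = 1))
#' @export
relativeRecruitment <- function(meanKpkg) {
  if (all(meanKpkg == 0)) stop("all means are zero; shares undefined")
  if (any(meanKpkg < 0)) stop("means must be >= 0")
  meanKpkg / sum(meanKpkg)
}

#' Identity diversity curve for one genome
#'
#' Distribution of recruited-read percent identities against one
#' reference: the fraction of retained hits falling in each identity
#' bin. Broad low-identity mass signals a microdiverse population.
#' Bins are half-open \code{[low, high)} except the last, which is
#' closed; hits outside the bin range are counted in the terminal bins
#' with a warning.
#'
#' @param hits hit table from [recruitReads].
#' @param genomeId reference genome id.
#' @param binEdges strictly increasing numeric bin edges (default
#'   1-point bins from 70 to 100).
#' @return data.frame: genome_id, bin_low, bin_high, n_reads,
#'   pct_reads (summing to 100 when any read is recruited).
#' @export
diversityCurve <- function(hits, genomeId, binEdges = seq(70, 100, by = 1)) {
  if (any(diff(binEdges) <= 0)) stop("binEdges must be strictly increasing")
  h <- hits[hits$sseqid == genomeId, , drop = FALSE]
  nb <- length(binEdges) - 1L
  lo <- binEdges[-length(binEdges)]
  hi <- binEdges[-1L]
  p <- h$pident
  if (length(p) && (any(p < binEdges[1L]) || any(p > binEdges[length(binEdges)])))
    warning("hit identities outside the bin range; counted in terminal bins")
  p <- pmin(pmax(p, binEdges[1L]), binEdges[length(binEdges)])
  idx <- findInterval(p, binEdges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  pct <- if (sum(counts) > 0) 100 * counts / sum(counts) else rep(0, nb)
  data.frame(genome_id = genomeId, bin_low = lo, bin_high = hi,
             n_reads = counts, pct_reads = pct, stringsAsFactors = FALSE)
}
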