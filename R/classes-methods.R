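#' @include AllClasses.R AllGenerics.R
NULL

## ---- constructors ----------------------------------------------------------

#' Construct a Genome
#'
#' @param id genome identifier.
#' @param seq nucleotide sequence (character or
#'   [Biostrings::DNAString]); alphabet \code{A,C,G,T}.
#' @param parentId optional id of the parent genome.
#' @param mutations data.frame of differences relative to the parent
#'   (columns pos, ref, alt, type).
#' @param islands [IRanges::IRanges] of hypervariable islands; a
#'   metadata column \code{divergence} gives the island substitution rate.
#' @return A [Genome-class] object.
#' @examples
#' g <- Genome("g1", "ACGTACGTACGT")
#' genomeId(g)
#' @export
Genome <- function(id, seq, parentId = NA_character_,
                   mutations = emptyMutationTable(),
                   islands = IRanges::IRanges()) {
  if (is.character(seq)) {
    checkNucleotides(seq, what = sprintf("genome '%s'", id), allow_n = FALSE)
    seq <- Biostrings::DNAString(toupper(seq))
  }
  new("Genome", id = as.character(id), seq = seq,
      parentId = as.character(parentId), mutations = mutations,
      islands = islands)
}

#' Construct a ViralPopulation
#'
#' @param genomes list of [Genome-class] objects.
#' @param abundances relative abundances (default uniform); recycled
#'   names are taken from the genomes.
#' @param focalId id of the focal genome (default: first genome).
#' @param scenario scenario label.
#' @return A [ViralPopulation-class] object.
#' @export
ViralPopulation <- function(genomes, abundances = NULL, focalId = NULL,
                            scenario = "custom") {
  ids <- vapply(genomes, genomeId, character(1L))
  names(genomes) <- ids
  if (is.null(abundances)) abundances <- rep(1 / length(genomes),
                                             length(genomes))
  if (is.null(names(abundances))) names(abundances) <- ids
  abundances <- abundances / sum(abundances)
  new("ViralPopulation", genomes = genomes, abundances = abundances,
      focalId = focalId %||% ids[1L], scenario = scenario)
}

## ---- parameter constructors ------------------------------------------------

#' Parameter constructors
#'
#' Thin validated constructors for the parameter classes; see the class
#' documentation for slot meanings and defaults.
#'
#' @param matchScore,mismatchPenalty,gapOpen,gapExtend alignment scores.
#' @param minAlnScore,minAlnLength alignment report filters.
#' @param seedK,bandPad seed-and-extend heuristic controls.
#' @return A parameter object of the corresponding class.
#' @name params
#' @rdname params
#' @export
alignParams <- function(matchScore = 1L, mismatchPenalty = -2L,
                        gapOpen = -5L, gapExtend = -2L, minAlnScore = 20L,
                        minAlnLength = 30L, seedK = 11L, bandPad = 16L) {
  new("AlignParams", matchScore = as.integer(matchScore),
      mismatchPenalty = as.integer(mismatchPenalty),
      gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
      minAlnScore = as.integer(minAlnScore),
      minAlnLength = as.integer(minAlnLength), seedK = as.integer(seedK),
      bandPad = as.integer(bandPad))
}

#' @rdname params
#' @param fragmentSize,stepSize fragment tiling (bp).
#' @param minFragmentCoveragePct minimum fragment coverage percent.
#' @param align an [AlignParams] object.
#' @export
aniParams <- function(fragmentSize = 100L, stepSize = 50L,
                      minFragmentCoveragePct = 70, align = alignParams()) {
  new("AniParams", fragmentSize = as.integer(fragmentSize),
      stepSize = as.integer(stepSize),
      minFragmentCoveragePct = minFragmentCoveragePct, align = align)
}

#' @rdname params
#' @param minIdentityPct,minQcovPct,assignmentMode,speciesCutoffPct,genusCutoffPct
#'   recruitment filters; see [RecruitParams-class].
#' @export
recruitParams <- function(minIdentityPct = 50, minQcovPct = 80,
                          assignmentMode = c("best_hit", "all",
                                             "reciprocal_best_hit"),
                          speciesCutoffPct = 95, genusCutoffPct = 70,
                          align = alignParams()) {
  new("RecruitParams", minIdentityPct = minIdentityPct,
      minQcovPct = minQcovPct, assignmentMode = match.arg(assignmentMode),
      speciesCutoffPct = speciesCutoffPct, genusCutoffPct = genusCutoffPct,
      align = align)
}

#' @rdname params
#' @param readLength,insertMean,insertSd,errorRate,nPairs,coverage read
#'   simulation settings; see [ReadSimParams-class].
#' @export
readSimParams <- function(readLength = 150L, insertMean = 300,
                          insertSd = 30, errorRate = 0.001,
                          nPairs = NA_integer_, coverage = NA_real_) {
  new("ReadSimParams", readLength = as.integer(readLength),
      insertMean = insertMean, insertSd = insertSd, errorRate = errorRate,
      nPairs = as.integer(nPairs), coverage = as.numeric(coverage))
}

#' @rdname params
#' @param minMapIdentityPct,minReadCoveragePct pileup mapping filters.
#' @export
pileupParams <- function(minMapIdentityPct = 95, minReadCoveragePct = 70) {
  new("PileupParams", minMapIdentityPct = minMapIdentityPct,
      minReadCoveragePct = minReadCoveragePct)
}

#' @rdname params
#' @param minCoverage,maxP binomial caller thresholds.
#' @export
snpCallerParams <- function(minCoverage = 5L, maxP = 1e-6,
                            errorRate = 0.01) {
  if (errorRate <= 0 || errorRate >= 0.5)
    stop("errorRate must be in (0, 0.5)")
  new("SnpCallerParams", minCoverage = as.integer(minCoverage),
      maxP = maxP, errorRate = errorRate)
}

#' @rdname params
#' @param k,minKmerCount,bubblePolicy assembler settings; see
#'   [AssemblyParams-class].
#' @export
assemblyParams <- function(k = 31L, minKmerCount = 2L,
                           bubblePolicy = c("pop", "keep")) {
  new("AssemblyParams", k = as.integer(k),
      minKmerCount = as.integer(minKmerCount),
      bubblePolicy = match.arg(bubblePolicy))
}

#' @rdname params
#' @param maxMissedCleavages,minPeptideLength digestion settings.
#' @export
digestParams <- function(maxMissedCleavages = 4L, minPeptideLength = 6L) {
  new("DigestParams", maxMissedCleavages = as.integer(maxMissedCleavages),
      minPeptideLength = as.integer(minPeptideLength))
}

#' @rdname params
#' @param dropFrequencyHz,eventRateHz,noiseRateHz sorter rates (per s).
#' @export
sorterParams <- function(dropFrequencyHz = 38700, eventRateHz = 50,
                         noiseRateHz = 20) {
  new("SorterParams", dropFrequencyHz = dropFrequencyHz,
      eventRateHz = eventRateHz, noiseRateHz = noiseRateHz)
}

## ---- accessors -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("genomeId", "Genome", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("genomeSeq", "Genome", function(x) x@seq)
#' @rdname accessors
#' @export
setMethod("parentId", "Genome", function(x) x@parentId)
#' @rdname accessors
#' @export
setMethod("mutations", "Genome", function(x) x@mutations)
#' @rdname accessors
#' @export
setMethod("islands", "Genome", function(x) x@islands)

#' @rdname accessors
#' @export
setMethod("length", "Genome", function(x) length(x@seq))

#' @rdname accessors
#' @param object a Genome
#' @export
setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome '%s': %d bp", object@id, length(object@seq)))
  if (!is.na(object@parentId))
    cat(sprintf(", parent '%s' (%d recorded mutations)", object@parentId,
                nrow(object@mutations)))
  if (length(object@islands) > 0)
    cat(sprintf(", %d island(s)", length(object@islands)))
  cat("\n")
})

setMethod("as.character", "Genome", function(x) as.character(x@seq))

#' @rdname accessors
#' @export
setMethod("genomes", "ViralPopulation", function(x) x@genomes)
#' @rdname accessors
#' @export
setMethod("abundances", "ViralPopulation", function(x) x@abundances)
#' @rdname accessors
#' @export
setMethod("focalId", "ViralPopulation", function(x) x@focalId)
#' @rdname accessors
#' @export
setMethod("focalGenome", "ViralPopulation",
          function(x) x@genomes[[x@focalId]])
#' @rdname accessors
#' @export
setMethod("length", "ViralPopulation", function(x) length(x@genomes))
#' @rdname accessors
#' @export
setMethod("names", "ViralPopulation", function(x) names(x@genomes))

setMethod("[[", "ViralPopulation", function(x, i) x@genomes[[i]])

#' @rdname accessors
#' @export
setMethod("show", "ViralPopulation", function(object) {
  cat(sprintf("ViralPopulation (scenario %s): %d genomes, focal '%s'\n",
              object@scenario, length(object@genomes), object@focalId))
  for (g in object@genomes) {
    cat(sprintf("  %-14s %6d bp  abundance %.3f\n", g@id, length(g@seq),
                object@abundances[[g@id]]))
  }
})

#' @rdname accessors
#' @export
setMethod("mate1", "ReadSet", function(x) x@mate1)
#' @rdname accessors
#' @export
setMethod("mate2", "ReadSet", function(x) x@mate2)
#' @rdname accessors
#' @export
setMethod("truthTable", "ReadSet", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("readSequences", "ReadSet", function(x) c(x@mate1, x@mate2))
#' @rdname accessors
#' @export
setMethod("length", "ReadSet", function(x) length(x@mate1))

#' @rdname accessors
#' @export
setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet: %d pairs (%d reads), %d source genomes\n",
              length(object@mate1), 2L * length(object@mate1),
              length(unique(object@truth$genome_id))))
})

#' @rdname accessors
#' @export
setMethod("alleleCounts", "Pileup", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("siteDepth", "Pileup", function(x) colSums(x@counts))
#' @rdname accessors
#' @export
setMethod("mappedBases", "Pileup", function(x) x@mappedBases)

#' @rdname accessors
#' @export
setMethod("show", "Pileup", function(object) {
  d <- colSums(object@counts)
  cat(sprintf(
    "Pileup on '%s' (%d bp): %d reads, %.2f Mb mapped, mean depth %.1fx\n",
    object@refId, ncol(object@counts), object@nReads,
    object@mappedBases / 1e6, mean(d)))
})

#' @rdname accessors
#' @export
setMethod("aniPct", "AniResult", function(x) x@aniPct)
#' @rdname accessors
#' @export
setMethod("alignedFraction", "AniResult", function(x) x@alignedFraction)

#' @rdname accessors
#' @export
setMethod("show", "AniResult", function(object) {
  cat(sprintf("AniResult: ANI %.2f%%, aligned fraction %.3f (%s)\n",
              object@aniPct, object@alignedFraction,
              if (object@symmetric) "symmetric" else "one-way"))
})

#' @rdname accessors
#' @export
setMethod("recoveryTable", "AssemblyReport", function(x) x@recovery)
#' @rdname accessors
#' @export
setMethod("contigSummary", "AssemblyReport", function(x) x@contigSummary)
#' @rdname accessors
#' @export
setMethod("alleleTable", "AssemblyReport", function(x) x@alleleTable)

#' @rdname accessors
#' @export
setMethod("show", "AssemblyReport", function(object) {
  cat(sprintf("AssemblyReport: %d contigs, %d chimeric (identity >= %g%%)\n",
              object@nContigs,
              sum(object@contigSummary$chimeric %in% TRUE),
              object@recoveryIdentityPct))
  print(object@recovery, row.names = FALSE)
})

#' @rdname accessors
#' @export
setMethod("show", "ScenarioPreset", function(object) {
  cat(sprintf("ScenarioPreset %s: %d genomes", object@name,
              object@nGenomes))
  if (!is.na(object@snpCount)) cat(sprintf(", %d SNPs", object@snpCount))
  if (!anyNA(object@aniRange))
    cat(sprintf(", ANI range [%g, %g]", object@aniRange[1L],
                object@aniRange[2L]))
  cat("\n")
})
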