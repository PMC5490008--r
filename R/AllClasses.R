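#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#' @importFrom IRanges IRanges
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

## ---- parameter classes -----------------------------------------------------

#' Alignment scoring and filtering parameters
#'
#' Scoring defaults are BLASTN-like (+1 match, -2 mismatch, affine gaps
#' -5/-2, a gap of length L costing \code{gapOpen + (L-1)*gapExtend}).
#' Instead of an e-value gate, alignments are filtered by a minimum raw
#' score and a minimum alignment length, which is deterministic and
#' independent of database size. \code{seedK} and \code{bandPad} control
#' the seed-and-extend heuristic (exact k-mer seeds, banded extension
#' around seeded diagonals).
#'
#' @slot matchScore integer, positive match reward.
#' @slot mismatchPenalty integer, non-positive.
#' @slot gapOpen integer, non-positive; cost of the first gapped column.
#' @slot gapExtend integer, non-positive; cost per additional gap column.
#' @slot minAlnScore integer, minimum raw score for a reported alignment.
#' @slot minAlnLength integer, minimum alignment length (columns).
#' @slot seedK integer, exact-seed k-mer size.
#' @slot bandPad integer, extension band half-width around seeded diagonals.
#' @exportClass AlignParams
setClass("AlignParams",
  representation(matchScore = "integer", mismatchPenalty = "integer",
                 gapOpen = "integer", gapExtend = "integer",
                 minAlnScore = "integer", minAlnLength = "integer",
                 seedK = "integer", bandPad = "integer"),
  prototype(matchScore = 1L, mismatchPenalty = -2L, gapOpen = -5L,
            gapExtend = -2L, minAlnScore = 20L, minAlnLength = 30L,
            seedK = 11L, bandPad = 16L),
  validity = function(object) {
    if (object@matchScore <= 0L) return("matchScore must be > 0")
    if (object@mismatchPenalty > 0L || object@gapOpen > 0L ||
        object@gapExtend > 0L) return("penalties must be <= 0")
    if (object@minAlnLength < 1L) return("minAlnLength must be >= 1")
    if (object@seedK < 4L || object@seedK > 31L)
      return("seedK must be in [4, 31]")
    TRUE
  })

#' Fragment-based ANI parameters
#'
#' Genomes are tiled into fragments of \code{fragmentSize} every
#' \code{stepSize} bases; fragments whose best local alignment covers at
#' least \code{minFragmentCoveragePct} of the fragment contribute their
#' identity to the ANI mean.
#'
#' @slot fragmentSize integer bp (default 100).
#' @slot stepSize integer bp (default 50).
#' @slot minFragmentCoveragePct numeric percent (default 70).
#' @slot align an [AlignParams] object used for per-fragment alignment.
#' @exportClass AniParams
setClass("AniParams",
  representation(fragmentSize = "integer", stepSize = "integer",
                 minFragmentCoveragePct = "numeric", align = "AlignParams"),
  prototype(fragmentSize = 100L, stepSize = 50L,
            minFragmentCoveragePct = 70),
  validity = function(object) {
    if (object@fragmentSize < 20L) return("fragmentSize must be >= 20")
    if (object@stepSize > object@fragmentSize)
      return("stepSize must be <= fragmentSize")
    if (object@stepSize < 1L) return("stepSize must be >= 1")
    TRUE
  })

#' Read recruitment parameters
#'
#' @slot minIdentityPct numeric, search identity floor (default 50).
#' @slot minQcovPct numeric, minimum query (read) coverage percent
#'   (default 80); hits below are removed.
#' @slot assignmentMode one of "all", "best_hit", "reciprocal_best_hit".
#' @slot speciesCutoffPct numeric, species-level identity cutoff (95).
#' @slot genusCutoffPct numeric, genus-level identity cutoff (70).
#' @slot align an [AlignParams] object.
#' @exportClass RecruitParams
setClass("RecruitParams",
  representation(minIdentityPct = "numeric", minQcovPct = "numeric",
                 assignmentMode = "character", speciesCutoffPct = "numeric",
                 genusCutoffPct = "numeric", align = "AlignParams"),
  prototype(minIdentityPct = 50, minQcovPct = 80,
            assignmentMode = "best_hit", speciesCutoffPct = 95,
            genusCutoffPct = 70),
  validity = function(object) {
    if (!object@assignmentMode %in%
          c("all", "best_hit", "reciprocal_best_hit"))
      return("assignmentMode must be all, best_hit or reciprocal_best_hit")
    if (object@minIdentityPct < 0 ||
        object@minIdentityPct > object@speciesCutoffPct ||
        object@speciesCutoffPct > 100)
      return("need 0 <= minIdentityPct <= speciesCutoffPct <= 100")
    TRUE
  })

#' Read simulation parameters
#'
#' Substitution-only error model, uniform along the read; constant 'I'
#' (Q40) quality strings. Exactly one of \code{nPairs} and
#' \code{coverage} must be set.
#'
#' @slot readLength integer bp (default 150).
#' @slot insertMean,insertSd numeric bp; inserts are drawn from a normal
#'   distribution and clamped to \code{[readLength, genome length]}.
#' @slot errorRate per-base substitution probability in \code{[0, 0.2]}.
#' @slot nPairs integer or NA.
#' @slot coverage numeric mean depth or NA.
#' @exportClass ReadSimParams
setClass("ReadSimParams",
  representation(readLength = "integer", insertMean = "numeric",
                 insertSd = "numeric", errorRate = "numeric",
                 nPairs = "integer", coverage = "numeric"),
  prototype(readLength = 150L, insertMean = 300, insertSd = 30,
            errorRate = 0.001, nPairs = NA_integer_, coverage = NA_real_),
  validity = function(object) {
    if (object@errorRate < 0 || object@errorRate > 0.2)
      return("errorRate must be in [0, 0.2]")
    if (object@insertMean < object@readLength)
      return("insertMean must be >= readLength")
    if (!is.na(object@nPairs) && !is.na(object@coverage))
      return("give either nPairs or coverage, not both")
    TRUE
  })

#' Pileup construction parameters
#'
#' Mapping filters applied before a read contributes to the pileup.
#'
#' @slot minMapIdentityPct numeric percent (default 95).
#' @slot minReadCoveragePct numeric percent (default 70).
#' @exportClass PileupParams
setClass("PileupParams",
  representation(minMapIdentityPct = "numeric",
                 minReadCoveragePct = "numeric"),
  prototype(minMapIdentityPct = 95, minReadCoveragePct = 70),
  validity = function(object) {
    p <- c(object@minMapIdentityPct, object@minReadCoveragePct)
    if (any(p < 0 | p > 100)) return("percentages must be in [0, 100]")
    TRUE
  })

#' Binomial SNP caller parameters
#'
#' @slot minCoverage integer minimum depth (default 5).
#' @slot maxP numeric p-value threshold (default 1e-6).
#' @slot errorRate numeric per-base sequencing error probability
#'   (default 0.01); the null model for the binomial tail.
#' @exportClass SnpCallerParams
setClass("SnpCallerParams",
  representation(minCoverage = "integer", maxP = "numeric",
                 errorRate = "numeric"),
  prototype(minCoverage = 5L, maxP = 1e-6, errorRate = 0.01),
  validity = function(object) {
    if (object@minCoverage < 1L) return("minCoverage must be >= 1")
    if (object@maxP <= 0 || object@maxP >= 1)
      return("maxP must be in (0, 1)")
    TRUE
  })

#' de Bruijn assembly parameters
#'
#' k-mers are packed two bits per base into 64-bit words, so \code{k}
#' is limited to odd values in \code{[15, 31]}.
#'
#' @slot k odd integer k-mer size (default 31).
#' @slot minKmerCount integer abundance floor (default 2).
#' @slot bubblePolicy "pop" or "keep".
#' @exportClass AssemblyParams
setClass("AssemblyParams",
  representation(k = "integer", minKmerCount = "integer",
                 bubblePolicy = "character"),
  prototype(k = 31L, minKmerCount = 2L, bubblePolicy = "pop"),
  validity = function(object) {
    if (object@k %% 2L == 0L || object@k < 15L || object@k > 31L)
      return("k must be odd and in [15, 31]")
    if (!object@bubblePolicy %in% c("pop", "keep"))
      return("bubblePolicy must be 'pop' or 'keep'")
    TRUE
  })

#' Tryptic digestion parameters
#'
#' @slot maxMissedCleavages integer in \code{[0, 10]} (default 4).
#' @slot minPeptideLength integer residues (default 6).
#' @exportClass DigestParams
setClass("DigestParams",
  representation(maxMissedCleavages = "integer",
                 minPeptideLength = "integer"),
  prototype(maxMissedCleavages = 4L, minPeptideLength = 6L),
  validity = function(object) {
    if (object@maxMissedCleavages < 0L || object@maxMissedCleavages > 10L)
      return("maxMissedCleavages must be in [0, 10]")
    TRUE
  })

#' Droplet sorter parameters
#'
#' @slot dropFrequencyHz drops generated per second.
#' @slot eventRateHz detected events per second.
#' @slot noiseRateHz electronic-noise events per second.
#' @exportClass SorterParams
setClass("SorterParams",
  representation(dropFrequencyHz = "numeric", eventRateHz = "numeric",
                 noiseRateHz = "numeric"),
  prototype(dropFrequencyHz = 38700, eventRateHz = 50, noiseRateHz = 20),
  validity = function(object) {
    if (any(c(object@dropFrequencyHz, object@eventRateHz,
              object@noiseRateHz) < 0)) return("rates must be >= 0")
    if (object@eventRateHz < object@noiseRateHz)
      return("eventRateHz must be >= noiseRateHz")
    TRUE
  })

## ---- data classes ----------------------------------------------------------

#' A nucleotide genome with provenance
#'
#' Holds the sequence together with the information needed to replay its
#' history: the parent it was derived from, the substitution/indel record
#' relative to that parent, and any annotated hypervariable islands.
#'
#' @slot id character genome identifier.
#' @slot seq a [Biostrings::DNAString].
#' @slot parentId character id of the parent genome, or NA.
#' @slot mutations data.frame with columns pos, ref, alt, type; positions
#'   are 1-based on the parent.
#' @slot islands an [IRanges::IRanges] of island coordinates; the
#'   divergence rate is kept in its metadata column \code{divergence}.
#' @exportClass Genome
setClass("Genome",
  representation(id = "character", seq = "DNAString", parentId = "character",
                 mutations = "data.frame", islands = "IRanges"),
  validity = function(object) {
    s <- as.character(object@seq)
    if (!nzchar(s)) return("empty sequence")
    if (grepl("[^ACGT]", s)) return("sequence alphabet must be {A,C,G,T}")
    if (length(object@islands) > 0 &&
        max(IRanges::end(object@islands)) > nchar(s))
      return("island end beyond genome length")
    TRUE
  })

#' A set of co-occurring genomes with relative abundances
#'
#' @slot genomes list of [Genome] objects.
#' @slot abundances numeric relative abundances, named by genome id,
#'   summing to 1.
#' @slot focalId id of the focal genome.
#' @slot scenario scenario label ("A", "B", "C" or free text).
#' @exportClass ViralPopulation
setClass("ViralPopulation",
  representation(genomes = "list", abundances = "numeric",
                 focalId = "character", scenario = "character"),
  validity = function(object) {
    ids <- unname(vapply(object@genomes, function(g) g@id, character(1L)))
    if (anyDuplicated(ids)) return("duplicated genome ids")
    if (length(object@abundances) != length(object@genomes))
      return("one abundance per genome required")
    if (!isTRUE(all.equal(sum(object@abundances), 1, tolerance = 1e-9)))
      return("abundances must sum to 1")
    if (any(object@abundances < 0)) return("abundances must be >= 0")
    if (!identical(sort(unname(names(object@abundances))), sort(ids)))
      return("abundance names must match genome ids")
    if (!object@focalId %in% ids) return("focalId not among genome ids")
    TRUE
  })

#' A simulated paired-end read set with per-read truth provenance
#'
#' @slot mate1,mate2 [Biostrings::DNAStringSet] of first/second mates,
#'   named by read id.
#' @slot truth data.frame with one row per read: read_id, mate,
#'   genome_id, start (1-based leftmost position on the source genome),
#'   strand and n_errors.
#' @exportClass ReadSet
setClass("ReadSet",
  representation(mate1 = "DNAStringSet", mate2 = "DNAStringSet",
                 truth = "data.frame"),
  validity = function(object) {
    if (length(object@mate1) != length(object@mate2))
      return("mate files must have equal length")
    if (nrow(object@truth) != 2L * length(object@mate1))
      return("truth table must have one row per read")
    TRUE
  })

#' Per-position allele counts against one reference
#'
#' @slot counts 4 x L integer matrix (rows A, C, G, T).
#' @slot refId reference genome id.
#' @slot refSeq reference [Biostrings::DNAString].
#' @slot mappedBases total aligned read bases contributing to the pileup.
#' @slot nReads number of contributing reads.
#' @slot params the [PileupParams] used.
#' @exportClass Pileup
setClass("Pileup",
  representation(counts = "matrix", refId = "character",
                 refSeq = "DNAString", mappedBases = "numeric",
                 nReads = "integer", params = "PileupParams"),
  validity = function(object) {
    if (nrow(object@counts) != 4L) return("counts must have 4 rows")
    if (ncol(object@counts) != length(object@refSeq))
      return("counts width must equal reference length")
    TRUE
  })

#' Provenance-aware assembly evaluation report
#'
#' @slot recovery data.frame: genome_id, genome_length,
#'   recovery_fraction (fraction of the truth genome covered by contig
#'   alignments at or above the recovery identity threshold).
#' @slot contigSummary data.frame: contig_id, length, chimeric,
#'   n_sites, matching_parents.
#' @slot alleleTable data.frame: per contig and discriminating site, the
#'   allele carried and the parent genomes consistent with it.
#' @slot recoveryIdentityPct identity threshold used for recovery.
#' @slot nContigs integer.
#' @exportClass AssemblyReport
setClass("AssemblyReport",
  representation(recovery = "data.frame", contigSummary = "data.frame",
                 alleleTable = "data.frame",
                 recoveryIdentityPct = "numeric", nContigs = "integer"))

#' Fragment-based ANI result
#'
#' @slot aniPct mean identity of accepted fragments (percent).
#' @slot alignedFraction fraction of fragments with an accepted best hit.
#' @slot perFragmentIdentities numeric vector of accepted-fragment
#'   identities (both directions concatenated in symmetric mode).
#' @slot symmetric logical; TRUE when both directions were averaged.
#' @exportClass AniResult
setClass("AniResult",
  representation(aniPct = "numeric", alignedFraction = "numeric",
                 perFragmentIdentities = "numeric", symmetric = "logical"))

#' Scenario preset for population construction
#'
#' Encodes the three study designs: A, two genomes differing by exactly
#' 20 SNPs (no microdiversity); B, five genomes at ANI >= 95\% vs the
#' focal genome without elevated island divergence; C, ten genomes with
#' ANI spread over 75-95\% vs the focal genome plus a hypervariable
#' island.
#'
#' @slot name "A", "B" or "C".
#' @slot nGenomes population size including the focal genome.
#' @slot snpCount SNP count for preset A (NA otherwise).
#' @slot aniRange numeric length-2 ANI range vs focal (NA for A).
#' @slot aniTargets per-variant calibration targets within the range.
#' @slot islandDivergence island substitution rate (preset C), NA else.
#' @slot abundances relative abundances, or NULL for uniform.
#' @exportClass ScenarioPreset
setClass("ScenarioPreset",
  representation(name = "character", nGenomes = "integer",
                 snpCount = "integer", aniRange = "numeric",
                 aniTargets = "numeric", islandDivergence = "numeric",
                 abundances = "numericOrNULL"))
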