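#' @include align.R
NULL

#' Generate a random reference genome
#'
#' Draws an i.i.d. nucleotide sequence at the requested GC content; the
#' synthetic stand-in for a focal phage genome.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc target GC fraction in \code{[0, 1]}; realized GC is within
#'   about 2 percentage points for genomes >= 5 kb.
#' @param seed integer seed; identical seeds give identical genomes.
#' @param id genome id (default "focal").
#' @return A [Genome-class] object.
#' @examples
#' g <- generateReference(15000, 0.40, seed = 7)
#' length(g)
#' @export
generateReference <- function(length, gc, seed, id = "focal") {
  if (length < 1000) stop("length must be >= 1,000 bp")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  seq <- withSeed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
  Genome(id, seq)
}

# draw substitutions at given positions; alternative base uniform over
# the other three
substituteAt <- function(chars, positions) {
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    alt <- sample(setdiff(bases, chars[p]), 1L)
    chars[p] <- alt
  }
  chars
}

# island coordinates for a focal genome: the annotated 9,000-9,700
# window of an ~18-kb genome, scaled proportionally when the genome is
# too short to hold it
defaultIsland <- function(genomeLength, divergence = 0.10) {
  if (genomeLength >= 9700L) {
    ir <- IRanges::IRanges(start = 9000L, end = 9700L)
  } else {
    ir <- IRanges::IRanges(start = max(1L, round(genomeLength * 9000 / 18000)),
                           end = max(2L, round(genomeLength * 9700 / 18000)))
  }
  S4Vectors::mcols(ir)$divergence <- divergence
  ir
}

islandPositions <- function(island) {
  if (is.null(island) || length(island) == 0L) return(integer())
  unlist(lapply(seq_along(island), function(i) {
    seq.int(IRanges::start(island)[i], IRanges::end(island)[i])
  }))
}

#' Introduce a fixed number of SNPs into a genome
#'
#' The child differs from the parent by exactly `nSnps` substitutions
#' at distinct uniformly drawn positions. When an island is supplied,
#' island positions are additionally substituted at the island's
#' divergence rate, and the `nSnps` background substitutions are drawn
#' outside the island. The full mutation record is stored on the child,
#' so the child can be replayed from the parent.
#'
#' @param parent a [Genome-class].
#' @param nSnps number of background substitutions (< parent length).
#' @param island optional [IRanges::IRanges] with metadata column
#'   `divergence`.
#' @param seed integer seed.
#' @param id child id (default parent id + "_v").
#' @return A [Genome-class] child.
#' @examples
#' p <- generateReference(2000, 0.5, seed = 1)
#' v <- mutateGenome(p, 20, seed = 2)
#' nrow(mutations(v))  # 20
#' @export
mutateGenome <- function(parent, nSnps, island = NULL, seed,
                         id = paste0(genomeId(parent), "_v")) {
  L <- length(parent)
  if (nSnps >= L) stop("nSnps must be smaller than the genome length")
  chars <- strsplit(as.character(genomeSeq(parent)), "", fixed = TRUE)[[1L]]
  ref <- chars
  chars <- withSeed(seed, {
    islPos <- islandPositions(island)
    bgPool <- if (length(islPos)) setdiff(seq_len(L), islPos) else seq_len(L)
    bgPos <- if (nSnps > 0) sample(bgPool, nSnps) else integer()
    chars <- substituteAt(chars, sort(bgPos))
    if (length(islPos)) {
      div <- S4Vectors::mcols(island)$divergence[1L]
      hit <- islPos[stats::runif(length(islPos)) < div]
      chars <- substituteAt(chars, sort(hit))
    }
    chars
  })
  changed <- which(chars != ref)
  muts <- if (length(changed) == 0L) emptyMutationTable() else
    data.frame(pos = changed, ref = ref[changed], alt = chars[changed],
               type = "sub", stringsAsFactors = FALSE)
  Genome(id, paste(chars, collapse = ""), parentId = genomeId(parent),
         mutations = muts,
         islands = if (is.null(island)) IRanges::IRanges() else island)
}

#' Replay a mutation record on a parent genome
#'
#' Reconstructs a child byte-for-byte from its parent and its recorded
#' substitution list.
#'
#' @param parent the parent [Genome-class].
#' @param child the child [Genome-class] carrying a mutation record.
#' @return The reconstructed sequence as a character string.
#' @export
replayMutations <- function(parent, child) {
  chars <- strsplit(as.character(genomeSeq(parent)), "", fixed = TRUE)[[1L]]
  m <- mutations(child)
  if (nrow(m) > 0) {
    if (any(m$type != "sub")) stop("only substitution records can be replayed")
    if (any(chars[m$pos] != m$ref)) stop("mutation record does not match parent")
    chars[m$pos] <- m$alt
  }
  paste(chars, collapse = "")
}

#' Evolve a genome to a target fragment-ANI
#'
#' Doses uniform substitutions (outside the island, when one is given)
#' and measures the result with [fragmentANI] until the measured ANI of
#' child vs parent is within `tolPct` of the target. Island positions
#' are substituted at the island divergence rate before calibration
#' starts. The measuring stick is the same fragment-based ANI statistic
#' used everywhere else in the package, so calibrated populations are
#' self-consistent under later re-measurement.
#'
#' @param parent a [Genome-class].
#' @param targetAniPct target ANI vs parent, in \code{[70, 100]}.
#' @param island optional island ([IRanges::IRanges] with `divergence`).
#' @param seed integer seed.
#' @param tolPct convergence tolerance in percentage points (default 1).
#' @param aniParams [AniParams] used for measurement.
#' @param maxIter calibration iteration cap (default 20).
#' @param id child id.
#' @return A [Genome-class] whose measured ANI vs parent is within
#'   `targetAniPct` plus/minus `tolPct`.
#' @export
evolveToANI <- function(parent, targetAniPct, island = NULL, seed,
                        tolPct = 1.0, aniParams = virodiv::aniParams(),
                        maxIter = 20L,
                        id = paste0(genomeId(parent), "_ani")) {
  if (targetAniPct < 70 || targetAniPct > 100)
    stop("targetAniPct must be in [70, 100]")
  if (targetAniPct == 100) {
    return(Genome(id, as.character(genomeSeq(parent)),
                  parentId = genomeId(parent)))
  }
  L <- length(parent)
  islPos <- islandPositions(island)
  nOut <- L - length(islPos)
  p <- (100 - targetAniPct) / 100
  for (iter in seq_len(maxIter)) {
    nSnps <- max(0L, min(nOut - 1L, round(p * nOut)))
    child <- mutateGenome(parent, nSnps, island = island,
                          seed = deriveSeed(seed, iter), id = id)
    measured <- aniPct(fragmentANI(child, parent, aniParams))
    if (!is.na(measured) && abs(measured - targetAniPct) <= tolPct)
      return(child)
    # proportional re-dosing on the divergence scale
    if (is.na(measured) || measured >= 100) {
      p <- p + 0.005
    } else {
      p <- p * (100 - targetAniPct) / (100 - measured)
    }
    p <- min(max(p, 0), 0.45)
  }
  stop("evolveToANI did not reach ", targetAniPct, "% within ", maxIter,
       " calibration iterations")
}

#' Scenario presets
#'
#' The three population designs: A, two genomes differing by exactly 20
#' substitutions; B, five genomes at ANI >= 95\% vs the focal genome
#' with no elevated island divergence; C, ten genomes with ANI vs focal
#' spread over \code{[75, 95]} and a hypervariable island at divergence
#' `islandDivergence`. Calibration targets are spaced evenly one
#' tolerance unit inside the stated range so a plus/minus 1 point
#' calibrated generator honors the hard bounds: B uses targets 96-99,
#' C uses nine targets from 76 to 94.
#'
#' @param name "A", "B" or "C".
#' @param islandDivergence island substitution rate for preset C
#'   (default 0.10).
#' @param abundances optional relative abundances (default uniform).
#' @return A [ScenarioPreset-class].
#' @examples
#' scenarioPreset("A")
#' @export
scenarioPreset <- function(name = c("A", "B", "C"), islandDivergence = 0.10,
                           abundances = NULL) {
  name <- match.arg(name)
  switch(name,
    A = new("ScenarioPreset", name = "A", nGenomes = 2L, snpCount = 20L,
            aniRange = c(NA_real_, NA_real_), aniTargets = numeric(),
            islandDivergence = NA_real_, abundances = abundances),
    B = new("ScenarioPreset", name = "B", nGenomes = 5L,
            snpCount = NA_integer_, aniRange = c(95, 100),
            aniTargets = c(96, 97, 98, 99),
            islandDivergence = NA_real_, abundances = abundances),
    C = new("ScenarioPreset", name = "C", nGenomes = 10L,
            snpCount = NA_integer_, aniRange = c(75, 95),
            aniTargets = seq(76, 94, length.out = 9L),
            islandDivergence = islandDivergence, abundances = abundances))
}

#' Build a scenario population around a focal genome
#'
#' Expands a [ScenarioPreset-class] into a [ViralPopulation-class]:
#' preset A adds one 20-SNP variant; preset B adds four variants
#' calibrated to ANI targets 96-99\% vs the focal genome; preset C adds
#' nine variants spread over 76-94\% ANI, each carrying elevated island
#' divergence. Abundances default to uniform.
#'
#' @param preset a [ScenarioPreset-class] (or preset name).
#' @param focal the focal [Genome-class].
#' @param seed integer seed.
#' @param aniParams [AniParams] for calibration measurement.
#' @param tolPct ANI calibration tolerance (default 1).
#' @return A [ViralPopulation-class].
#' @examples
#' \donttest{
#' focal <- generateReference(15000, 0.45, seed = 7)
#' popA <- buildScenario(scenarioPreset("A"), focal, seed = 7)
#' }
#' @export
buildScenario <- function(preset, focal, seed,
                          aniParams = virodiv::aniParams(), tolPct = 1.0) {
  if (is.character(preset)) preset <- scenarioPreset(preset)
  L <- length(focal)
  island <- NULL
  if (!is.na(preset@islandDivergence)) {
    island <- defaultIsland(L, preset@islandDivergence)
    if (max(IRanges::end(island)) > L)
      stop("focal genome too short for the island annotation")
  }

  gs <- list(focal)
  if (preset@name == "A") {
    gs[[2L]] <- mutateGenome(focal, preset@snpCount, island = NULL,
                             seed = deriveSeed(seed, 1L),
                             id = paste0(genomeId(focal), "_v1"))
  } else {
    for (i in seq_along(preset@aniTargets)) {
      gs[[i + 1L]] <- evolveToANI(
        focal, preset@aniTargets[i], island = island,
        seed = deriveSeed(seed, i), tolPct = tolPct, aniParams = aniParams,
        id = sprintf("%s_v%d", genomeId(focal), i))
    }
  }
  ab <- preset@abundances
  if (!is.null(ab) && length(ab) != length(gs))
    stop("preset abundances length does not match the population size")
  ViralPopulation(gs, abundances = ab, focalId = genomeId(focal),
                  scenario = preset@name)
}
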