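#' @include io.R
NULL

#' Scenario run configuration
#'
#' One object capturing every knob of the end-to-end scenario runner;
#' it is serialized verbatim into the run manifest, and one global seed
#' governs all stochastic stages (expanded into per-stage seeds by a
#' fixed derivation, recorded in the manifest).
#'
#' @slot preset scenario name ("A", "B" or "C").
#' @slot seed global integer seed.
#' @slot outDir output directory.
#' @slot focalLength,gc focal genome simulation parameters (used unless
#'   `focalFasta` is given).
#' @slot focalFasta optional FASTA path with the focal genome.
#' @slot nBackground,backgroundLengthRange,backgroundGc background
#'   community parameters.
#' @slot backgroundFraction fraction of read pairs from the background.
#' @slot islandDivergence island substitution rate for preset C.
#' @slot readSim a [ReadSimParams].
#' @slot recruit a [RecruitParams].
#' @slot pileup a [PileupParams].
#' @slot snp a [SnpCallerParams].
#' @slot assembly an [AssemblyParams].
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(preset = "character", seed = "integer",
                 outDir = "character", focalLength = "integer",
                 gc = "numeric", focalFasta = "characterOrNULL",
                 nBackground = "integer",
                 backgroundLengthRange = "integer",
                 backgroundGc = "numeric", backgroundFraction = "numeric",
                 islandDivergence = "numeric", readSim = "ReadSimParams",
                 recruit = "RecruitParams", pileup = "PileupParams",
                 snp = "SnpCallerParams", assembly = "AssemblyParams"))

#' @rdname ScenarioConfig-class
#' @param preset,seed,outDir,focalLength,gc,focalFasta,nBackground see
#'   the class slots.
#' @param backgroundLengthRange,backgroundGc,backgroundFraction see
#'   the class slots.
#' @param islandDivergence,readSim,recruit,pileup,snp,assembly see the
#'   class slots.
#' @return a ScenarioConfig object.
#' @export
scenarioConfig <- function(preset = c("A", "B", "C"), seed = 1L,
                           outDir = tempfile("scenario"),
                           focalLength = 15000L, gc = 0.45,
                           focalFasta = NULL, nBackground = 10L,
                           backgroundLengthRange = c(5000L, 20000L),
                           backgroundGc = 0.45,
                           backgroundFraction = 0.5,
                           islandDivergence = 0.10,
                           readSim = readSimParams(coverage = 50),
                           recruit = recruitParams(),
                           pileup = pileupParams(),
                           snp = snpCallerParams(),
                           assembly = assemblyParams()) {
  new("ScenarioConfig", preset = match.arg(preset), seed = as.integer(seed),
      outDir = outDir, focalLength = as.integer(focalLength), gc = gc,
      focalFasta = focalFasta, nBackground = as.integer(nBackground),
      backgroundLengthRange = as.integer(backgroundLengthRange),
      backgroundGc = backgroundGc,
      backgroundFraction = backgroundFraction,
      islandDivergence = islandDivergence, readSim = readSim,
      recruit = recruit, pileup = pileup, snp = snp, assembly = assembly)
}

paramsAsList <- function(p) {
  sn <- methods::slotNames(class(p))
  out <- lapply(sn, function(s) {
    v <- methods::slot(p, s)
    if (isS4(v)) paramsAsList(v) else v
  })
  names(out) <- sn
  out
}

#' Run an end-to-end microdiversity scenario
#'
#' Executes population construction, background generation, read
#' simulation, recruitment (KPKG at the species and genus cutoffs plus
#' the focal diversity curve), pileup + SNP calling + SNP frequency,
#' assembly and contig evaluation, writing every artifact under the
#' configured output directory and a JSON manifest listing each file
#' with its MD5 digest. Identical configurations produce identical
#' digests.
#'
#' @param config a [ScenarioConfig-class] from [scenarioConfig].
#' @param quiet suppress per-stage messages.
#' @return the manifest, invisibly (a list).
#' @export
runScenario <- function(config, quiet = FALSE) {
  t0 <- Sys.time()
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config@outDir, "run.log")
  stageSeeds <- vapply(1:5, function(i) deriveSeed(config@seed, i),
                       integer(1L))
  logLine <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, msg)
    cat(line, "\n", file = log, append = TRUE)
    if (!quiet) message(line)
  }
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## population
  logLine("popgen", sprintf("preset %s, seed %d", config@preset,
                            config@seed))
  pop <- runStage("popgen", {
    focal <- if (!is.null(config@focalFasta)) {
      fa <- Biostrings::readDNAStringSet(config@focalFasta)
      Genome(names(fa)[1L] %||% "focal", as.character(fa[[1L]]))
    } else {
      generateReference(config@focalLength, config@gc,
                        seed = stageSeeds[1L])
    }
    buildScenario(scenarioPreset(config@preset,
                                 islandDivergence = config@islandDivergence),
                  focal, seed = stageSeeds[1L])
  })
  popPaths <- writePopulation(pop, config@outDir)

  ## background + reads
  bg <- runStage("background", {
    makeBackground(config@nBackground, config@backgroundLengthRange,
                   config@backgroundGc, seed = stageSeeds[2L])
  })
  logLine("readsim", sprintf("%d background genomes", length(bg)))
  rs <- runStage("readsim", {
    simulateReads(pop, background = bg, params = config@readSim,
                  seed = stageSeeds[3L],
                  backgroundFraction = if (length(bg))
                    config@backgroundFraction else 0)
  })
  readPaths <- writeReadSet(rs, config@outDir)

  ## recruitment
  logLine("recruit", sprintf("%d reads vs %d genomes", 2L * length(rs),
                             length(pop)))
  hits <- runStage("recruit", recruitReads(rs, pop, config@recruit))
  hitPath <- file.path(config@outDir, "hits.tsv")
  writeHits(hits, hitPath)
  metagenomeBases <- sum(Biostrings::width(readSequences(rs)))
  gl <- vapply(genomes(pop), length, integer(1L))
  kpkg <- rbind(
    computeKPKG(hits, gl, metagenomeBases, config@recruit@speciesCutoffPct),
    computeKPKG(hits, gl, metagenomeBases, config@recruit@genusCutoffPct))
  kpkgPath <- file.path(config@outDir, "kpkg.tsv")
  utils::write.table(kpkg, kpkgPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  curve <- diversityCurve(hits, focalId(pop))
  curvePath <- file.path(config@outDir, "diversity_curve.tsv")
  utils::write.table(curve, curvePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## SNP statistics on the focal genome
  logLine("snpstat", "pileup + binomial calling on the focal genome")
  snpOut <- runStage("snpstat", {
    pu <- buildPileup(hits, rs, focalGenome(pop), config@pileup)
    calls <- callSNPs(pu, config@snp)
    freq <- if (any(siteDepth(pu) >= config@snp@minCoverage))
      snpFrequency(calls, pu, params = config@snp)
    else data.frame(n_snps = 0L, effective_kb = 0, mapped_mb =
                      mappedBases(pu) / 1e6, frequency = NA_real_)
    list(pileup = pu, calls = calls, freq = freq)
  })
  vcfPath <- file.path(config@outDir, "snps.vcf")
  writeSnpVcf(snpOut$calls, focalId(pop), vcfPath,
              refLength = length(focalGenome(pop)))
  freqPath <- file.path(config@outDir, "snp_frequency.json")
  jsonlite::write_json(as.list(snpOut$freq), freqPath, auto_unbox = TRUE,
                       digits = NA, na = "null")

  ## assembly + evaluation
  logLine("asmeval", sprintf("k=%d, policy %s", config@assembly@k,
                             config@assembly@bubblePolicy))
  contigs <- runStage("asmeval", debruijnAssemble(rs, config@assembly))
  contigPath <- file.path(config@outDir, "contigs.fasta")
  Biostrings::writeXStringSet(contigs, contigPath)
  report <- runStage("asmeval", evaluateContigs(contigs, pop))
  reportPathT <- file.path(config@outDir, "assembly_report.tsv")
  utils::write.table(recoveryTable(report), reportPathT, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reportPathJ <- file.path(config@outDir, "assembly_report.json")
  jsonlite::write_json(
    list(recovery = recoveryTable(report),
         contigs = contigSummary(report),
         alleles = alleleTable(report),
         recovery_identity_pct = report@recoveryIdentityPct),
    reportPathJ, auto_unbox = TRUE, digits = NA, na = "null")

  ## manifest
  files <- c(popPaths, readPaths, hits = hitPath, kpkg = kpkgPath,
             diversity_curve = curvePath, vcf = vcfPath,
             snp_frequency = freqPath, contigs = contigPath,
             assembly_report_tsv = reportPathT,
             assembly_report_json = reportPathJ)
  manifest <- list(
    config = list(
      preset = config@preset, seed = config@seed,
      focal_length = config@focalLength, gc = config@gc,
      n_background = config@nBackground,
      background_length_range = config@backgroundLengthRange,
      background_gc = config@backgroundGc,
      background_fraction = config@backgroundFraction,
      island_divergence = config@islandDivergence,
      read_sim = paramsAsList(config@readSim),
      recruit = paramsAsList(config@recruit),
      pileup = paramsAsList(config@pileup),
      snp = paramsAsList(config@snp),
      assembly = paramsAsList(config@assembly)),
    stage_seeds = as.list(stats::setNames(stageSeeds,
      c("popgen", "background", "readsim", "recruit_snp", "assembly"))),
    files = lapply(stats::setNames(unname(files), names(files)),
                   function(f) list(path = basename(f),
                                    md5 = unname(tools::md5sum(f)))))
  manifestPath <- file.path(config@outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA)
  logLine("done", sprintf("%.1f s elapsed",
                          as.numeric(difftime(Sys.time(), t0,
                                              units = "secs"))))
  invisible(manifest)
}
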