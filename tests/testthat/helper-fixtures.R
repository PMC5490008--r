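# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the standard 15-kb focal genome used by scenario-level tests
getFocal <- function() {
  fixture("focal", function() generateReference(15000, 0.45, seed = 7))
}

getPopA <- function() {
  fixture("popA", function() buildScenario("A", getFocal(), seed = 7))
}

getPopB <- function() {
  fixture("popB", function() buildScenario("B", getFocal(), seed = 7))
}

getPopC <- function() {
  fixture("popC", function() buildScenario("C", getFocal(), seed = 7))
}

# per-variant symmetric fragment-ANI vs the focal genome
aniVsFocal <- function(pop) {
  focal <- focalGenome(pop)
  vapply(genomes(pop)[-1L],
         function(g) aniPct(fragmentANI(g, focal)), numeric(1L))
}

# random nucleotide string (caller controls the RNG state)
randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# two 15-kb haplotypes whose 20 SNPs sit far apart (spacing 700 >> k),
# for bubble-structure tests
getSpacedHaplotypes <- function() {
  fixture("spacedHaps", function() {
    focal <- getFocal()
    ch <- strsplit(as.character(genomeSeq(focal)), "", fixed = TRUE)[[1L]]
    pos <- seq(400L, by = 700L, length.out = 20L)
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
    list(hap1 = as.character(genomeSeq(focal)),
         hap2 = paste(ch, collapse = ""), positions = pos)
  })
}

# a small random hit table for KPKG accumulation checks
randomHitTable <- function(nHits, genomeIds, seed) {
  withr::with_seed(seed, {
    data.frame(
      qseqid = sprintf("r%04d", seq_len(nHits)),
      sseqid = sample(genomeIds, nHits, replace = TRUE),
      pident = round(stats::runif(nHits, 60, 100), 2),
      qstart = sample(1:20, nHits, replace = TRUE),
      qend = sample(120:150, nHits, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}
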