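# de Bruijn assembly, bubble structure and the provenance-aware
# contig evaluator.

test_that("a single genome at 50x error-free coverage assembles to one contig", {
  g <- generateReference(15000, 0.45, seed = 7)
  rs <- simulateReads(ViralPopulation(list(g)),
                      params = readSimParams(coverage = 50, errorRate = 0),
                      seed = 13)
  contigs <- debruijnAssemble(rs)
  expect_equal(length(contigs), 1L)
  rep <- evaluateContigs(contigs, ViralPopulation(list(g)))
  expect_gte(recoveryTable(rep)$recovery_fraction[1L], 0.99)
  expect_false(any(contigSummary(rep)$chimeric %in% TRUE))
})

test_that("no reads produce no contigs and no bubbles", {
  expect_length(debruijnAssemble(character()), 0L)
  expect_equal(countBubbles(character()), 0L)
})

test_that("assembly parameters are validated", {
  expect_error(assemblyParams(k = 30L), "odd")
  expect_error(assemblyParams(k = 7L), "odd|\\[15")
})

test_that("reads from a single genome contain no bubbles", {
  g <- generateReference(8000, 0.5, seed = 21)
  expect_equal(countBubbles(as.character(genomeSeq(g)),
                            assemblyParams(minKmerCount = 1L)), 0L)
})

test_that("one isolated SNP between two haplotypes makes exactly one bubble", {
  g <- generateReference(5000, 0.5, seed = 22)
  ch <- strsplit(as.character(genomeSeq(g)), "", fixed = TRUE)[[1L]]
  ch[2500] <- setdiff(c("A", "C", "G", "T"), ch[2500])[1L]
  hap2 <- paste(ch, collapse = "")
  n <- countBubbles(c(as.character(genomeSeq(g)), hap2),
                    assemblyParams(minKmerCount = 1L))
  expect_equal(n, 1L)
})

test_that("twenty well-separated SNPs make exactly twenty bubbles", {
  haps <- getSpacedHaplotypes()
  n <- countBubbles(c(haps$hap1, haps$hap2),
                    assemblyParams(minKmerCount = 1L))
  expect_equal(n, 20L)
})

test_that("error-free single-genome assembly is idempotent up to k", {
  g <- generateReference(12000, 0.45, seed = 30)
  rs <- simulateReads(ViralPopulation(list(g)),
                      params = readSimParams(coverage = 50, errorRate = 0),
                      seed = 31)
  c1 <- debruijnAssemble(rs)
  expect_equal(length(c1), 1L)
  len1 <- S4Vectors::mcols(c1)$length[1L]
  g2 <- Genome("contig", as.character(c1[[1L]]))
  rs2 <- simulateReads(ViralPopulation(list(g2)),
                       params = readSimParams(coverage = 50, errorRate = 0),
                       seed = 32)
  c2 <- debruijnAssemble(rs2)
  expect_equal(length(c2), 1L)
  expect_lte(abs(S4Vectors::mcols(c2)$length[1L] - len1), 31L)
})

test_that("a constructed mixed-allele contig is flagged as chimeric", {
  pop <- getPopA()   # carries the mutation records
  # build a consensus carrying focal alleles at the first 10 recorded
  # SNP sites and variant alleles at the last 10
  focal <- focalGenome(pop)
  variant <- genomes(pop)[[2L]]
  m <- mutations(variant)
  ch <- strsplit(as.character(genomeSeq(focal)), "", fixed = TRUE)[[1L]]
  late <- m[order(m$pos), ][11:20, ]
  ch[late$pos] <- late$alt
  mixed <- paste(ch, collapse = "")
  rep <- evaluateContigs(mixed, pop)
  cs <- contigSummary(rep)
  expect_true(cs$chimeric[1L])
  expect_equal(cs$n_sites[1L], 20L)
  # and a contig identical to one parent is never chimeric
  repPure <- evaluateContigs(as.character(genomeSeq(variant)), pop)
  csPure <- contigSummary(repPure)
  expect_false(csPure$chimeric[1L])
  expect_equal(csPure$matching_parents[1L], genomeId(variant))
  recPure <- recoveryTable(repPure)
  expect_equal(
    recPure$recovery_fraction[recPure$genome_id == genomeId(variant)], 1)
})

test_that("exact substrings of one truth genome are never chimeric", {
  pop <- getPopA()
  s <- as.character(genomeSeq(focalGenome(pop)))
  withr::with_seed(44, starts <- sample(10000, 5))
  pieces <- substring(s, starts, starts + 3999)
  rep <- evaluateContigs(pieces, pop)
  expect_false(any(contigSummary(rep)$chimeric %in% TRUE))
})

test_that("external contig FASTA files are accepted with an identical report schema", {
  pop <- getPopA()
  fa <- withr::local_tempfile(fileext = ".fasta")
  x <- Biostrings::DNAStringSet(
    substr(as.character(genomeSeq(focalGenome(pop))), 1, 5000))
  names(x) <- "external_1"
  Biostrings::writeXStringSet(x, fa)
  repFile <- evaluateContigs(fa, pop)
  repMem <- evaluateContigs(x, pop)
  expect_identical(names(contigSummary(repFile)), names(contigSummary(repMem)))
  expect_equal(recoveryTable(repFile), recoveryTable(repMem))
})

test_that("unassigned contigs are reported, not errors", {
  pop <- getPopA()
  withr::with_seed(50, alien <- randomSeq(2000))
  rep <- evaluateContigs(alien, pop)
  cs <- contigSummary(rep)
  expect_equal(nrow(cs), 1L)
  expect_false(cs$aligned[1L])
  expect_true(is.na(cs$chimeric[1L]))
})
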