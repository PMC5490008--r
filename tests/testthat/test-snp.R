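# Pileup construction, binomial SNP calling, the normalized
# SNP-frequency statistic and VCF output.

# closed-form binomial upper tail, written independently of the caller
oracleTail <- function(altCount, depth, errorRate) {
  if (altCount <= 0) return(1)
  sum(vapply(altCount:depth, function(k) {
    choose(depth, k) * errorRate^k * (1 - errorRate)^(depth - k)
  }, numeric(1L)))
}

test_that("a single error-free read produces unit depth over its span", {
  g <- generateReference(1000, 0.5, seed = 3)
  s <- as.character(genomeSeq(g))
  read <- substr(s, 101, 250)
  hits <- recruitReads(c(r1 = read), list(g))
  pu <- buildPileup(hits, c(r1 = read), g)
  d <- siteDepth(pu)
  expect_true(all(d[101:250] == 1))
  expect_true(all(d[-(101:250)] == 0))
  expect_equal(mappedBases(pu), 150)
})

test_that("reads below the mapping identity threshold are excluded entirely", {
  g <- generateReference(1000, 0.5, seed = 5)
  s <- as.character(genomeSeq(g))
  read <- substr(s, 201, 350)
  ch <- strsplit(read, "", fixed = TRUE)[[1L]]
  withr::with_seed(2, {
    for (p in sample(150, 15)) {   # ~90% identity
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
  })
  noisy <- paste(ch, collapse = "")
  hits <- recruitReads(c(r1 = noisy), list(g))
  pu <- buildPileup(hits, c(r1 = noisy), g)
  expect_equal(sum(siteDepth(pu)), 0)
})

test_that("pileup demands consistency between hits and reads", {
  g <- generateReference(1000, 0.5, seed = 3)
  s <- as.character(genomeSeq(g))
  read <- substr(s, 101, 250)
  hits <- recruitReads(c(r1 = read), list(g))
  expect_error(buildPileup(hits, c(other = read), g), "absent")
})

test_that("p-values match the closed-form binomial oracle on a grid", {
  counts <- matrix(0L, 4, 60, dimnames = list(c("A", "C", "G", "T"), NULL))
  refSeq <- strrep("A", 60)
  i <- 0L
  cases <- expand.grid(depth = c(5L, 10L, 20L, 40L),
                       alt = c(0L, 1L, 2L, 5L, 10L))
  cases <- cases[cases$alt <= cases$depth, ]
  for (r in seq_len(nrow(cases))) {
    i <- i + 1L
    counts["A", i] <- cases$depth[r] - cases$alt[r]
    counts["C", i] <- cases$alt[r]
  }
  pu <- new("Pileup", counts = counts, refId = "ref",
            refSeq = Biostrings::DNAString(refSeq), mappedBases = 1e5,
            nReads = 100L, params = pileupParams())
  calls <- callSNPs(pu, snpCallerParams(errorRate = 0.01), allSites = TRUE)
  for (r in seq_len(nrow(cases))) {
    expect_equal(calls$p_value[r],
                 oracleTail(cases$alt[r], cases$depth[r], 0.01),
                 tolerance = 1e-12)
  }
  # spot checks from first principles
  c20a10 <- calls[calls$depth == 20 & calls$alt_count == 10, ][1L, ]
  expect_lt(c20a10$p_value, 1e-6)
  expect_true(c20a10$is_snp)
  c20a1 <- calls[calls$depth == 20 & calls$alt_count == 1, ][1L, ]
  expect_equal(c20a1$p_value, 1 - 0.99^20, tolerance = 1e-12)
  expect_false(c20a1$is_snp)
})

test_that("no call is ever made below the minimum coverage", {
  counts <- matrix(0L, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", ] <- 0:7
  counts["C", ] <- c(4L, 3L, 4L, 1L, 0L, 2L, 4L, 4L)  # depth 4..11
  pu <- new("Pileup", counts = counts, refId = "ref",
            refSeq = Biostrings::DNAString(strrep("A", 8)),
            mappedBases = 100, nReads = 10L, params = pileupParams())
  calls <- callSNPs(pu, allSites = TRUE)
  expect_false(any(calls$is_snp[calls$depth < 5]))
  # depth 4 with all-alternative alleles still refused
  expect_false(calls$is_snp[1L])
})

test_that("p-value is non-increasing in the alternative count", {
  p <- vapply(0:30, function(a) {
    stats::pbinom(a - 1, 30, 0.01, lower.tail = FALSE)
  }, numeric(1L))
  calls <- vapply(0:30, function(a) {
    counts <- matrix(0L, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
    counts["A", 1] <- 30L - a
    counts["C", 1] <- a
    pu <- new("Pileup", counts = counts, refId = "r",
              refSeq = Biostrings::DNAString("A"), mappedBases = 10,
              nReads = 1L, params = pileupParams())
    callSNPs(pu, allSites = TRUE)$p_value[1L]
  }, numeric(1L))
  expect_true(all(diff(calls) <= 1e-12))
  expect_equal(calls, p, tolerance = 1e-12)
})

test_that("planted SNPs at 0.5 frequency are recovered with no off-site calls", {
  focal <- getFocal()
  planted <- mutations(mutateGenome(focal, 30, seed = 90))$pos
  hap2 <- mutateGenome(focal, 30, seed = 90, id = "hap2")
  pop <- ViralPopulation(list(focal, hap2))
  recalls <- numeric(5)
  for (s in 1:5) {
    rs <- simulateReads(pop, params = readSimParams(coverage = 20,
                                                    errorRate = 0),
                        seed = 500 + s)
    hits <- recruitReads(rs, list(focal))
    pu <- buildPileup(hits, rs, focal)
    calls <- callSNPs(pu)
    called <- calls$position[calls$is_snp]
    expect_length(setdiff(called, planted), 0)
    recalls[s] <- mean(planted %in% called)
  }
  expect_gte(mean(recalls), 0.9)
})

test_that("SNP frequency follows its defining arithmetic", {
  counts <- matrix(2L, 4, 15000)   # depth 8 everywhere -> effective 15 kb
  rownames(counts) <- c("A", "C", "G", "T")
  pu <- new("Pileup", counts = counts, refId = "ref",
            refSeq = Biostrings::DNAString(strrep("A", 15000)),
            mappedBases = 3e6, nReads = 1000L, params = pileupParams())
  calls <- data.frame(position = 1:30, is_snp = TRUE)
  fr <- snpFrequency(calls, pu)
  expect_equal(fr$frequency, 30 / 15 / 3)
  fr0 <- snpFrequency(data.frame(is_snp = logical()), pu)
  expect_equal(fr0$frequency, 0)
  # doubling mapped bases halves the frequency exactly
  fr2 <- snpFrequency(calls, pu, mappedReadBases = 6e6)
  expect_equal(fr2$frequency, fr$frequency / 2)
})

test_that("snpFrequency refuses an empty effective genome", {
  counts <- matrix(0L, 4, 100)
  rownames(counts) <- c("A", "C", "G", "T")
  pu <- new("Pileup", counts = counts, refId = "ref",
            refSeq = Biostrings::DNAString(strrep("A", 100)),
            mappedBases = 1000, nReads = 10L, params = pileupParams())
  expect_error(snpFrequency(data.frame(is_snp = logical()), pu),
               "effective|minimum coverage")
})

test_that("emitted VCF is valid v4.2 and round-trips through VariantAnnotation", {
  focal <- generateReference(2000, 0.5, seed = 2)
  pop <- ViralPopulation(list(focal,
                              mutateGenome(focal, 10, seed = 3, id = "v")))
  rs <- simulateReads(pop, params = readSimParams(coverage = 30,
                                                  errorRate = 0), seed = 5)
  hits <- recruitReads(rs, pop, recruitParams(assignmentMode = "all"))
  pu <- buildPileup(hits, rs, focal)
  calls <- callSNPs(pu)
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  writeSnpVcf(calls, "focal", vcfPath, refLength = 2000)
  v <- VariantAnnotation::readVcf(vcfPath)
  expect_equal(nrow(v), sum(calls$is_snp))
  expect_equal(sort(BiocGenerics::start(v)),
               sort(calls$position[calls$is_snp]))
  dp <- VariantAnnotation::info(v)$DP
  expect_equal(sort(dp), sort(calls$depth[calls$is_snp]))
})
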