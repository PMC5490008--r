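# Fragment recruitment, KPKG normalization, relative recruitment and
# diversity curves.

test_that("error-free reads recruit at identity 100 and coverage 100", {
  pop <- ViralPopulation(list(generateReference(4000, 0.5, seed = 2)))
  rs <- simulateReads(pop, params = readSimParams(nPairs = 100L,
                                                  errorRate = 0), seed = 3)
  hits <- recruitReads(rs, pop)
  expect_equal(nrow(hits), 200)
  expect_true(all(hits$pident == 100))
  expect_true(all(hits$qcovs == 100))
})

test_that("a 10 percent divergent read passes the genus but not the species cutoff", {
  g <- generateReference(4000, 0.5, seed = 6)
  s <- as.character(genomeSeq(g))
  read <- substr(s, 1001, 1150)
  ch <- strsplit(read, "", fixed = TRUE)[[1L]]
  withr::with_seed(9, {
    for (p in sample(150, 15)) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
  })
  read <- paste(ch, collapse = "")
  hits <- recruitReads(c(divergent = read), list(g))
  expect_equal(nrow(hits), 1)
  expect_gte(hits$pident[1L], 70)
  expect_lt(hits$pident[1L], 95)
  p <- recruitParams()
  expect_equal(nrow(hits[hits$pident >= p@genusCutoffPct, ]), 1)
  expect_equal(nrow(hits[hits$pident >= p@speciesCutoffPct, ]), 0)
})

test_that("reads hanging off a genome end fail the query-coverage filter", {
  g <- generateReference(3000, 0.5, seed = 12)
  s <- as.character(genomeSeq(g))
  withr::with_seed(4, tail75 <- randomSeq(75))
  read <- paste0(substr(s, 2926, 3000), tail75)  # 50% aligns
  hits <- recruitReads(c(edge = read), list(g))
  expect_equal(nrow(hits), 0)
  hitsAll <- recruitReads(c(edge = read), list(g),
                          recruitParams(minQcovPct = 40))
  expect_equal(nrow(hitsAll), 1)
})

test_that("best-hit assignment keeps each read at most once", {
  pop <- getPopA()
  rs <- simulateReads(pop, params = readSimParams(nPairs = 200L), seed = 15)
  hits <- recruitReads(rs, pop, recruitParams(assignmentMode = "best_hit"))
  expect_false(any(duplicated(hits$qseqid)))
  hitsRBH <- recruitReads(rs, pop,
                          recruitParams(assignmentMode = "reciprocal_best_hit"))
  expect_false(any(duplicated(hitsRBH$qseqid)))
})

test_that("recruitReads requires a non-empty reference set", {
  expect_error(recruitReads(c(r = "ACGT"), list()), "empty")
})

test_that("KPKG reproduces the hand-computed example", {
  # 100 reads x 200 aligned bp on a 10-kb genome from a 1-Mb metagenome
  hits <- data.frame(qseqid = sprintf("r%03d", 1:100), sseqid = "g",
                     pident = 100, qstart = 1, qend = 200,
                     stringsAsFactors = FALSE)
  st <- computeKPKG(hits, c(g = 10000), 1e6, 95)
  expect_equal(st$recruited_kb, 20)
  expect_equal(st$kpkg, 2000)
  expect_equal(st$n_reads, 100L)
})

test_that("KPKG equals a brute-force accumulation on 1,000-hit tables", {
  genomeLengths <- c(gA = 12000, gB = 8000, gC = 20000)
  hits <- randomHitTable(1000, names(genomeLengths), seed = 31)
  for (cutoff in c(70, 95)) {
    st <- computeKPKG(hits, genomeLengths, 5e8, cutoff)
    for (g in names(genomeLengths)) {
      acc <- 0
      for (i in seq_len(nrow(hits))) {   # deliberate brute-force oracle
        if (hits$sseqid[i] == g && hits$pident[i] >= cutoff) {
          acc <- acc + (hits$qend[i] - hits$qstart[i] + 1)
        }
      }
      expected <- (acc / 1000) / (genomeLengths[[g]] / 1000) / 0.5
      expect_equal(st$kpkg[st$genome_id == g], expected)
    }
  }
})

test_that("doubling the metagenome size exactly halves KPKG", {
  hits <- randomHitTable(300, c("gA", "gB"), seed = 8)
  s1 <- computeKPKG(hits, c(gA = 10000, gB = 5000), 1e7, 70)
  s2 <- computeKPKG(hits, c(gA = 10000, gB = 5000), 2e7, 70)
  expect_equal(s1$kpkg, 2 * s2$kpkg)
})

test_that("zero hits give zero KPKG, unknown genomes error", {
  empty <- randomHitTable(0, "gA", seed = 1)
  st <- computeKPKG(empty, c(gA = 1000), 1e6, 95)
  expect_equal(st$kpkg, 0)
  bad <- randomHitTable(10, "mystery", seed = 2)
  expect_error(computeKPKG(bad, c(gA = 1000), 1e6, 95), "mystery")
})

test_that("relative recruitment normalizes means to shares", {
  expect_equal(relativeRecruitment(c(a = 2, b = 1, c = 1)),
               c(a = 0.5, b = 0.25, c = 0.25))
  expect_equal(relativeRecruitment(c(only = 7)), c(only = 1))
  x <- c(a = 3, b = 1, c = 6)
  expect_equal(relativeRecruitment(x[c(3, 1, 2)]),
               relativeRecruitment(x)[c(3, 1, 2)])
  expect_error(relativeRecruitment(c(a = 0, b = 0)), "zero")
})

test_that("diversity curve bins are complete and sum to 100", {
  hits <- data.frame(qseqid = sprintf("r%d", 1:50), sseqid = "g",
                     pident = c(rep(100, 20), rep(87.3, 15), rep(72.5, 15)),
                     stringsAsFactors = FALSE)
  dc <- diversityCurve(hits, "g")
  expect_equal(sum(dc$pct_reads), 100, tolerance = 1e-6)
  expect_equal(nrow(dc), 30)
  # all reads at identity 100 fall in the terminal [99,100] bin
  dcTop <- diversityCurve(hits[hits$pident == 100, ], "g")
  expect_equal(dcTop$pct_reads[dcTop$bin_low == 99], 100)
})

test_that("out-of-range identities go to the terminal bin with a warning", {
  hits <- data.frame(qseqid = "r1", sseqid = "g", pident = 55,
                     stringsAsFactors = FALSE)
  expect_warning(dc <- diversityCurve(hits, "g"), "terminal")
  expect_equal(dc$pct_reads[1L], 100)
})

test_that("bin edges must increase strictly", {
  expect_error(diversityCurve(data.frame(qseqid = "r", sseqid = "g",
                                         pident = 90), "g",
                              binEdges = c(70, 70, 100)), "increasing")
})

test_that("a microdiverse population shows its mass below the species cutoff", {
  popC <- getPopC()
  focal <- focalGenome(popC)
  rs <- simulateReads(popC, params = readSimParams(nPairs = 600L),
                      seed = 71)
  hits <- recruitReads(rs, list(focal))
  dc <- diversityCurve(hits, genomeId(focal))
  below <- sum(dc$pct_reads[dc$bin_high <= 95])
  above <- sum(dc$pct_reads[dc$bin_low >= 95])
  expect_gt(below, above)
})

test_that("background reads are never assigned to the focal genome at species level", {
  popA <- getPopA()
  bg <- makeBackground(4, c(4000, 6000), 0.45, seed = 81)
  rs <- simulateReads(popA, background = bg,
                      params = readSimParams(nPairs = 400L), seed = 82)
  hits <- recruitReads(rs, popA,
                       recruitParams(assignmentMode = "best_hit"))
  tt <- truthTable(rs)
  bgIds <- vapply(bg, genomeId, character(1L))
  bgReads <- tt$read_id[tt$genome_id %in% bgIds]
  species <- hits[hits$pident >= 95, , drop = FALSE]
  expect_length(intersect(species$qseqid, bgReads), 0)
})
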