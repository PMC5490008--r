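# Alignment primitives: the seed-and-extend Smith-Waterman engine is
# checked against Biostrings::pairwiseAlignment as an independent
# dynamic-programming oracle.

oracleScore <- function(a, b) {
  # same scoring scheme: +1/-2, gap of length L costs 5 + 2(L-1);
  # Biostrings charges gapOpening + gapExtension per opened gap column
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
    gapOpening = 3, gapExtension = 2))
}

test_that("local alignment matches the exhaustive DP oracle on mutated pairs", {
  withr::with_seed(11, {
    for (i in 1:8) {
      a <- randomSeq(250)
      ch <- strsplit(a, "", fixed = TRUE)[[1L]]
      for (p in sample(250, 12)) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      }
      # also an indel to exercise gap scoring
      ch <- append(ch, c("G", "G", "G"), after = 120)
      b <- paste(ch, collapse = "")
      h <- alignLocal(a, b, method = "full")
      expect_gt(nrow(h), 0)
      expect_equal(h$score[1L], oracleScore(a, b))
    }
  })
})

test_that("identity accounting follows the pident convention", {
  withr::with_seed(3, {
    a <- randomSeq(200)
    ch <- strsplit(a, "", fixed = TRUE)[[1L]]
    ch[100] <- setdiff(c("A", "C", "G", "T"), ch[100])[1L]
    b <- paste(ch, collapse = "")
  })
  h <- alignLocal(a, b, method = "full")
  # identity_pct == (length - mismatch - gapcols) / length * 100
  expect_equal(h$pident,
               100 * (h$length - h$mismatch - h$gapcols) / h$length)
  expect_equal(h$pident[1L], 100 * 199 / 200)
  expect_equal(h$qcovs[1L], 100)
})

test_that("a sequence aligned to itself gives a full-identity hit", {
  withr::with_seed(1, s <- randomSeq(50))
  h <- alignLocal(s, s)
  expect_equal(h$pident[1L], 100)
  expect_equal(h$qcovs[1L], 100)
  expect_equal(h$length[1L], 50L)
})

test_that("a 20-mer with one substitution aligns at 95 percent identity", {
  a <- "ATGGCCATTGTAATGGGCCG"
  ch <- strsplit(a, "", fixed = TRUE)[[1L]]
  ch[10] <- "C"   # T -> C
  b <- paste(ch, collapse = "")
  h <- alignLocal(a, b, alignParams(minAlnScore = 5L, minAlnLength = 10L),
                  method = "full")
  h <- h[h$strand == "+", , drop = FALSE]
  expect_equal(h$length[1L], 20L)
  expect_equal(h$pident[1L], 95)
})

test_that("unalignable sequences yield an empty hit table", {
  h <- alignLocal(strrep("A", 40), strrep("C", 40), method = "full")
  expect_equal(nrow(h), 0)
})

test_that("reverse-strand hits report forward subject coordinates", {
  withr::with_seed(5, s <- randomSeq(120))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  subject <- paste0(strrep("A", 30), s, strrep("T", 30))
  h <- alignLocal(rc, subject)
  h <- h[h$strand == "-", , drop = FALSE]
  expect_gte(nrow(h), 1)
  expect_equal(h$sstart[1L], 31)
  expect_equal(h$send[1L], 150)
  expect_equal(h$pident[1L], 100)
})

test_that("input validation names the offending symbol", {
  expect_error(alignLocal("", "ACGT"), "empty")
  expect_error(alignLocal("ACGTX", "ACGT"), "X")
})

test_that("fragment ANI of a genome against itself is 100", {
  g <- generateReference(2000, 0.45, seed = 1)
  r <- fragmentANI(g, g)
  expect_equal(aniPct(r), 100)
  expect_equal(alignedFraction(r), 1)
})

test_that("20 evenly spaced substitutions in 2 kb give ANI near 99", {
  a <- generateReference(2000, 0.5, seed = 3)
  ch <- strsplit(as.character(genomeSeq(a)), "", fixed = TRUE)[[1L]]
  for (p in seq(50, 1950, by = 100)) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
  }
  b <- paste(ch, collapse = "")
  r <- fragmentANI(a, b)
  expect_lt(abs(aniPct(r) - 99), 0.2)
})

test_that("unrelated random genomes share almost no fragments", {
  withr::with_seed(17, {
    a <- randomSeq(2000)
    b <- randomSeq(2000)
  })
  r <- fragmentANI(a, b)
  expect_lt(alignedFraction(r), 0.05)
})

test_that("symmetric fragment ANI is direction-insensitive", {
  g <- generateReference(5000, 0.45, seed = 9)
  v <- mutateGenome(g, 250, seed = 10)
  ab <- aniPct(fragmentANI(g, v))
  ba <- aniPct(fragmentANI(v, g))
  expect_lt(abs(ab - ba), 0.1)
})

test_that("fragment ANI rejects genomes shorter than a fragment", {
  expect_error(fragmentANI(strrep("ACGT", 10), strrep("ACGT", 500)),
               "fragmentSize")
})

test_that("genomeDiff is empty for identical genomes", {
  g <- generateReference(1500, 0.5, seed = 2)
  expect_equal(nrow(genomeDiff(g, g)), 0)
})

test_that("genomeDiff matches a character-comparison oracle on substitution-only pairs", {
  withr::with_seed(21, {
    for (i in 1:5) {
      g <- generateReference(3000, 0.45, seed = 30 + i)
      v <- mutateGenome(g, sample(5:80, 1L), seed = 60 + i)
      d <- genomeDiff(g, v)
      av <- strsplit(as.character(genomeSeq(g)), "", fixed = TRUE)[[1L]]
      bv <- strsplit(as.character(genomeSeq(v)), "", fixed = TRUE)[[1L]]
      expect_equal(sum(d$type == "sub"), sum(av != bv))
      expect_equal(d$pos, which(av != bv))
    }
  })
})

test_that("genomeDiff reports a clean 3-bp insertion", {
  g <- generateReference(2000, 0.5, seed = 4)
  s <- as.character(genomeSeq(g))
  b <- paste0(substr(s, 1, 1000), "TTT", substr(s, 1001, 2000))
  d <- genomeDiff(g, b)
  expect_equal(sum(d$type == "ins"), 1)
  expect_equal(sum(d$type == "sub"), 0)
  expect_equal(d$alt[d$type == "ins"], "TTT")
})

test_that("genomeDiff refuses unalignable pairs", {
  withr::with_seed(33, {
    a <- randomSeq(2000)
    b <- paste0(randomSeq(1990))
  })
  expect_error(genomeDiff(a, b), "divergent")
})
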