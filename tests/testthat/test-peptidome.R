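# ORF finding, tryptic digestion (checked against the brute-force
# cleavage-subset enumeration oracle in helper-oracles.R) and
# exact-match peptide recruitment.

# a 300-nt ORF (start + 98 codons + stop) free of internal stops/starts
makeOrf <- function(seed) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste,
                  collapse = "")
  safe <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG", "GTG"))
  withr::with_seed(seed, {
    paste0("ATG", paste(sample(safe, 98, replace = TRUE), collapse = ""),
           "TAA")
  })
}

test_that("an embedded 300-nt ORF yields exactly one 99-residue protein", {
  orf <- makeOrf(4)
  expect_equal(nchar(orf), 300L)
  g <- Genome("t", paste0(strrep("C", 500), orf, strrep("C", 500)))
  prots <- findORFs(g, minLenAA = 60)
  expect_equal(length(prots), 1L)
  expect_equal(Biostrings::width(prots)[1L], 99L)
  expect_equal(substr(as.character(prots[[1L]]), 1, 1), "M")
  md <- S4Vectors::mcols(prots)
  expect_equal(md$start, 501L)
  expect_equal(md$end, 800L)
})

test_that("the same ORF on the reverse strand gives the same protein", {
  orf <- makeOrf(4)
  g <- Genome("t", paste0(strrep("C", 500), orf, strrep("C", 500)))
  gRev <- Genome("tRev", as.character(
    Biostrings::reverseComplement(genomeSeq(g))))
  p1 <- findORFs(g, minLenAA = 60)
  p2 <- findORFs(gRev, minLenAA = 60)
  expect_equal(length(p2), 1L)
  expect_identical(as.character(p1[[1L]]), as.character(p2[[1L]]))
  expect_equal(S4Vectors::mcols(p2)$strand, "-")
})

test_that("the minimum-length filter removes short ORFs", {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste,
                  collapse = "")
  safe <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG", "GTG"))
  withr::with_seed(5, short <- paste0(
    "ATG", paste(sample(safe, 29, replace = TRUE), collapse = ""), "TAA"))
  g <- Genome("s", paste0(strrep("C", 300), short, strrep("C", 300)))
  expect_equal(length(findORFs(g, minLenAA = 60)), 0L)
  expect_equal(length(findORFs(g, minLenAA = 20)), 1L)
})

test_that("digestion matches the worked cleavage example", {
  peps <- trypticDigest("GGKAARPCCKDD",
                        digestParams(maxMissedCleavages = 0,
                                     minPeptideLength = 1))
  # no cleavage at the R that precedes P
  expect_setequal(peps, c("GGK", "AARPCCK", "DD"))
})

test_that("a protein without K or R survives digestion whole", {
  expect_equal(trypticDigest("MAGICSTINE", digestParams()), "MAGICSTINE")
})

test_that("digestion equals the brute-force enumeration at 0-4 missed cleavages", {
  withr::with_seed(61, {
    toy <- paste(sample(c("A", "G", "S", "T", "L", "K", "R", "P", "D", "E"),
                        60, replace = TRUE, prob = c(rep(0.11, 5),
                                                     0.15, 0.15, 0.08,
                                                     0.08, 0.09)),
                 collapse = "")
  })
  for (mm in 0:4) {
    got <- trypticDigest(toy, digestParams(maxMissedCleavages = mm,
                                           minPeptideLength = 1))
    expect_setequal(got, bruteDigest(toy, mm, 1))
  }
})

test_that("peptides are substrings and zero-missed peptides tile the protein", {
  withr::with_seed(62, {
    prot <- paste(sample(c("A", "G", "S", "K", "R", "L", "V", "D"),
                         80, replace = TRUE), collapse = "")
  })
  peps <- trypticDigest(prot, digestParams(maxMissedCleavages = 3,
                                           minPeptideLength = 1))
  expect_true(all(vapply(peps, function(p) grepl(p, prot, fixed = TRUE),
                         logical(1L))))
  zero <- trypticDigest(prot, digestParams(maxMissedCleavages = 0,
                                           minPeptideLength = 1))
  # independent segmentation by the cleavage rule: the segments tile
  # the protein and each (deduplicated) segment is an emitted peptide
  ch <- strsplit(prot, "", fixed = TRUE)[[1L]]
  cut <- which(ch %in% c("K", "R"))
  cut <- cut[cut < length(ch) & ch[cut + 1L] != "P"]
  bounds <- c(0L, cut, length(ch))
  segments <- substring(prot, head(bounds, -1L) + 1L, bounds[-1L])
  expect_equal(paste(segments, collapse = ""), prot)
  expect_setequal(zero, unique(segments))
})

test_that("non-standard residues are rejected by name", {
  expect_error(trypticDigest("MAGKXR"), "X")
})

test_that("peptide recruitment demands perfect full-length matches", {
  prot <- Biostrings::AAStringSet(c(gA_p1 = "MAGKSTLVKDERPLK"))
  lens <- c(gA = 20000)
  hit <- peptideRecruit("STLVK", list(gA = prot), lens)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$position, 5L)
  miss <- peptideRecruit("STIVK", list(gA = prot), lens)
  expect_equal(nrow(miss), 0L)
})

test_that("per-genome counts are normalized by genome kb", {
  # 10 exact matches on a 20-kb genome -> 0.5 hits per kb
  prot <- Biostrings::AAStringSet(
    c(gA_p1 = paste0(strrep("GASK", 10), "LLLL")))
  hits <- peptideRecruit("GASK", list(gA = prot), c(gA = 20000))
  expect_equal(nrow(hits), 10L)
  expect_true(all(hits$normalized_count == 0.5))
})

test_that("an empty peptide list warns and returns an empty table", {
  expect_warning(out <- peptideRecruit(character(),
                                       list(g = Biostrings::AAStringSet()),
                                       c(g = 1000)), "empty")
  expect_equal(nrow(out), 0L)
})
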