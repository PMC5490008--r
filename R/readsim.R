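#' @include popgen.R
NULL

#' Generate an unrelated background community
#'
#' Random genomes standing in for the natural virome a focal population
#' is spiked into. Being i.i.d. sequences, they are mutually unrelated
#' and unrelated to any focal population (verifiable post hoc with
#' [fragmentANI]: aligned fraction below 0.05 against the focal genome).
#'
#' @param nGenomes number of background genomes (>= 0).
#' @param lengthRange length-2 integer range of genome lengths (bp).
#' @param gc GC fraction.
#' @param seed integer seed.
#' @param prefix id prefix (default "bg").
#' @return list of [Genome-class] objects.
#' @examples
#' bg <- makeBackground(3, c(5000, 8000), 0.45, seed = 3)
#' @export
makeBackground <- function(nGenomes, lengthRange = c(5000L, 50000L),
                           gc = 0.45, seed, prefix = "bg") {
  if (nGenomes < 0) stop("nGenomes must be >= 0")
  if (nGenomes == 0L) return(list())
  lens <- withSeed(seed, {
    sample(seq.int(lengthRange[1L], lengthRange[2L]), nGenomes,
           replace = TRUE)
  })
  lapply(seq_len(nGenomes), function(i) {
    generateReference(lens[i], gc, seed = deriveSeed(seed, i),
                      id = sprintf("%s%02d", prefix, i))
  })
}

# vectorised substring extraction for one genome's fragments
extractReads <- function(genomeChar, starts, readLength) {
  substring(genomeChar, starts, starts + readLength - 1L)
}

#' Simulate paired-end reads from a population (plus background)
#'
#' Draws read pairs genome by genome with probability proportional to
#' abundance times genome length, fragment start positions uniform
#' along the genome, insert sizes normal (clamped to
#' \code{[readLength, genome length]}), and i.i.d. substitution errors
#' at `errorRate`. Every read carries truth provenance (source genome,
#' 1-based leftmost position, strand, error count).
#'
#' When `background` genomes are supplied, a fraction
#' `backgroundFraction` of the pair mass is assigned to them (split
#' within the background proportionally to genome length), and the
#' population abundances are scaled to the remainder — the spike-in
#' design of a focal population inside a larger virome.
#'
#' @param population a [ViralPopulation-class].
#' @param background optional list of [Genome-class] background genomes.
#' @param params a [ReadSimParams] object; exactly one of `nPairs` and
#'   `coverage` must be set (`coverage` is converted using the total
#'   source length).
#' @param seed integer seed.
#' @param backgroundFraction fraction of pairs drawn from the
#'   background when present (default 0.5).
#' @return A [ReadSet-class].
#' @examples
#' pop <- ViralPopulation(list(generateReference(2000, 0.5, seed = 1)))
#' rs <- simulateReads(pop, params = readSimParams(nPairs = 100L,
#'                     insertMean = 300), seed = 9)
#' length(rs)
#' @export
simulateReads <- function(population, background = NULL,
                          params = readSimParams(), seed,
                          backgroundFraction = 0.5) {
  stopifnot(is(population, "ViralPopulation"))
  ab <- abundances(population)
  if (abs(sum(ab) - 1) > 1e-9) stop("abundances must sum to 1")
  gs <- genomes(population)
  if (length(background)) {
    bgLens <- vapply(background, length, integer(1L))
    bgAb <- backgroundFraction * bgLens / sum(bgLens)
    ab <- c(ab * (1 - backgroundFraction), bgAb)
    names(ab) <- c(names(gs), vapply(background, genomeId, character(1L)))
    gs <- c(gs, stats::setNames(background,
                                vapply(background, genomeId, character(1L))))
  }
  lens <- vapply(gs, length, integer(1L))
  rl <- params@readLength
  if (any(lens < rl)) stop("all source genomes must be >= readLength")

  nPairs <- params@nPairs
  if (is.na(nPairs)) {
    if (is.na(params@coverage))
      stop("one of nPairs or coverage must be set")
    nPairs <- as.integer(round(params@coverage * sum(lens) / (2 * rl)))
  }

  gsChar <- vapply(gs, as.character, character(1L))
  w <- ab * lens

  sim <- withSeed(seed, {
    gi <- sample.int(length(gs), nPairs, replace = TRUE, prob = w)
    ins <- round(stats::rnorm(nPairs, params@insertMean, params@insertSd))
    ins <- pmin(pmax(ins, rl), lens[gi])
    fragStart <- floor(stats::runif(nPairs) * (lens[gi] - ins + 1)) + 1L
    fragStrand <- ifelse(stats::runif(nPairs) < 0.5, "+", "-")
    nerr <- stats::rbinom(2L * nPairs, rl, params@errorRate)
    list(gi = gi, ins = ins, fragStart = fragStart, fragStrand = fragStrand,
         nerr = nerr,
         errs = lapply(seq_len(2L * nPairs), function(i) {
           if (nerr[i] == 0L) NULL
           else list(pos = sample.int(rl, nerr[i]),
                     shift = sample.int(3L, nerr[i], replace = TRUE))
         }))
  })

  fragEnd <- sim$fragStart + sim$ins - 1L
  # forward-strand substrings at both fragment ends
  leftSeq <- character(nPairs)
  rightSeq <- character(nPairs)
  for (g in unique(sim$gi)) {
    idx <- sim$gi == g
    leftSeq[idx] <- extractReads(gsChar[g], sim$fragStart[idx], rl)
    rightSeq[idx] <- extractReads(gsChar[g], fragEnd[idx] - rl + 1L, rl)
  }
  plus <- sim$fragStrand == "+"
  # mate1 reads the fragment 5' end on the fragment strand
  m1seq <- ifelse(plus, leftSeq, revcompChar(rightSeq))
  m2seq <- ifelse(plus, revcompChar(rightSeq), leftSeq)
  m1start <- ifelse(plus, sim$fragStart, fragEnd - rl + 1L)
  m2start <- ifelse(plus, fragEnd - rl + 1L, sim$fragStart)
  m1strand <- ifelse(plus, "+", "-")
  m2strand <- ifelse(plus, "-", "+")

  # apply substitution errors (read-local positions)
  bases <- c("A", "C", "G", "T")
  applyErr <- function(seqs, errList) {
    for (i in seq_along(seqs)) {
      e <- errList[[i]]
      if (is.null(e)) next
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      for (j in seq_along(e$pos)) {
        p <- e$pos[j]
        ch[p] <- bases[((match(ch[p], bases) - 1L + e$shift[j]) %% 4L) + 1L]
      }
      seqs[i] <- paste(ch, collapse = "")
    }
    seqs
  }
  m1seq <- applyErr(m1seq, sim$errs[seq_len(nPairs)])
  m2seq <- applyErr(m2seq, sim$errs[nPairs + seq_len(nPairs)])

  ids <- sprintf("r%06d", seq_len(nPairs))
  m1 <- Biostrings::DNAStringSet(m1seq)
  names(m1) <- paste0(ids, "/1")
  m2 <- Biostrings::DNAStringSet(m2seq)
  names(m2) <- paste0(ids, "/2")
  gids <- names(gs)[sim$gi]
  truth <- data.frame(
    read_id = c(names(m1), names(m2)),
    mate = rep(c(1L, 2L), each = nPairs),
    genome_id = c(gids, gids),
    start = c(m1start, m2start),
    strand = c(m1strand, m2strand),
    n_errors = sim$nerr,
    stringsAsFactors = FALSE)
  new("ReadSet", mate1 = m1, mate2 = m2, truth = truth)
}
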