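#' @include assembly.R
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG")

# ORFs on one oriented strand: list of (start, end) 1-based on that
# strand, start codon ATG/GTG, ending at a stop codon
orfScanStrand <- function(seqChar, minLenAA) {
  L <- nchar(seqChar)
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, L - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(seqChar, starts, starts + 2L)
    isStop <- codons %in% STOP_CODONS
    isStart <- codons %in% START_CODONS
    regionStart <- NA_integer_   # index into codons of the first start codon
    for (i in seq_along(codons)) {
      if (isStop[i]) {
        if (!is.na(regionStart) && (i - regionStart) >= minLenAA) {
          out[[length(out) + 1L]] <- c(starts[regionStart],
                                       starts[i] + 2L)
        }
        regionStart <- NA_integer_
      } else if (is.na(regionStart) && isStart[i]) {
        regionStart <- i
      }
    }
    # open regions at the sequence end are dropped (stop-to-stop bounded)
  }
  out
}

#' Find open reading frames
#'
#' Scans both strands for ORFs starting at ATG or GTG and ending at a
#' stop codon, translates them (alternative starts become M), and
#' returns the proteins ordered by genomic position.
#'
#' @param genome a [Genome-class] (or sequence).
#' @param minLenAA minimum protein length in residues (default 60,
#'   excluding the stop).
#' @return [Biostrings::AAStringSet] named `<genome>_orf<N>` with
#'   metadata columns start, end, strand (forward-strand 1-based
#'   coordinates of the ORF including the stop codon).
#' @export
findORFs <- function(genome, minLenAA = 60L) {
  s <- toupper(seqChar(genome))
  checkNucleotides(s, "genome")
  id <- seqId(genome, "genome")
  L <- nchar(s)
  fwd <- orfScanStrand(s, minLenAA)
  rev <- orfScanStrand(revcompChar(s), minLenAA)
  coords <- rbind(
    if (length(fwd)) data.frame(start = vapply(fwd, `[`, 0, 1L),
                                end = vapply(fwd, `[`, 0, 2L),
                                strand = "+") else NULL,
    if (length(rev)) data.frame(start = L - vapply(rev, `[`, 0, 2L) + 1L,
                                end = L - vapply(rev, `[`, 0, 1L) + 1L,
                                strand = "-") else NULL)
  if (is.null(coords) || nrow(coords) == 0L) {
    return(Biostrings::AAStringSet())
  }
  coords <- coords[order(coords$start, coords$end), , drop = FALSE]
  prots <- vapply(seq_len(nrow(coords)), function(i) {
    nt <- substr(s, coords$start[i], coords$end[i])
    if (coords$strand[i] == "-") nt <- revcompChar(nt)
    nt <- substr(nt, 1L, nchar(nt) - 3L)   # drop the stop codon
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    paste0("M", substr(aa, 2L, nchar(aa)))  # alternative starts as M
  }, character(1L))
  out <- Biostrings::AAStringSet(prots)
  names(out) <- sprintf("%s_orf%d", id, seq_along(out))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    start = as.integer(coords$start), end = as.integer(coords$end),
    strand = coords$strand)
  out
}

#' Six-frame translation of a genome
#'
#' Stop-to-stop fragments from all six frames, for peptide matching
#' against unannotated sequence.
#'
#' @param genome a [Genome-class] (or sequence).
#' @param minLenAA minimum fragment length in residues (default 20).
#' @return [Biostrings::AAStringSet].
#' @export
sixFrameProteome <- function(genome, minLenAA = 20L) {
  s <- toupper(seqChar(genome))
  id <- seqId(genome, "genome")
  frags <- character()
  for (str in c(s, revcompChar(s))) {
    for (frame in 0:2) {
      sub <- substr(str, 1L + frame, nchar(str))
      sub <- substr(sub, 1L, 3L * (nchar(sub) %/% 3L))
      if (nchar(sub) < 3L) next
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
      parts <- strsplit(aa, "*", fixed = TRUE)[[1L]]
      frags <- c(frags, parts[nchar(parts) >= minLenAA])
    }
  }
  out <- Biostrings::AAStringSet(frags)
  if (length(out)) names(out) <- sprintf("%s_frame%d", id, seq_along(out))
  out
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when followed by P, and emits every
#' peptide spanning 0 to `maxMissedCleavages` internal retained
#' cleavage sites, deduplicated, with the minimum length applied.
#'
#' @param protein an [Biostrings::AAString] or character string using
#'   the 20 standard residues.
#' @param params a [DigestParams] object.
#' @return character vector of peptides (deterministic order: by start
#'   position, then length).
#' @examples
#' trypticDigest("GGKAARPCCKDD",
#'               digestParams(maxMissedCleavages = 0, minPeptideLength = 1))
#' @export
trypticDigest <- function(protein, params = digestParams()) {
  p <- toupper(if (is(protein, "AAString")) as.character(protein)
               else protein)
  if (!nzchar(p)) stop("protein is empty")
  bad <- gsub("[ACDEFGHIKLMNPQRSTVWY]", "", p)
  if (nzchar(bad))
    stop("protein contains non-standard residue '", substr(bad, 1, 1), "'")
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  cut <- which(chars %in% c("K", "R"))
  cut <- cut[cut < n & chars[pmin(cut + 1L, n)] != "P"]
  bounds <- c(0L, cut, n)
  peptides <- character()
  for (i in seq_len(length(bounds) - 1L)) {
    jmax <- min(i + 1L + params@maxMissedCleavages, length(bounds))
    for (j in (i + 1L):jmax) {
      peptides <- c(peptides, substr(p, bounds[i] + 1L, bounds[j]))
    }
  }
  peptides <- unique(peptides[nchar(peptides) >= params@minPeptideLength])
  peptides
}

#' Exact-match peptide recruitment
#'
#' Matches peptides against per-genome proteomes at 100\% identity and
#' full peptide coverage (exact substring), and normalizes per-genome
#' hit counts by genome size in kb.
#'
#' @param peptides character vector of peptides.
#' @param proteomes named list of [Biostrings::AAStringSet], one per
#'   genome (e.g. from [findORFs]); names are genome ids.
#' @param genomeLengths named integer vector of genome lengths in bp.
#' @return data.frame: peptide, genome_id, protein_id, position
#'   (1-based residue offset), normalized_count (genome-level hits per
#'   genome kb, repeated on each row). Zero rows (with a warning) for
#'   an empty peptide list.
#' @export
peptideRecruit <- function(peptides, proteomes, genomeLengths) {
  empty <- data.frame(peptide = character(), genome_id = character(),
                      protein_id = character(), position = integer(),
                      normalized_count = numeric(),
                      stringsAsFactors = FALSE)
  if (length(peptides) == 0L) {
    warning("empty peptide list; no recruitment possible")
    return(empty)
  }
  if (is.null(names(proteomes)) ||
      !all(names(proteomes) %in% names(genomeLengths)))
    stop("proteomes must be named by genome ids present in genomeLengths")
  rows <- list()
  for (gid in names(proteomes)) {
    prot <- proteomes[[gid]]
    if (length(prot) == 0L) next
    pchar <- as.character(prot)
    for (pep in unique(peptides)) {
      m <- gregexpr(pep, pchar, fixed = TRUE)
      for (k in seq_along(m)) {
        pos <- m[[k]]
        if (pos[1L] == -1L) next
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, genome_id = gid,
          protein_id = names(prot)[k] %||% sprintf("%s_p%d", gid, k),
          position = as.integer(pos), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  nHits <- table(out$genome_id)
  out$normalized_count <- as.numeric(nHits[out$genome_id]) /
    (genomeLengths[out$genome_id] / 1000)
  rownames(out) <- NULL
  out
}
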