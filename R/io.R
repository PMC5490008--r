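#' @include labqc.R
NULL

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "score",
                 "qcovs")

#' Read and write hit tables
#'
#' The on-disk hit table is a headerless 12-column TSV in the BLAST
#' tabular (outfmt-6 style) layout, except column 11 is the raw
#' alignment score (not an e-value) and column 12 is the query
#' coverage percent: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, score, qcovs. In-memory extras
#' (strand, cigar) are not serialized.
#'
#' @param hits a hit-table data.frame.
#' @param file path.
#' @return `writeHits` returns the path invisibly; `readHits` returns
#'   a data.frame with the 12 named columns.
#' @export
writeHits <- function(hits, file) {
  out <- hits[, HIT_COLUMNS, drop = FALSE]
  out$pident <- sprintf("%.3f", out$pident)
  out$qcovs <- sprintf("%.2f", out$qcovs)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname writeHits
#' @export
readHits <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = HIT_COLUMNS)
  df
}

#' Write a population to disk
#'
#' Serializes a [ViralPopulation-class] as a multi-FASTA plus plain
#' tables: mutations as TSV (genome_id, position, ref, alt), islands
#' as BED (0-based half-open), abundances as TSV.
#'
#' @param population a [ViralPopulation-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default "population").
#' @return named character vector of the written paths.
#' @export
writePopulation <- function(population, dir, prefix = "population") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- genomes(population)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  seqs <- Biostrings::DNAStringSet(vapply(gs, as.character, character(1L)))
  names(seqs) <- names(gs)
  Biostrings::writeXStringSet(seqs, fa)

  mutPath <- file.path(dir, paste0(prefix, "_mutations.tsv"))
  muts <- do.call(rbind, lapply(gs, function(g) {
    m <- mutations(g)
    if (nrow(m) == 0L) return(NULL)
    data.frame(genome_id = genomeId(g), position = m$pos, ref = m$ref,
               alt = m$alt, stringsAsFactors = FALSE)
  }))
  if (is.null(muts))
    muts <- data.frame(genome_id = character(), position = integer(),
                       ref = character(), alt = character())
  utils::write.table(muts, mutPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  bedPath <- file.path(dir, paste0(prefix, "_islands.bed"))
  beds <- do.call(rbind, lapply(gs, function(g) {
    isl <- islands(g)
    if (length(isl) == 0L) return(NULL)
    data.frame(chrom = genomeId(g), start = IRanges::start(isl) - 1L,
               end = IRanges::end(isl), stringsAsFactors = FALSE)
  }))
  if (is.null(beds))
    beds <- data.frame(chrom = character(), start = integer(),
                       end = integer())
  utils::write.table(beds, bedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  abPath <- file.path(dir, paste0(prefix, "_abundances.tsv"))
  ab <- abundances(population)
  utils::write.table(
    data.frame(genome_id = names(ab), abundance = unname(ab)),
    abPath, sep = "\t", quote = FALSE, row.names = FALSE)

  c(fasta = fa, mutations = mutPath, islands = bedPath, abundances = abPath)
}

#' Write a read set as paired FASTQ plus a truth table
#'
#' @param readSet a [ReadSet-class].
#' @param dir output directory.
#' @param prefix file name prefix (default "reads").
#' @return named character vector of the written paths.
#' @export
writeReadSet <- function(readSet, dir, prefix = "reads") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    R1 = file.path(dir, paste0(prefix, "_R1.fastq")),
    R2 = file.path(dir, paste0(prefix, "_R2.fastq")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  writeFq <- function(x, path) {
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
    names(quals) <- names(x)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  }
  writeFq(mate1(readSet), paths[["R1"]])
  writeFq(mate2(readSet), paths[["R2"]])
  utils::write.table(truthTable(readSet), paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
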