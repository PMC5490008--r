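# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# deterministic per-stage / per-iteration seed derivation; stays < 2^31
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * index) %% 2147483647L)
}

# coerce the various sequence carriers to a plain character string
seqChar <- function(x) {
  if (is(x, "Genome")) return(as.character(genomeSeq(x)))
  if (is(x, "XString")) return(as.character(x))
  if (is.character(x) && length(x) == 1L) return(x)
  stop("cannot interpret object of class '", class(x)[1L],
       "' as a single nucleotide sequence")
}

# id for error messages / hit tables
seqId <- function(x, fallback) {
  if (is(x, "Genome")) return(genomeId(x))
  nm <- names(x)
  if (!is.null(nm) && nzchar(nm[1L])) return(nm[1L])
  fallback
}

checkNucleotides <- function(seq, what = "sequence", allow_n = TRUE) {
  if (!nzchar(seq)) stop(what, " is empty")
  alphabet <- if (allow_n) "ACGTNacgtn" else "ACGTacgt"
  bad <- gsub(sprintf("[%s]", alphabet), "", seq)
  if (nzchar(bad)) {
    stop(what, " contains non-nucleotide character '",
         substr(bad, 1L, 1L), "'")
  }
  invisible(TRUE)
}

revcompChar <- function(x) {
  if (length(x) == 0L) return(character())
  unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x))))
}

emptyMutationTable <- function() {
  data.frame(pos = integer(), ref = character(), alt = character(),
             type = character(), stringsAsFactors = FALSE)
}
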