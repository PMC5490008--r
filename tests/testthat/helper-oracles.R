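# Independent brute-force oracles shared across test files.

# tryptic digestion by enumeration over cleavage-site subsets
bruteDigest <- function(protein, maxMissed, minLen) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cut <- which(ch %in% c("K", "R"))
  cut <- cut[cut < n & ch[cut + 1L] != "P"]
  bounds <- c(0L, cut, n)
  peps <- character()
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in seq_len(length(bounds))[-seq_len(i)]) {
      if ((j - i - 1L) > maxMissed) next
      peps <- c(peps, substr(protein, bounds[i] + 1L, bounds[j]))
    }
  }
  sort(unique(peps[nchar(peps) >= minLen]))
}
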