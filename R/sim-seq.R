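# Sequence helpers for the simulator. Sequences are plain uppercase
# character strings internally; Biostrings handles FASTA I/O.

random_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# stop-free coding sequence of n_codons codons
random_cds <- function(n_codons) {
  paste(sample(.SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""), "",
    USE.NAMES = FALSE))
}

# per-base substitution at `rate`; returns the mutated string
mutate_seq <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(.BASES, b), 1), "")
    s <- paste(v, collapse = "")
  }
  s
}

# mutate a CDS at `rate` without creating internal stop codons: any
# codon turned into a stop reverts its mutated bases
mutate_cds <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0) return(s)
  v0 <- strsplit(s, "", fixed = TRUE)[[1]]
  v <- v0
  hit <- which(runif(length(v)) < rate)
  if (!length(hit)) return(s)
  v[hit] <- vapply(v[hit], function(b) sample(setdiff(.BASES, b), 1), "")
  nc <- length(v) %/% 3
  cod <- paste0(v[3 * seq_len(nc) - 2], v[3 * seq_len(nc) - 1],
                v[3 * seq_len(nc)])
  bad <- which(cod %in% .STOPS)
  for (k in bad) {
    idx <- (3 * k - 2):(3 * k)
    v[idx] <- v0[idx]
  }
  paste(v, collapse = "")
}
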