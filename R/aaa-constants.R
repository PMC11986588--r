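# Shared alphabet/codon constants (file named to load first).

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- local({
  all3 <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  setdiff(all3, .STOPS)
})
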