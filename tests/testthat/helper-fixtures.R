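# Shared small fixture (built once per test run, cached in an env).

.fixture_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 7L, ...) {
  sim_config(seed = seed, chroms_per_subgenome = 1L, chrom_length = 100000L,
             n_genes = 30L, n_tes = 40L, n_captures = 10L,
             sirna_library_size = 5000L, depth = 15, ...)
}

# genome + planted captures at small scale, memoised
small_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    g <- generate_genome(small_config())
    .fixture_cache$fx <- plant_captures(g)
  }
  .fixture_cache$fx
}

# tiny two-isoform GFF3 written to a temp file
write_two_isoform_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chrA01\t.\tgene\t101\t1000\t.\t+\t.\tID=g1",
    "chrA01\t.\tmRNA\t101\t1000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrA01\t.\texon\t101\t300\t.\t+\t.\tParent=g1.t1",
    "chrA01\t.\texon\t501\t1000\t.\t+\t.\tParent=g1.t1",
    "chrA01\t.\tmRNA\t101\t1000\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chrA01\t.\texon\t101\t200\t.\t+\t.\tParent=g1.t2"), path)
  path
}
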