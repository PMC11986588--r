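test_that("genome generation is deterministic and well-formed", {
  cfg <- small_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- generate_genome(cfg, d1)
  g2 <- generate_genome(cfg, d2)
  for (f in c("genome.fa", "genes.gff3", "tes.gff3", "pseudogenes.bed",
              "homoeologs.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  expect_equal(names(g1$seqs), c("chrA01", "chrC01"))
  cfg2 <- sim_config(chroms_per_subgenome = 2, n_genes = 40, n_tes = 40,
                     chrom_length = 200000)
  gg <- generate_genome(cfg2)
  expect_equal(names(gg$seqs), c("chrA01", "chrA02", "chrC01", "chrC02"))
  # homoeolog table has the configured number of 1:1 pairs
  n_pairs <- round(cfg$homoeolog_fraction * (cfg$n_genes %/% 2))
  expect_equal(nrow(g1$homoeologs), n_pairs)
  expect_false(anyDuplicated(g1$homoeologs$gene_an) > 0)
  expect_false(anyDuplicated(g1$homoeologs$gene_cn) > 0)
  # genes and TEs never physically intersect by construction
  expect_equal(exclude_overlaps(g1$models, g1$tes)$removed_genes, 0L)
})

test_that("gene models written by the simulator re-read identically", {
  fx <- small_fixture()
  d <- withr::local_tempdir()
  write_genome_set(fx$genome, d)
  gm <- read_gene_models(file.path(d, "genes.gff3"))
  expect_equal(gm$genes, fx$genome$models$genes)
  expect_equal(gm$exons, fx$genome$models$exons)
  tes <- read_te_annotations(file.path(d, "tes.gff3"))
  expect_equal(tes$te_id, fx$genome$tes$te_id)
  expect_equal(tes$start, fx$genome$tes$start)
})

test_that("planted fragments are exact at zero divergence", {
  cfg <- small_config(divergence = 0)
  pc <- plant_captures(generate_genome(cfg))
  tr <- pc$truth
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    te <- pc$genome$tes[pc$genome$tes$te_id == tr$te_id[i], ]
    te_seq <- helicap:::te_sequence(pc$genome, te)
    planted <- substr(te_seq, tr$te_local_start[i] + 1, tr$te_local_end[i])
    ex <- pc$genome$models$exons
    ex <- ex[ex$gene_id == tr$gene_id[i] & ex$exon_index == tr$exon_index[i], ]
    gene_frag <- helicap:::genome_seq(pc$genome, tr$chrom[i],
                                      tr$frag_start[i], tr$frag_end[i],
                                      ex$strand)
    expect_identical(planted, gene_frag)
    expect_equal(tr$divergence_applied[i], 0)
  }
})

test_that("capture multiplicity and divergence follow the config", {
  cfg0 <- small_config(multi_capture_fraction = 0)
  tr0 <- plant_captures(generate_genome(cfg0))$truth
  expect_true(all(table(tr0$te_id) == 1))
  cfg <- sim_config(seed = 3)   # default: 60 captures at 5% divergence
  tr <- plant_captures(generate_genome(cfg))$truth
  expect_equal(nrow(tr), 60L)
  expect_equal(mean(tr$divergence_applied), 0.05, tolerance = 0.4)
  expect_true(abs(mean(tr$divergence_applied) - 0.05) < 0.02)
  # fragment lengths within the configured bounds
  expect_true(all(tr$length >= cfg$fragment_length_min))
  expect_true(all(tr$length <= cfg$fragment_length_max))
  # multi TEs exist at the configured share
  n_loci <- table(tr$te_id)
  expect_gt(mean(n_loci >= 2), 0.2)
})

test_that("simulated methylomes and siRNA libraries satisfy the contracts", {
  fx <- small_fixture()
  d <- withr::local_tempdir()
  epi <- simulate_epigenomes(fx$genome, fx$truth, d)
  expect_length(epi$cx, 9L)
  rec <- read_cx_report(epi$cx[["NAC_rep1"]])
  expect_true(all(rec$n_meth <= rec$n_total))
  expect_true(all(rec$context %in% c("CG", "CHG", "CHH")))
  reads <- read_sirna_bed(epi$sirna[["AC_rep1"]])
  expect_true(all(reads$read_length == 24L))
  # RAC relaxation shows up as lower TE methylation than NAC
  rec_rac <- read_cx_report(epi$cx[["RAC_rep1"]])
  te_feat <- data.frame(chrom = fx$genome$tes$chrom,
                        start = fx$genome$tes$start,
                        end = fx$genome$tes$end)
  cap <- fx$genome$tes$te_id %in% fx$truth$te_id
  m_nac <- methylation_level(te_feat[cap, ], rec, "CG")
  m_rac <- methylation_level(te_feat[cap, ], rec_rac, "CG")
  expect_equal(mean(m_rac, na.rm = TRUE) / mean(m_nac, na.rm = TRUE),
               fx$genome$config$rac_relaxation, tolerance = 0.08)
})

test_that("expression counts are seeded NB with the donor fold ladder", {
  fx <- small_fixture()
  cm1 <- simulate_expression(fx$genome, fx$truth)
  cm2 <- simulate_expression(fx$genome, fx$truth)
  expect_identical(cm1$counts, cm2$counts)
  expect_true(all(cm1$counts >= 0))
  expect_error(simulate_expression(
    fx$genome, fx$truth), NA)
  cfg_bad <- small_config()
  cfg_bad$nb_dispersion <- -1
  expect_error(simulate_expression(
    structure(list(config = cfg_bad), class = "genome_set"), fx$truth),
    "nb_dispersion")
  # null fold ladder removes the genotype effect on donors
  g0 <- fx$genome
  g0$config$expression_fold_ladder <- c(AC = 1, RAC = 1, NAC = 1)
  cm0 <- simulate_expression(g0, fx$truth)
  donors <- rownames(cm0$counts) %in% fx$truth$gene_id
  m_ac <- rowMeans(cm0$counts[donors, cm0$samples$genotype == "AC"])
  m_nac <- rowMeans(cm0$counts[donors, cm0$samples$genotype == "NAC"])
  expect_equal(mean(log2((m_nac + 1) / (m_ac + 1))), 0, tolerance = 0.3)
  # and the default ladder raises donor counts NAC > AC
  m_ac1 <- rowMeans(cm1$counts[donors, cm1$samples$genotype == "AC"])
  m_nac1 <- rowMeans(cm1$counts[donors, cm1$samples$genotype == "NAC"])
  expect_gt(median(log2((m_nac1 + 1) / (m_ac1 + 1))), 0.5)
})

test_that("configs round-trip through YAML", {
  cfg <- small_config(divergence = 0.02)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, p)
  cfg2 <- read_sim_config(p)
  expect_equal(cfg2[order(names(cfg2))], cfg[order(names(cfg))])
})
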