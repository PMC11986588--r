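char_models <- function() {
  genes <- data.frame(gene_id = "g1", chrom = "chrA01", start = 1000L,
                      end = 2000L, strand = "+", subgenome = "An")
  exons <- data.frame(gene_id = "g1", exon_index = 1L, chrom = "chrA01",
                      start = 1000L, end = 2000L, strand = "+")
  sf <- data.frame(gene_id = "g1",
                   kind = c("five_prime_UTR", "CDS", "three_prime_UTR"),
                   chrom = "chrA01", start = c(1000L, 1200L, 1800L),
                   end = c(1200L, 1800L, 2000L), strand = "+")
  structure(list(genes = genes, exons = exons, subfeatures = sf),
            class = "gene_models")
}

char_event <- function(fs, fe) {
  data.frame(event_id = "ev_0001", te_id = "t1", locus = 1L,
             donor_gene_id = "g1", exon_index = 1L, chrom = "chrA01",
             frag_start = fs, frag_end = fe, te_start = 0L,
             te_end = fe - fs, raw_score = 100L, bit_score = 100,
             evalue = 1e-50, identity = 1, captured_length = fe - fs,
             is_tie = FALSE)
}

test_that("captured regions are typed UTR, CDS or mixed by majority", {
  m <- char_models()
  expect_equal(classify_captured_region(char_event(1000L, 1150L),
                                        m)$region_kind, "UTR")
  expect_equal(classify_captured_region(char_event(1300L, 1700L),
                                        m)$region_kind, "CDS")
  # 100 bp of UTR and 100 bp of CDS: below the 80% majority
  expect_equal(classify_captured_region(char_event(1100L, 1300L),
                                        m)$region_kind, "mixed")
  # a UTR-leaning fragment becomes classifiable at a permissive threshold
  expect_equal(classify_captured_region(char_event(1080L, 1280L),
                                        m)$region_kind, "mixed")
  expect_equal(classify_captured_region(char_event(1080L, 1280L), m,
                                        majority = 0.5)$region_kind, "UTR")
  expect_error(classify_captured_region(char_event(5000L, 5100L), m),
               "outside the exons")
})

test_that("positional classes partition the classifiable events", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      chrom = c("chrA01", "chrA01", "chrA02", "scaffold_1"),
                      start = c(13000L, 50000L, 1000L, 100L),
                      end = c(14000L, 51000L, 2000L, 600L),
                      strand = "+",
                      subgenome = c("An", "An", "An", "other"))
  tes <- data.frame(te_id = c("t1", "t2", "t3", "t4"),
                    chrom = c("chrA01", "chrA01", "chrC01", "chrA01"),
                    start = c(10000L, 10000L, 1000L, 1000L),
                    end = c(12000L, 12000L, 2000L, 1500L),
                    strand = "+", superfamily = "Helitron",
                    length = c(2000L, 2000L, 1000L, 500L))
  mk <- function(te, gene) data.frame(event_id = paste0(te, gene),
                                      te_id = te, donor_gene_id = gene)
  ev <- rbind(mk("t1", "g1"),   # gap 1000 -> NEAR
              mk("t2", "g2"),   # gap 38000 -> SAME_CHROM_FAR
              mk("t1", "g3"),   # A01 vs A02 -> SAME_SUBGENOME_DIFF_CHROM
              mk("t3", "g1"),   # C vs A -> DIFF_SUBGENOME
              mk("t4", "g4"))   # scaffold -> excluded
  r <- positional_class(ev, tes, genes)
  expect_equal(unname(as.integer(r$class_counts)), c(1L, 1L, 1L, 1L))
  expect_equal(r$n_excluded, 1L)
  expect_equal(nrow(r$events) + r$n_excluded, nrow(ev))
})

test_that("density tracks conserve counts and bin by midpoint", {
  f <- data.frame(chrom = "chrA01",
                  start = c(0L, 150L, 199L, 200L, 950L),
                  end = c(100L, 250L, 201L, 300L, 1000L))
  d <- feature_density(f, c(chrA01 = 1000L), window = 200L)
  expect_equal(sum(d$count), nrow(f))
  # midpoints 50,200,200,250,975: boundary midpoint 200 goes right
  expect_equal(d$count, c(1L, 3L, 0L, 0L, 1L))
  expect_equal(feature_density(data.frame(chrom = character(),
                                          start = integer(),
                                          end = integer()),
                               c(chrA01 = 1000L), 200L)$count, rep(0L, 5))
  expect_error(feature_density(data.frame(chrom = "chrA01", start = 0L,
                                          end = 2000L),
                               c(chrA01 = 1000L), 200L), "beyond")
})

test_that("GC content excludes N from the denominator", {
  expect_equal(gc_content(c("GGCC", "ATGC", "ANGC")), c(1, 0.5, 2 / 3))
  expect_true(is.na(gc_content("NNN")))
  expect_true(is.na(gc_content("")))
})

test_that("pseudogene overlap uses >= 1 bp intersection", {
  tes <- data.frame(te_id = c("t1", "t2"), chrom = "chrA01",
                    start = c(100L, 100L), end = c(200L, 200L))
  pg1 <- data.frame(chrom = "chrA01", start = 150L, end = 160L)
  pg2 <- data.frame(chrom = "chrA01", start = 200L, end = 300L)
  expect_equal(pseudogene_overlap(tes[1, ], pg1)$fraction, 1)
  expect_equal(pseudogene_overlap(tes[1, ], pg2)$fraction, 0)
  expect_equal(pseudogene_overlap(tes, pg1)$n_overlapping, 2L)
})

test_that("donor vs sampled-free exon statistics are seeded and sound", {
  fx <- small_fixture()
  models <- fx$genome$models
  ids <- models$genes$gene_id
  donors <- ids[1:8]; free <- ids[9:length(ids)]
  r1 <- donor_vs_free_exon_stats(models, donors, free, seed = 11)
  r2 <- donor_vs_free_exon_stats(models, donors, free, seed = 11)
  expect_identical(r1$sampled_free_ids, r2$sampled_free_ids)
  r3 <- donor_vs_free_exon_stats(models, donors, free, seed = 12)
  expect_false(identical(r1$sampled_free_ids, r3$sampled_free_ids))
  # same population on both sides: no rejection expected
  expect_gt(r1$p_exon_length, 0.001)
  expect_error(donor_vs_free_exon_stats(models, ids, ids[1:3], 1),
               "fewer free genes")
})

test_that("count-length correlation flags degenerate input", {
  lens <- c(a = 10e6, b = 20e6, c = 30e6, d = 40e6)
  cnt <- c(a = 10, b = 20, c = 30, d = 40)
  r <- count_length_correlation(cnt, lens)
  expect_equal(r$statistic, 1)
  expect_lt(r$p_value, 0.05)
  r0 <- count_length_correlation(c(a = 5, b = 5, c = 5, d = 5), lens)
  expect_true(r0$degenerate)
  expect_error(count_length_correlation(cnt[1:2], lens[1:2]), "3 chromosomes")
})
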