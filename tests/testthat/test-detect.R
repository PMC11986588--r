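make_models <- function(genes, exons = NULL) {
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, exon_index = 1L,
                        chrom = genes$chrom, start = genes$start,
                        end = genes$end, strand = genes$strand)
  }
  structure(list(genes = genes, exons = exons,
                 subfeatures = helicap:::empty_gene_models()$subfeatures),
            class = "gene_models")
}

test_that("physical-intersection filtering removes both members", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = c("chrA01", "chrA01", "chrC01"),
                      start = c(100L, 300L, 100L), end = c(200L, 400L, 200L),
                      strand = "+", subgenome = c("An", "An", "Cn"))
  tes <- data.frame(te_id = c("t1", "t2", "t3"),
                    chrom = c("chrA01", "chrA01", "chrA01"),
                    start = c(150L, 400L, 5000L), end = c(250L, 500L, 6000L),
                    strand = "+", superfamily = "Helitron",
                    length = c(100L, 100L, 1000L))
  r <- exclude_overlaps(make_models(genes), tes)
  # g1 and t1 overlap -> both gone; g2/t2 abut half-open -> both kept;
  # g3 is on another chromosome -> kept
  expect_setequal(r$models$genes$gene_id, c("g2", "g3"))
  expect_setequal(r$tes$te_id, c("t2", "t3"))
  expect_equal(r$removed_genes, 1L)
  expect_equal(r$removed_tes, 1L)
})

test_that("donor assignment picks the highest bit score and keeps ties", {
  hits <- data.frame(
    te_id = c("t1", "t1", "t2", "t2", "t3", "t3"),
    gene_id = c("g1", "g2", "g1", "g2", "g1", "g1"),
    exon_index = c(1L, 1L, 1L, 1L, 1L, 2L),
    raw_score = c(120L, 90L, 100L, 100L, 80L, 80L),
    bit_score = c(120, 90, 100, 100, 80, 80),
    evalue = c(1e-50, 1e-45, 1e-48, 1e-48, 1e-44, 1e-44),
    te_start = c(10L, 20L, 10L, 15L, 100L, 500L),
    te_end = c(110L, 100L, 110L, 105L, 180L, 580L),
    exon_start = 0L, exon_end = c(100L, 80L, 100L, 90L, 80L, 80L),
    identity = 1)
  exon_tab <- data.frame(gene_id = c("g1", "g1", "g2"),
                         exon_index = c(1L, 2L, 1L),
                         chrom = "chrA01", start = c(1000L, 3000L, 5000L),
                         end = c(2000L, 4000L, 6000L),
                         strand = c("+", "+", "-"))
  ev <- assign_donors(hits, exon_tab)
  # t1: one locus, g1 wins outright
  e1 <- ev[ev$te_id == "t1", ]
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$donor_gene_id, "g1")
  expect_false(e1$is_tie)
  # t2: identical bit scores -> both genes retained as tied events
  e2 <- ev[ev$te_id == "t2", ]
  expect_equal(nrow(e2), 2L)
  expect_true(all(e2$is_tie))
  # t3: two disjoint loci of the same gene -> two events (multi-capture)
  e3 <- ev[ev$te_id == "t3", ]
  expect_equal(nrow(e3), 2L)
  expect_equal(sort(unique(e3$locus)), c(1L, 2L))
  # genomic fragment mapping honours strand: g2 exon is on minus
  expect_equal(e2$frag_start[e2$donor_gene_id == "g2"], 6000 - 90)
  # multiplicity classification
  mult <- classify_capture_multiplicity(ev)
  expect_equal(mult$per_te$class[mult$per_te$te_id == "t3"], "multiple")
  expect_equal(mult$summary$n_single, 2L)
  expect_equal(mult$summary$prop_multiple, 1 / 3)
})

test_that("a TE hitting two exons of one gene at one locus gives one event", {
  hits <- data.frame(te_id = "t1", gene_id = "g1", exon_index = c(1L, 2L),
                     raw_score = c(100L, 90L), bit_score = c(100, 90),
                     evalue = c(1e-48, 1e-45),
                     te_start = c(10L, 50L), te_end = c(110L, 140L),
                     exon_start = 0L, exon_end = c(100L, 90L), identity = 1)
  exon_tab <- data.frame(gene_id = "g1", exon_index = 1:2, chrom = "chrA01",
                         start = c(1000L, 3000L), end = c(2000L, 4000L),
                         strand = "+")
  ev <- assign_donors(hits, exon_tab)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$exon_index, 1L)
})

test_that("planted captures are recovered on the small fixture", {
  fx <- small_fixture()
  catalog <- detect_captures(fx$genome)
  truth <- fx$truth
  ov <- function(ev, i) ev[ev$te_id == truth$te_id[i] &
                           pmax(ev$te_start, truth$te_local_start[i]) <
                           pmin(ev$te_end, truth$te_local_end[i]), ]
  recovered <- vapply(seq_len(nrow(truth)), function(i)
    nrow(ov(catalog$events, i)) > 0, TRUE)
  expect_gte(mean(recovered), 0.9)
  # every recovered event names the true donor (ties count if present)
  for (i in which(recovered))
    expect_true(truth$gene_id[i] %in% ov(catalog$events, i)$donor_gene_id)
  # catalog partitions the TE universe
  expect_length(intersect(catalog$capturing_te_ids, catalog$free_te_ids), 0)
  expect_true(all(catalog$donor_gene_ids %in% catalog$captured_gene_ids))
})

test_that("the k-mer prefilter does not change the event set", {
  fx <- small_fixture()
  filt <- exclude_overlaps(fx$genome$models, fx$genome$tes)
  exon_tab <- helicap:::exon_sequence_table(fx$genome, filt$models)
  te_seqs <- setNames(vapply(seq_len(nrow(filt$tes)), function(i)
    helicap:::te_sequence(fx$genome, filt$tes[i, ]), ""), filt$tes$te_id)
  h_on <- scan_captures(te_seqs, exon_tab, kmer_prefilter = TRUE)
  h_off <- scan_captures(te_seqs, exon_tab, kmer_prefilter = FALSE)
  key <- function(h) sort(paste(h$te_id, h$gene_id, h$exon_index, h$raw_score))
  expect_identical(key(h_on), key(h_off))
})

test_that("short perfect matches cannot pass the default screen", {
  # a 30-bp perfect match scores 30; with lambda ~1.33, K ~0.62 that is
  # ~57 bits, and E = m*n*2^-57 stays far above 1e-40 for any fixture
  sch <- scoring_scheme()
  st <- hit_statistics(30, m = 2000, n = 2e5, sch)
  expect_gt(st$evalue, 1e-40)
  # whereas a 100-bp perfect match passes comfortably
  expect_lt(hit_statistics(100, m = 2000, n = 2e5, sch)$evalue, 1e-40)
})
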