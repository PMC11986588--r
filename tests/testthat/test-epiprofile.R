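cx_records <- function(chrom, pos, n_meth, n_total, context = "CG",
                       strand = "+") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, context = context,
                         n_meth = as.integer(n_meth),
                         n_total = as.integer(n_total))
}

test_that("siRNA filtering keeps 24-nt reads outside exclusion zones", {
  reads <- data.frame(chrom = "chrA01", start = c(0L, 100L, 200L),
                      end = c(21L, 124L, 224L),
                      name = c("r1", "r2", "r3"), copies = 1L, strand = "+",
                      read_length = c(21L, 24L, 24L))
  excl <- data.frame(chrom = "chrA01", start = 110L, end = 130L)
  r <- filter_sirna_reads(reads, excl)
  expect_equal(r$reads$name, "r3")
  expect_equal(unname(r$log), c(1L, 1L, 1L))
})

test_that("in-silico hybrid mixes parents 1:1", {
  mk <- function(n, ch) data.frame(chrom = ch, start = seq_len(n) * 30L,
                                   end = seq_len(n) * 30L + 24L,
                                   name = sprintf("%s%d", ch, seq_len(n)),
                                   copies = 1L, strand = "+",
                                   read_length = 24L)
  a <- mk(1000, "chrA01"); c_ <- mk(2000, "chrC01")
  h <- make_in_silico_hybrid(a, c_, seed = 4)
  expect_equal(sum(h$copies), 2000L)
  expect_equal(sum(h$copies[h$chrom == "chrA01"]), 1000L)
  expect_equal(sum(h$copies[h$chrom == "chrC01"]), 1000L)
  # equal sizes: pure union; same seed: identical result
  h2 <- make_in_silico_hybrid(a, a, seed = 1)
  expect_equal(sum(h2$copies), 2000L)
  expect_identical(make_in_silico_hybrid(a, c_, seed = 4), h)
  expect_error(make_in_silico_hybrid(a[0, ], c_), "empty")
})

test_that("RPM is the midpoint-count rate per million", {
  feats <- data.frame(chrom = "chrA01", start = 1000L, end = 2000L)
  reads <- data.frame(chrom = "chrA01",
                      start = c(1100L, 1500L, 1990L, 2100L),
                      end = c(1124L, 1524L, 2014L, 2124L),
                      copies = c(1L, 2L, 1L, 5L))
  # midpoints 1112, 1512, 2002, 2112 -> first two inside (3 copies)
  expect_equal(rpm_quantify(feats, reads, 2000L), 3 / 2000 * 1e6)
  expect_equal(rpm_quantify(feats, reads[0, ], 2000L), 0)
  expect_error(rpm_quantify(feats, reads, 0), "library_size")
  # overlap rule counts the read straddling the boundary too
  expect_equal(rpm_quantify(feats, reads, 1e6, rule = "overlap"), 4)
  # doubling every copy and the library leaves RPM unchanged
  reads2 <- reads; reads2$copies <- reads$copies * 2L
  expect_equal(rpm_quantify(feats, reads2, 4000L),
               rpm_quantify(feats, reads, 2000L))
})

test_that("TPM normalizes length-corrected rates to a million", {
  cm <- structure(list(
    counts = matrix(c(10L, 20L, 0L, 0L), 2,
                    dimnames = list(c("g1", "g2"), NULL)),
    samples = data.frame(genotype = c("AC", "AC"), replicate = 1:2),
    lengths = c(g1 = 1000L, g2 = 2000L), feature_ids = c("g1", "g2")),
    class = "count_matrix")
  r <- tpm_normalize(cm)
  expect_equal(unname(r$tpm[, 1]), c(5e5, 5e5))
  expect_equal(r$zero_samples, colnames(cm$counts)[2])
  fx_cm <- simulate_expression(small_fixture()$genome, small_fixture()$truth)
  tt <- tpm_normalize(fx_cm)
  expect_equal(unname(colSums(tt$tpm)), rep(1e6, ncol(tt$tpm)),
               tolerance = 1e-9)
})

test_that("methylation levels are count-weighted, not cytosine-averaged", {
  feats <- data.frame(chrom = "chrA01", start = 0L, end = 100L)
  rec <- cx_records("chrA01", c(10, 20), c(1, 0), c(1, 9))
  expect_equal(methylation_level(feats, rec, "CG"), 10)
  expect_true(is.na(methylation_level(feats, rec, "CHH")))
  # pooled-partition property: level of the whole equals the level
  # computed from pooled counts of any split
  rec2 <- cx_records("chrA01", seq(5, 95, 10), rbinom(10, 5, 0.4),
                     rep(5L, 10))
  whole <- methylation_level(feats, rec2, "CG")
  halves <- data.frame(chrom = "chrA01", start = c(0L, 50L),
                       end = c(50L, 100L))
  ha <- methylation_level(halves, rec2, "CG")
  pooled <- sum(rec2$n_meth) / sum(rec2$n_total) * 100
  expect_equal(whole, pooled)
  w <- c(sum(rec2$n_total[rec2$pos < 50]), sum(rec2$n_total[rec2$pos >= 50]))
  expect_equal(sum(ha * w) / sum(w), whole)
})

test_that("metaprofiles separate flank and body signal and flip strand", {
  feats <- data.frame(chrom = "chrA01", start = 4000L, end = 6000L,
                      strand = "+")
  pos <- seq(2000, 7999, 7)
  rec <- cx_records("chrA01", pos, ifelse(pos < 4000 | pos >= 6000, 10L, 0L),
                    10L)
  mp <- metaprofile(feats, rec, "CG", flank = 2000L, bins_per_region = 10L)
  expect_equal(nrow(mp), 30L)
  expect_equal(mean(mp$level[mp$region == "body"]), 0)
  expect_equal(mean(mp$level[mp$region == "upstream"]), 100)
  # uniform methylome: flat profile
  rec50 <- cx_records("chrA01", pos, 5L, 10L)
  mp50 <- metaprofile(feats, rec50, "CG", 2000L, 10L)
  expect_true(all(abs(mp50$level - 50) < 1e-9))
  # a 5'-biased signal reads the same for plus and minus features
  grad <- as.integer(round(10 * (7999 - pos) / 6000))
  rec_g <- cx_records("chrA01", pos, grad, 10L)
  mp_plus <- metaprofile(feats, rec_g, "CG", 2000L, 10L)
  feats_m <- transform(feats, strand = "-")
  grad_m <- as.integer(round(10 * (pos - 2000) / 6000))
  mp_minus <- metaprofile(feats_m, cx_records("chrA01", pos, grad_m, 10L),
                          "CG", 2000L, 10L)
  expect_lt(max(abs(mp_plus$level - mp_minus$level)), 4)
})

test_that("methylation histogram uses closed-right last bin", {
  h <- methylation_histogram(c(0, 5, 15, 95, 100, NA))
  expect_equal(unname(h$counts[c(1, 2, 10)]), c(2L, 1L, 2L))
  expect_equal(h$n_undefined, 1L)
  expect_equal(sum(h$proportions), 1)
})

test_that("TE-local intervals map to genomic coordinates by strand", {
  te_p <- data.frame(te_id = "t", chrom = "chrA01", start = 10000L,
                     end = 12000L, strand = "+", length = 2000L)
  te_m <- transform(te_p, strand = "-")
  expect_equal(te_local_to_genomic(te_p, 100L, 300L)[c("start", "end")],
               list(start = 10100L, end = 10300L))
  expect_equal(te_local_to_genomic(te_m, 100L, 300L)[c("start", "end")],
               list(start = 11700L, end = 11900L))
  expect_error(te_local_to_genomic(te_p, 100L, 2300L), "outside")
})

test_that("fragment pairs carry the planted crosstalk offset", {
  fx <- small_fixture()
  d <- withr::local_tempdir()
  epi <- simulate_epigenomes(fx$genome, fx$truth, d)
  rec <- read_cx_report(epi$cx[["NAC_rep1"]])
  reads <- read_sirna_bed(epi$sirna[["NAC_rep1"]])
  catalog <- detect_captures(fx$genome)
  pp <- fragment_pair_profile(catalog$events, fx$genome$tes, rec, reads,
                              sum(reads$copies))
  expect_equal(nrow(pp), nrow(catalog$events))
  # gene-side CHG exceeds the TE side by about crosstalk_delta (CHG is
  # unsaturated: TE baseline 65 + 20 stays below 100)
  dd <- pp$gene_chg - pp$te_chg
  expect_equal(mean(dd, na.rm = TRUE), fx$genome$config$crosstalk_delta,
               tolerance = 0.25)
  expect_gt(mean(dd > 0, na.rm = TRUE), 0.9)
  # CG saturates but the direction is still recovered
  expect_gt(mean(pp$gene_cg - pp$te_cg > 0, na.rm = TRUE), 0.9)
})
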