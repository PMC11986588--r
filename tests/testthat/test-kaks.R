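test_that("NG86 counts behave on canonical cases", {
  s <- "ATGGCTAAA"
  r <- ng86_sites_and_diffs(s, s)
  expect_equal(r$Sd, 0); expect_equal(r$Nd, 0)
  expect_equal(r$S + r$N, 9)
  # one synonymous third-position change (GCT -> GCC, both Ala)
  r2 <- ng86_sites_and_diffs("ATGGCTAAA", "ATGGCCAAA")
  expect_equal(r2$Sd, 1); expect_equal(r2$Nd, 0)
  # one nonsynonymous first-position change (GCT Ala -> CCT Pro)
  r3 <- ng86_sites_and_diffs("ATGGCTAAA", "ATGCCTAAA")
  expect_equal(r3$Sd, 0); expect_equal(r3$Nd, 1)
  expect_error(ng86_sites_and_diffs("ATGTAAAAA", "ATGTAAAAA"),
               "internal stop")
  expect_error(ng86_sites_and_diffs("ATGGCT", "ATGGCTAAA"), "lengths differ")
})

test_that("pathway averaging conserves the number of differing positions", {
  set.seed(31)
  for (i in 1:25) {
    a <- random_codons(sample(2:5, 1))
    b <- mutate_uniform_cds(a, 0.3)
    r <- ng86_sites_and_diffs(a, b)
    ndiff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(r$Sd + r$Nd, ndiff, tolerance = 1e-9)
  }
})

test_that("NG86 equals the substitution-pathway enumeration oracle", {
  set.seed(17)
  for (i in 1:40) {
    a <- random_codons(sample(1:5, 1))
    b <- mutate_uniform_cds(a, 0.25)
    r <- ng86_sites_and_diffs(a, b)
    o <- ng86_oracle(a, b)
    expect_equal(r$S, o$S, tolerance = 1e-9)
    expect_equal(r$N, o$N, tolerance = 1e-9)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-9)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-9)
  }
})

test_that("NG86 is symmetric in its two sequences", {
  set.seed(23)
  for (i in 1:10) {
    a <- random_codons(8); b <- mutate_uniform_cds(a, 0.2)
    r1 <- ng86_kaks(a, b); r2 <- ng86_kaks(b, a)
    expect_equal(r1$Ka, r2$Ka); expect_equal(r1$Ks, r2$Ks)
    expect_equal(r1$S, r2$S)
  }
})

test_that("Jukes-Cantor correction and flags follow the closed form", {
  expect_equal(-0.75 * log(1 - 0.4 / 3), 0.10732563, tolerance = 1e-6)
  r <- ng86_kaks("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(r$Ka, 0); expect_equal(r$Ks, 0)
  expect_true(is.na(r$ratio))   # Ks = 0 -> undefined ratio
  expect_true(r$flags[["ks_zero"]])
  # synonymous-only divergence (single-base synonymous neighbours so no
  # pathway crosses a nonsynonymous step): Ka = 0, Ks > 0
  set.seed(41)
  a <- random_codons(300)
  cods <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  gc <- Biostrings::GENETIC_CODE
  one_off <- function(cod) {
    v <- strsplit(cod, "")[[1]]
    out <- character()
    for (p in 1:3) for (bb in setdiff(c("A", "C", "G", "T"), v[p])) {
      w <- v; w[p] <- bb
      out <- c(out, paste(w, collapse = ""))
    }
    out
  }
  for (i in seq_along(cods)) {
    syn <- intersect(one_off(cods[i]),
                     names(gc)[gc == gc[[cods[i]]]])
    if (length(syn) && runif(1) < 0.3) cods[i] <- sample(syn, 1)
  }
  b <- paste(cods, collapse = "")
  r2 <- ng86_kaks(a, b)
  expect_equal(r2$Ka, 0, tolerance = 1e-9)
  expect_gt(r2$Ks, 0)
})

test_that("codon-aware alignment back-threads and drops gap codons", {
  a <- "ATGGCTCATAAACCC"             # M A H K P
  b <- "ATGGCTAAACCC"                # M A K P (H deleted)
  al <- codon_align(a, b)
  expect_equal(nchar(al$cds_a), nchar(al$cds_b))
  expect_equal(nchar(al$cds_a) %% 3, 0)
  expect_equal(al$cds_b, "ATGGCTAAACCC")
  r <- ng86_sites_and_diffs(al$cds_a, al$cds_b)
  expect_equal(r$Sd + r$Nd, 0)       # identical after removing the gap
  # trailing stop is trimmed, internal stop rejected
  expect_equal(nchar(codon_align("ATGGCTTAA", "ATGGCT")$cds_a), 6)
  expect_error(codon_align("ATGTAAGCT", "ATGGCTGCT"), "internal stop")
})

test_that("homoeolog pairs partition into donor and free groups", {
  pairs <- data.frame(gene_an = c("a1", "a2", "a3", "a4"),
                      gene_cn = c("c1", "c2", "c3", "c4"))
  cl <- classify_homoeolog_pairs(pairs, donor_gene_ids = c("a1", "c2", "a3",
                                                           "c3"))
  expect_equal(cl$group, c("donor", "donor", "donor", "free"))
  expect_warning(
    classify_homoeolog_pairs(pairs, "a1",
                             known_gene_ids = c("a1", "c1", "a2", "c2")),
    "dropped")
})

test_that("simulated homoeologs are under purifying-free divergence", {
  fx <- small_fixture()
  donors <- unique(fx$truth$gene_id)
  kk <- homoeolog_kaks(fx$genome, fx$genome$homoeologs, donors)
  expect_equal(nrow(kk), nrow(fx$genome$homoeologs))
  expect_true(all(kk$group %in% c("donor", "free")))
  # uniform substitutions in the simulator: Ka/Ks centred near one
  # (few pairs at this scale, so only a broad location check)
  expect_gt(median(kk$ratio, na.rm = TRUE), 0.5)
  expect_lt(median(kk$ratio, na.rm = TRUE), 2)
  expect_true(all(kk$Ks >= 0, na.rm = TRUE))
})
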