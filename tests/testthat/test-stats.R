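test_that("Wilcoxon rank-sum matches exact enumeration on small samples", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$method, "wilcoxon-exact")
  # identical groups (ties force the approximate branch): p near 1
  expect_gt(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 0.9)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "empty")
  # property: exact branch equals full enumeration for all n_a+n_b <= 8
  set.seed(19)
  for (na in 2:4) for (nb in 2:4) {
    x <- sample(100, na + nb)   # distinct -> no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, wilcoxon_oracle(a, b),
                 tolerance = 1e-12, info = paste(na, nb))
  }
})

test_that("exact and approximate Wilcoxon branches agree closely", {
  set.seed(29)
  diffs <- replicate(100, {
    a <- rnorm(6); b <- rnorm(6)
    p_ex <- wilcoxon_rank_sum(a, b)$p_value
    p_ap <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                         correct = TRUE)$p.value)
    abs(p_ex - p_ap)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("Student's t handles identical and degenerate input", {
  r <- students_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0, ignore_attr = TRUE)
  expect_equal(r$p_value, 1)
  rd <- students_t_test(c(0, 0, 0), c(1, 1, 1))
  expect_true(rd$degenerate)
  expect_equal(rd$p_value, 0)
  re <- students_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(re$p_value, 1)
  expect_error(students_t_test(1, c(1, 2)), "at least 2")
  # Welch variant differs under unequal variances
  a <- c(1, 2, 3, 4); b <- c(10, 30, 50, 70)
  expect_false(isTRUE(all.equal(students_t_test(a, b)$p_value,
                                students_t_test(a, b, welch = TRUE)$p_value)))
})

test_that("Pearson correlation recovers exact linear relations", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_correlation(x, -x)$statistic, -1)
  expect_true(pearson_correlation(x, rep(1, 10))$degenerate)
  expect_error(pearson_correlation(1:2, 1:2), "lengths >= 3")
})

test_that("NB test is antisymmetric and null-safe", {
  set.seed(43)
  a <- rnbinom(3, mu = 100, size = 10); b <- rnbinom(3, mu = 400, size = 10)
  r1 <- nb_differential_test(a, b)
  r2 <- nb_differential_test(b, a)
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$p_value, r2$p_value)
  r0 <- nb_differential_test(c(100, 110, 90), c(100, 110, 90))
  expect_equal(r0$log2fc, 0)
  expect_equal(r0$call, "ns")
  rz <- nb_differential_test(c(0, 0), c(0, 0))
  expect_equal(rz$p_value, 1)
  expect_error(nb_differential_test(1, c(1, 2)), "replicates")
})

test_that("matrix-level NB calls are rare under the null", {
  set.seed(47)
  counts <- matrix(rnbinom(600 * 6, mu = 100, size = 10), ncol = 6)
  rownames(counts) <- sprintf("f%03d", seq_len(nrow(counts)))
  de <- nb_de_matrix(counts, 1:3, 4:6)
  expect_lte(mean(de$call != "ns"), 0.005)
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
})

test_that("differential wrappers report the three genotype contrasts", {
  set.seed(53)
  feats <- sprintf("g%02d", 1:20)
  prof <- expand.grid(feature_id = feats, genotype = c("AC", "RAC", "NAC"),
                      replicate = 1:3, stringsAsFactors = FALSE)
  prof$value <- rnorm(nrow(prof), 50, 5)
  # plant a strong RAC-specific drop on the first five features
  drop <- prof$feature_id %in% feats[1:5] & prof$genotype == "RAC"
  prof$value[drop] <- prof$value[drop] - 30
  r <- call_differential_sets(prof, "DML",
                              classes = setNames(rep(c("donor", "free"),
                                                     c(5, 15)), feats))
  expect_setequal(unique(r$calls$contrast),
                  c("RAC_vs_AC", "NAC_vs_RAC", "NAC_vs_AC"))
  pr <- r$proportions
  expect_gt(pr$prop_called[pr$contrast == "RAC_vs_AC" &
                           pr$class == "donor"], 0.8)
  expect_lt(pr$prop_called[pr$contrast == "NAC_vs_AC" &
                           pr$class == "donor"], 0.6)
  # stars mapping
  expect_equal(helicap:::p_stars(c(0.009, 0.04, 0.0005, 0.2, NA)),
               c("**", "*", "***", "", ""))
})
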