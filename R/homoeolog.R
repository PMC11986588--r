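# Homoeologous pair partitions and the six genotype x donor-subgenome
# class comparisons.

#' Partition homoeologous pairs by donor subgenome
#'
#' Counts pairs whose donor gene lies only in the An subgenome, only in
#' Cn, in both, or in neither; the four counts partition the pair set.
#'
#' @param pairs data.frame gene_an, gene_cn.
#' @param donor_gene_ids donor gene ids from the capture catalog.
#' @return list(counts = c(An_only, Cn_only, both, neither), pairs =
#'   pairs with donor_an/donor_cn flags and a `partition` column).
#' @export
venn_partition_by_donor_subgenome <- function(pairs, donor_gene_ids) {
  pairs$donor_an <- pairs$gene_an %in% donor_gene_ids
  pairs$donor_cn <- pairs$gene_cn %in% donor_gene_ids
  pairs$partition <- ifelse(pairs$donor_an & pairs$donor_cn, "both",
                     ifelse(pairs$donor_an, "An_only",
                     ifelse(pairs$donor_cn, "Cn_only", "neither")))
  counts <- c(An_only = sum(pairs$partition == "An_only"),
              Cn_only = sum(pairs$partition == "Cn_only"),
              both = sum(pairs$partition == "both"),
              neither = sum(pairs$partition == "neither"))
  list(counts = counts, pairs = pairs)
}

#' Build the six genotype x donor-subgenome classes
#'
#' Only pairs with exactly one donor gene enter; each contributes one
#' observation to every genotype under its donor side, yielding classes
#' (AC, An), (RAC, An), (NAC, An), (AC, Cn), (RAC, Cn), (NAC, Cn).
#' Pairs with both or neither side a donor are excluded and counted.
#'
#' @param pairs data.frame gene_an, gene_cn.
#' @param donor_gene_ids donor gene ids.
#' @param genotypes genotype labels (default AC, RAC, NAC).
#' @return list(classes = data.frame(genotype, donor_side, gene_an,
#'   gene_cn, donor_gene, other_gene), n_excluded).
#' @export
build_six_classes <- function(pairs, donor_gene_ids,
                              genotypes = c("AC", "RAC", "NAC")) {
  vp <- venn_partition_by_donor_subgenome(pairs, donor_gene_ids)$pairs
  one <- vp[vp$partition %in% c("An_only", "Cn_only"), , drop = FALSE]
  n_excluded <- nrow(vp) - nrow(one)
  if (nrow(one) == 0)
    return(list(classes = data.frame(genotype = character(),
                                     donor_side = character(),
                                     gene_an = character(),
                                     gene_cn = character(),
                                     donor_gene = character(),
                                     other_gene = character()),
                n_excluded = n_excluded))
  base <- data.frame(
    donor_side = ifelse(one$partition == "An_only", "An", "Cn"),
    gene_an = one$gene_an, gene_cn = one$gene_cn,
    donor_gene = ifelse(one$partition == "An_only", one$gene_an, one$gene_cn),
    other_gene = ifelse(one$partition == "An_only", one$gene_cn, one$gene_an),
    stringsAsFactors = FALSE)
  classes <- do.call(rbind, lapply(genotypes, function(g)
    data.frame(genotype = g, base, stringsAsFactors = FALSE)))
  rownames(classes) <- NULL
  list(classes = classes, n_excluded = n_excluded)
}

#' Donor-side versus other-side comparison within each class
#'
#' Within each of the six classes, compares the metric values of the
#' donor-side genes against the non-donor-side genes of the same pairs
#' with a two-sided Wilcoxon test (unpaired rank-sum by default,
#' matching group box plots; `paired = TRUE` uses the signed-rank
#' form). Values are per-gene metric values in the class's genotype
#' (replicates averaged upstream).
#'
#' @param classes class table from [build_six_classes()].
#' @param profiles data.frame feature_id, genotype, value (one value
#'   per gene and genotype, e.g. replicate-mean RPM, methylation or
#'   TPM).
#' @param metric label recorded in the output.
#' @param paired use the paired signed-rank variant.
#' @return data.frame genotype, donor_side, metric, n_pairs,
#'   median_donor_side, median_other_side, p_value, stars.
#' @export
compare_class_epigenetics <- function(classes, profiles, metric = "metric",
                                      paired = FALSE) {
  key <- paste(profiles$feature_id, profiles$genotype)
  val <- setNames(profiles$value, key)
  combos <- unique(classes[, c("genotype", "donor_side")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    g <- combos$genotype[i]; s <- combos$donor_side[i]
    cl <- classes[classes$genotype == g & classes$donor_side == s, ]
    dv <- unname(val[paste(cl$donor_gene, g)])
    ov <- unname(val[paste(cl$other_gene, g)])
    keep <- !is.na(dv) & !is.na(ov)
    dv <- dv[keep]; ov <- ov[keep]
    p <- NA_real_
    if (length(dv) >= 3) {
      p <- if (paired) suppressWarnings(
             wilcox.test(dv, ov, paired = TRUE)$p.value)
           else wilcoxon_rank_sum(dv, ov)$p_value
    }
    data.frame(genotype = g, donor_side = s, metric = metric,
               n_pairs = length(dv),
               median_donor_side = if (length(dv)) median(dv) else NA_real_,
               median_other_side = if (length(ov)) median(ov) else NA_real_,
               p_value = p, stars = p_stars(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
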