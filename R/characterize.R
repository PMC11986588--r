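# Characterization of capture events and the features they involve.

#' Classify a captured fragment as UTR, CDS or mixed
#'
#' Fragment bases are attributed to UTR vs CDS by intersection with the
#' donor gene's subfeatures; when at least `majority` of the attributed
#' bases are one kind the fragment takes that label, otherwise `mixed`.
#'
#' @param events event table from [assign_donors()] (genomic
#'   frag_start/frag_end per event).
#' @param models `gene_models` carrying the donor genes' subfeatures.
#' @param majority majority threshold (default 0.8).
#' @return events with columns utr_bases, cds_bases and region_kind
#'   appended.
#' @export
classify_captured_region <- function(events, models, majority = 0.8) {
  if (nrow(events) == 0) {
    events$utr_bases <- integer(); events$cds_bases <- integer()
    events$region_kind <- character(); return(events)
  }
  sf <- models$subfeatures
  ex <- models$exons
  utr_bases <- integer(nrow(events)); cds_bases <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    gid <- events$donor_gene_id[i]
    fs <- events$frag_start[i]; fe <- events$frag_end[i]
    gex <- ex[ex$gene_id == gid, , drop = FALSE]
    if (!any(pmax(gex$start, fs) < pmin(gex$end, fe)))
      stop("fragment of event ", events$event_id[i],
           " lies outside the exons of ", gid, " (catalog inconsistency)")
    gsf <- sf[sf$gene_id == gid, , drop = FALSE]
    ov <- pmin(gsf$end, fe) - pmax(gsf$start, fs)
    ov[ov < 0] <- 0L
    utr_bases[i] <- sum(ov[gsf$kind %in% c("five_prime_UTR",
                                           "three_prime_UTR")])
    cds_bases[i] <- sum(ov[gsf$kind == "CDS"])
  }
  tot <- utr_bases + cds_bases
  kind <- rep("mixed", nrow(events))
  utr_frac <- utr_bases / pmax(tot, 1)
  # first matching rule wins, so a 50/50 split at majority 0.5 is UTR
  kind[tot > 0 & utr_frac >= majority] <- "UTR"
  kind[tot > 0 & (1 - utr_frac) >= majority & utr_frac < majority] <- "CDS"
  events$utr_bases <- utr_bases; events$cds_bases <- cds_bases
  events$region_kind <- kind
  events
}

#' Positional class of capture events
#'
#' Four groups by the relative position of the gene-capturing TE and its
#' donor gene: `NEAR` (closest-edge gap of at most `near_threshold` on
#' the same chromosome), `SAME_CHROM_FAR`, `SAME_SUBGENOME_DIFF_CHROM`
#' and `DIFF_SUBGENOME`. Events with either member on an unassigned
#' ("other") sequence are excluded and counted.
#'
#' @param events event table.
#' @param tes TE annotation.
#' @param genes gene table (`models$genes`).
#' @param near_threshold bp (default 2000).
#' @return list(events (classified subset with positional_class column),
#'   n_excluded, class_counts).
#' @export
positional_class <- function(events, tes, genes, near_threshold = 2000L) {
  if (nrow(events) == 0)
    return(list(events = cbind(events, positional_class = character()),
                n_excluded = 0L, class_counts = integer()))
  te_ix <- match(events$te_id, tes$te_id)
  ge_ix <- match(events$donor_gene_id, genes$gene_id)
  te_sub <- subgenome_of(tes$chrom[te_ix])
  ge_sub <- subgenome_of(genes$chrom[ge_ix])
  ok <- te_sub != "other" & ge_sub != "other"
  cls <- character(nrow(events))
  same_chrom <- tes$chrom[te_ix] == genes$chrom[ge_ix]
  gap <- pmax(pmax(tes$start[te_ix], genes$start[ge_ix]) -
              pmin(tes$end[te_ix], genes$end[ge_ix]), 0L)
  cls[same_chrom & gap <= near_threshold] <- "NEAR"
  cls[same_chrom & gap > near_threshold] <- "SAME_CHROM_FAR"
  cls[!same_chrom & te_sub == ge_sub] <- "SAME_SUBGENOME_DIFF_CHROM"
  cls[!same_chrom & te_sub != ge_sub] <- "DIFF_SUBGENOME"
  out <- events[ok, , drop = FALSE]
  out$positional_class <- cls[ok]
  lv <- c("NEAR", "SAME_CHROM_FAR", "SAME_SUBGENOME_DIFF_CHROM",
          "DIFF_SUBGENOME")
  list(events = out, n_excluded = sum(!ok),
       class_counts = table(factor(out$positional_class, levels = lv)))
}

#' Per-window feature density
#'
#' Features are binned by midpoint into fixed windows (default 1 Mb);
#' a midpoint exactly on a boundary belongs to the right-hand window;
#' the last partial window is kept.
#'
#' @param features data.frame with chrom, start, end.
#' @param chrom_lengths named lengths.
#' @param window window size in bp.
#' @return data.frame chrom, window_start, window_end, count.
#' @export
feature_density <- function(features, chrom_lengths, window = 1000000L) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    n_win <- max(1L, as.integer(ceiling(L / window)))
    starts <- (seq_len(n_win) - 1L) * window
    f <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(f) && any(f$end > L))
      stop("feature beyond chromosome length on ", ch)
    mid <- floor((f$start + f$end) / 2)
    idx <- pmin(floor(mid / window), n_win - 1L) + 1L
    cnt <- tabulate(idx, nbins = n_win)
    out[[ch]] <- data.frame(chrom = ch, window_start = starts,
                            window_end = pmin(starts + window, L),
                            count = cnt, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' GC content of a sequence
#'
#' (G+C)/(A+C+G+T); N (and other ambiguity codes) are excluded from the
#' denominator. Undefined (NA) for an empty or all-N sequence.
#'
#' @param seq DNA string (vectorized).
#' @return numeric proportion in `[0, 1]` or NA.
#' @export
gc_content <- function(seq) {
  vapply(toupper(seq), function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    den <- sum(v %in% c("A", "C", "G", "T"))
    if (den == 0) return(NA_real_)
    sum(v %in% c("G", "C")) / den
  }, 0, USE.NAMES = FALSE)
}

#' Fraction of capturing TEs overlapping pseudogenes
#'
#' A TE counts as overlapping iff it intersects any pseudogene interval
#' by at least 1 bp.
#'
#' @param capturing_tes TE annotation subset (capturing TEs).
#' @param pseudogenes data.frame chrom, start, end.
#' @return list(n_overlapping, n_total, fraction).
#' @export
pseudogene_overlap <- function(capturing_tes, pseudogenes) {
  if (nrow(capturing_tes) == 0)
    return(list(n_overlapping = 0L, n_total = 0L, fraction = NA_real_))
  if (nrow(pseudogenes) == 0)
    return(list(n_overlapping = 0L, n_total = nrow(capturing_tes),
                fraction = 0))
  gr_t <- GRanges(capturing_tes$chrom,
                  IRanges(capturing_tes$start + 1L, capturing_tes$end))
  gr_p <- GRanges(pseudogenes$chrom,
                  IRanges(pseudogenes$start + 1L, pseudogenes$end))
  n_ov <- length(unique(queryHits(findOverlaps(gr_t, gr_p))))
  list(n_overlapping = n_ov, n_total = nrow(capturing_tes),
       fraction = n_ov / nrow(capturing_tes))
}

#' Donor versus randomly sampled free genes: exon statistics
#'
#' Samples as many free genes as there are donor genes (seeded, without
#' replacement) and compares exon lengths and per-gene exon counts with
#' two-sided Wilcoxon rank-sum tests.
#'
#' @param models `gene_models`.
#' @param donor_gene_ids donor gene ids.
#' @param free_gene_ids free gene ids (must be at least as many).
#' @param seed sampling seed.
#' @return list(sampled_free_ids, donor_exon_lengths, free_exon_lengths,
#'   donor_exon_counts, free_exon_counts, p_exon_length, p_exon_count).
#' @export
donor_vs_free_exon_stats <- function(models, donor_gene_ids, free_gene_ids,
                                     seed = 1L) {
  if (length(free_gene_ids) < length(donor_gene_ids))
    stop("fewer free genes than donor genes; cannot sample a matched set")
  set.seed(seed)
  sampled <- sample(free_gene_ids, length(donor_gene_ids))
  ex <- models$exons
  len_of <- function(ids) (ex$end - ex$start)[ex$gene_id %in% ids]
  cnt_of <- function(ids) {
    sub <- ex[ex$gene_id %in% ids, , drop = FALSE]
    as.integer(tapply(sub$exon_index, factor(sub$gene_id, levels = ids),
                      length))
  }
  dl <- len_of(donor_gene_ids); fl <- len_of(sampled)
  dc <- cnt_of(donor_gene_ids); fc <- cnt_of(sampled)
  list(sampled_free_ids = sampled,
       donor_exon_lengths = dl, free_exon_lengths = fl,
       donor_exon_counts = dc, free_exon_counts = fc,
       p_exon_length = wilcoxon_rank_sum(dl, fl)$p_value,
       p_exon_count = wilcoxon_rank_sum(dc, fc)$p_value)
}

#' Correlation of per-chromosome feature counts with chromosome length
#'
#' Pearson correlation (two-sided) between chromosome length and the
#' count of features on each chromosome.
#'
#' @param counts named per-chromosome counts.
#' @param chrom_lengths named lengths (same chromosomes).
#' @return a `TestResult` from [pearson_correlation()], or a flagged
#'   NA result when a vector has zero variance.
#' @export
count_length_correlation <- function(counts, chrom_lengths) {
  ch <- intersect(names(counts), names(chrom_lengths))
  if (length(ch) < 3) stop("need at least 3 chromosomes")
  x <- as.numeric(chrom_lengths[ch]); y <- as.numeric(counts[ch])
  if (sd(x) == 0 || sd(y) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = "pearson", degenerate = TRUE))
  pearson_correlation(x, y)
}
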