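# siRNA abundance (RPM), context-resolved methylation levels, TPM,
# metaprofiles and fragment-level paired profiles.

#' Filter a small-RNA library to 24-nt siRNA reads
#'
#' Keeps reads of exactly 24 nt that do not overlap any exclusion
#' interval (tRNA/miRNA/rRNA/snRNA/snoRNA annotations supplied as BED).
#'
#' @param reads library data.frame from [read_sirna_bed()].
#' @param exclusion optional data.frame chrom, start, end.
#' @return list(reads, log = c(removed_length, removed_exclusion, kept)).
#' @export
filter_sirna_reads <- function(reads, exclusion = NULL) {
  len_ok <- reads$read_length == 24L
  removed_length <- sum(!len_ok)
  reads <- reads[len_ok, , drop = FALSE]
  removed_excl <- 0L
  if (!is.null(exclusion) && nrow(exclusion) > 0 && nrow(reads) > 0) {
    gr_r <- GRanges(reads$chrom, IRanges(reads$start + 1L, reads$end))
    gr_x <- GRanges(exclusion$chrom, IRanges(exclusion$start + 1L,
                                             exclusion$end))
    bad <- unique(queryHits(findOverlaps(gr_r, gr_x)))
    removed_excl <- length(bad)
    if (length(bad)) reads <- reads[-bad, , drop = FALSE]
  }
  rownames(reads) <- NULL
  list(reads = reads,
       log = c(removed_length = removed_length,
               removed_exclusion = removed_excl, kept = nrow(reads)))
}

#' Mix two parental libraries into a 1:1 in-silico hybrid
#'
#' The larger library is downsampled (seeded, without replacement) to
#' the size of the smaller — sizes counted in collapsed copies — then
#' the two are concatenated, so each parent contributes the same number
#' of reads.
#'
#' @param parent_a,parent_c read data.frames (collapsed libraries).
#' @param seed downsampling seed.
#' @return combined read data.frame.
#' @export
make_in_silico_hybrid <- function(parent_a, parent_c, seed = 1L) {
  if (nrow(parent_a) == 0 || nrow(parent_c) == 0)
    stop("cannot mix an empty parental library")
  na <- sum(parent_a$copies); nc <- sum(parent_c$copies)
  target <- min(na, nc)
  set.seed(seed)
  downsample <- function(lib, n_from, n_to) {
    if (n_from == n_to) return(lib)
    # expand collapsed copies, sample without replacement, re-collapse
    idx <- rep(seq_len(nrow(lib)), lib$copies)
    keep <- sample(idx, n_to)
    cnt <- table(keep)
    out <- lib[as.integer(names(cnt)), , drop = FALSE]
    out$copies <- as.integer(cnt)
    out
  }
  a <- downsample(parent_a, na, target)
  c_ <- downsample(parent_c, nc, target)
  out <- rbind(a, c_)
  rownames(out) <- NULL
  out
}

#' siRNA abundance of features in reads per million
#'
#' A read belongs to a feature when its midpoint lies inside the
#' interval (`rule = "midpoint"`, the default) or when it overlaps it by
#' at least 1 bp (`rule = "overlap"`). RPM = copies-in-feature /
#' library_size * 1e6.
#'
#' @param features data.frame chrom, start, end (one row per feature).
#' @param reads filtered read data.frame.
#' @param library_size total retained copies in the sample.
#' @param rule read-in-feature rule.
#' @return numeric RPM per feature row.
#' @export
rpm_quantify <- function(features, reads, library_size,
                         rule = c("midpoint", "overlap")) {
  rule <- match.arg(rule)
  if (library_size <= 0) stop("library_size must be > 0")
  if (nrow(features) == 0) return(numeric())
  if (nrow(reads) == 0) return(rep(0, nrow(features)))
  if (rule == "midpoint") {
    mid <- floor((reads$start + reads$end) / 2)
    gr_r <- GRanges(reads$chrom, IRanges(mid + 1L, mid + 1L))
  } else {
    gr_r <- GRanges(reads$chrom, IRanges(reads$start + 1L, reads$end))
  }
  gr_f <- GRanges(features$chrom, IRanges(features$start + 1L, features$end))
  ov <- findOverlaps(gr_r, gr_f)
  cnt <- tapply(reads$copies[queryHits(ov)], factor(subjectHits(ov),
                levels = seq_len(nrow(features))), sum)
  cnt[is.na(cnt)] <- 0
  as.numeric(cnt) / library_size * 1e6
}

#' TPM normalization of a count matrix
#'
#' rate = count / length_kb; TPM = rate / sum(rate) * 1e6 per sample.
#' An all-zero sample yields all-zero TPM and is flagged.
#'
#' @param cm a `count_matrix`.
#' @return list(tpm matrix, zero_samples).
#' @export
tpm_normalize <- function(cm) {
  len_kb <- unname(cm$lengths[rownames(cm$counts)]) / 1000
  if (any(len_kb <= 0)) stop("feature lengths must be > 0")
  rate <- cm$counts / len_kb
  tot <- colSums(rate)
  zero <- tot == 0
  tot[zero] <- 1
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  list(tpm = tpm, zero_samples = colnames(cm$counts)[zero])
}

#' Weighted methylation level of an interval
#'
#' level = sum(n_meth) / sum(n_total) * 100 over cytosines of the
#' context inside the interval; NA (undefined) when no covered cytosine
#' falls inside. Vectorized over features.
#'
#' @param features data.frame chrom, start, end.
#' @param records CX records (data.table from [read_cx_report()]).
#' @param context one of CG, CHG, CHH.
#' @return numeric percent level per feature row (NA when uncovered).
#' @export
methylation_level <- function(features, records, context) {
  if (nrow(features) == 0) return(numeric())
  keep <- which(records$context == context & records$n_total > 0)
  rec <- records[keep, ]
  if (nrow(rec) == 0) return(rep(NA_real_, nrow(features)))
  gr_c <- GRanges(rec$chrom, IRanges(rec$pos + 1L, rec$pos + 1L))
  gr_f <- GRanges(features$chrom, IRanges(features$start + 1L, features$end))
  ov <- findOverlaps(gr_c, gr_f)
  f <- factor(subjectHits(ov), levels = seq_len(nrow(features)))
  meth <- tapply(rec$n_meth[queryHits(ov)], f, sum)
  tot <- tapply(rec$n_total[queryHits(ov)], f, sum)
  out <- as.numeric(meth) / as.numeric(tot) * 100
  out[is.na(as.numeric(tot)) | as.numeric(tot) == 0] <- NA_real_
  out
}

#' Per-feature epigenetic profiles for one sample
#'
#' siRNA RPM and CG/CHG/CHH weighted methylation levels over a feature
#' set, plus its upstream and downstream flanks.
#'
#' @param features data.frame feature_id, chrom, start, end, strand.
#' @param records CX records.
#' @param reads filtered siRNA reads.
#' @param library_size total retained copies.
#' @param flank flank width (default 2000).
#' @param rule read-in-feature rule, see [rpm_quantify()].
#' @return data.frame feature_id, region (upstream/body/downstream),
#'   sirna_rpm, meth_cg, meth_chg, meth_chh.
#' @export
feature_epi_profile <- function(features, records, reads, library_size,
                                flank = 2000L, rule = "midpoint") {
  up <- features; dn <- features
  plus <- features$strand != "-"
  up$start <- ifelse(plus, pmax(0L, features$start - flank), features$end)
  up$end <- ifelse(plus, features$start, features$end + flank)
  dn$start <- ifelse(plus, features$end, pmax(0L, features$start - flank))
  dn$end <- ifelse(plus, features$end + flank, features$start)
  one <- function(f, region) {
    data.frame(feature_id = f$feature_id, region = region,
               sirna_rpm = rpm_quantify(f, reads, library_size, rule),
               meth_cg = methylation_level(f, records, "CG"),
               meth_chg = methylation_level(f, records, "CHG"),
               meth_chh = methylation_level(f, records, "CHH"),
               stringsAsFactors = FALSE)
  }
  rbind(one(up, "upstream"), one(features, "body"), one(dn, "downstream"))
}

#' Binned metaprofile over features and flanks
#'
#' Upstream flank, body and downstream flank are each split into
#' `bins_per_region` bins (body bins proportional to feature length);
#' per-bin weighted levels are averaged across features. Minus-strand
#' features are reversed so bin 1 is always 5'-most.
#'
#' @param features data.frame chrom, start, end, strand.
#' @param records CX records.
#' @param context methylation context.
#' @param flank flank width.
#' @param bins_per_region bins per region (default 20).
#' @return data.frame region, bin, level (mean percent across features).
#' @export
metaprofile <- function(features, records, context, flank = 2000L,
                        bins_per_region = 20L) {
  B <- bins_per_region
  rec <- records[which(records$context == context & records$n_total > 0), ]
  minus <- features$strand == "-"
  regions <- list(
    upstream = data.frame(
      chrom = features$chrom,
      start = ifelse(minus, features$end, pmax(0L, features$start - flank)),
      end = ifelse(minus, features$end + flank, features$start)),
    body = data.frame(chrom = features$chrom, start = features$start,
                      end = features$end),
    downstream = data.frame(
      chrom = features$chrom,
      start = ifelse(minus, pmax(0L, features$start - flank), features$end),
      end = ifelse(minus, features$start, features$end + flank)))
  out <- list()
  gr_c <- if (nrow(rec)) GRanges(rec$chrom, IRanges(rec$pos + 1L,
                                                    rec$pos + 1L)) else NULL
  for (rg in names(regions)) {
    rr <- regions[[rg]]
    lev <- rep(NA_real_, B)
    ok <- rr$end > rr$start
    if (any(ok) && !is.null(gr_c)) {
      gr_f <- GRanges(rr$chrom[ok], IRanges(rr$start[ok] + 1L, rr$end[ok]))
      ov <- findOverlaps(gr_c, gr_f)
      if (length(ov)) {
        ci <- queryHits(ov); fi <- which(ok)[subjectHits(ov)]
        rel <- (rec$pos[ci] - rr$start[fi]) / (rr$end[fi] - rr$start[fi])
        rel[minus[fi]] <- 1 - rel[minus[fi]] - 1e-12
        b <- pmin(floor(rel * B), B - 1L) + 1L
        # weighted level per (feature, bin), then mean across features
        dt <- data.table(f = fi, b = b, m = rec$n_meth[ci],
                         t = rec$n_total[ci])
        fb <- dt[, .(lv = sum(m) / sum(t) * 100), by = .(f, b)]
        mb <- fb[, .(level = mean(lv)), by = b]
        lev[mb$b] <- mb$level
      }
    }
    out[[rg]] <- data.frame(region = rg, bin = seq_len(B), level = lev,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Histogram of methylation levels in 10 equal groups
#'
#' Equal-width bins over 0-100 percent, left-closed right-open with the
#' last bin closed; undefined (NA) levels are excluded and counted
#' separately.
#'
#' @param levels percent levels.
#' @param n_bins number of groups (default 10).
#' @return list(counts, proportions, n_undefined); bins labelled
#'   `[0,10)`, ..., `[90,100]`.
#' @export
methylation_histogram <- function(levels, n_bins = 10L) {
  nd <- sum(is.na(levels))
  x <- levels[!is.na(levels)]
  w <- 100 / n_bins
  b <- pmin(floor(x / w), n_bins - 1L) + 1L
  counts <- tabulate(b, nbins = n_bins)
  labs <- sprintf("[%g,%g%s", w * (seq_len(n_bins) - 1), w * seq_len(n_bins),
                  c(rep(")", n_bins - 1), "]"))
  list(counts = setNames(counts, labs),
       proportions = setNames(if (length(x)) counts / length(x)
                              else rep(NA_real_, n_bins), labs),
       n_undefined = nd)
}

#' Map a TE-local interval to genomic coordinates
#'
#' Plus-strand TE: genomic = te_start + local; minus-strand TE:
#' genomic = [te_end - local_end, te_end - local_start).
#'
#' @param te_row one TE annotation row.
#' @param local_start,local_end 0-based half-open TE-local interval.
#' @return list(chrom, start, end).
#' @export
te_local_to_genomic <- function(te_row, local_start, local_end) {
  if (local_start < 0 || local_end > te_row$length)
    stop("TE-local interval outside the element span")
  if (identical(te_row$strand, "-")) {
    s <- te_row$end - local_end; e <- te_row$end - local_start
  } else {
    s <- te_row$start + local_start; e <- te_row$start + local_end
  }
  list(chrom = te_row$chrom, start = s, end = e)
}

#' Fragment-level paired profiles of capture events
#'
#' For each event, measures siRNA RPM and CG/CHG/CHH methylation on the
#' captured fragment in the gene (genomic `frag_start`/`frag_end`) and
#' on the homologous fragment in the TE (TE-local interval mapped to
#' genomic coordinates).
#'
#' @param events event table from [assign_donors()].
#' @param tes TE annotation.
#' @param records CX records.
#' @param reads filtered siRNA reads.
#' @param library_size total retained copies.
#' @return data.frame event_id plus gene_/te_ rpm and methylation
#'   columns and the TE fragment's genomic coordinates.
#' @export
fragment_pair_profile <- function(events, tes, records, reads,
                                  library_size) {
  if (nrow(events) == 0) return(data.frame())
  te_ix <- match(events$te_id, tes$te_id)
  gmap <- lapply(seq_len(nrow(events)), function(i)
    te_local_to_genomic(tes[te_ix[i], ], events$te_start[i],
                        events$te_end[i]))
  te_side <- data.frame(chrom = vapply(gmap, `[[`, "", "chrom"),
                        start = vapply(gmap, `[[`, 0, "start"),
                        end = vapply(gmap, `[[`, 0, "end"))
  gene_side <- data.frame(chrom = events$chrom, start = events$frag_start,
                          end = events$frag_end)
  side <- function(f, prefix) {
    out <- data.frame(rpm = rpm_quantify(f, reads, library_size),
                      cg = methylation_level(f, records, "CG"),
                      chg = methylation_level(f, records, "CHG"),
                      chh = methylation_level(f, records, "CHH"))
    setNames(out, paste0(prefix, names(out)))
  }
  cbind(data.frame(event_id = events$event_id, te_id = events$te_id,
                   donor_gene_id = events$donor_gene_id,
                   te_frag_chrom = te_side$chrom,
                   te_frag_start = te_side$start,
                   te_frag_end = te_side$end, stringsAsFactors = FALSE),
        side(gene_side, "gene_"), side(te_side, "te_"))
}
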