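# Gene-capture detection: overlap exclusion, E-value-screened local
# alignment of TE sequences against gene exons, donor assignment by
# highest bit score with tie retention, and multiplicity classification.

#' Remove physically intersecting genes and TEs
#'
#' Any gene overlapping at least 1 bp with any TE is removed, and any TE
#' overlapping at least 1 bp with any gene is removed (intervals are
#' 0-based half-open, so abutting features do not overlap).
#'
#' @param models a `gene_models` object.
#' @param tes TE annotation data.frame.
#' @return list(models, tes, removed_genes, removed_tes).
#' @export
exclude_overlaps <- function(models, tes) {
  g <- models$genes
  if (nrow(g) == 0 || nrow(tes) == 0)
    return(list(models = models, tes = tes, removed_genes = 0L,
                removed_tes = 0L))
  gr_g <- GRanges(g$chrom, IRanges(g$start + 1L, g$end))
  gr_t <- GRanges(tes$chrom, IRanges(tes$start + 1L, tes$end))
  ov <- findOverlaps(gr_g, gr_t)
  bad_g <- unique(queryHits(ov)); bad_t <- unique(subjectHits(ov))
  keep_ids <- g$gene_id[setdiff(seq_len(nrow(g)), bad_g)]
  models2 <- subset_gene_models(models, keep_ids)
  tes2 <- tes[setdiff(seq_len(nrow(tes)), bad_t), , drop = FALSE]
  rownames(tes2) <- NULL
  list(models = models2, tes = tes2, removed_genes = length(bad_g),
       removed_tes = length(bad_t))
}

#' Subset a gene_models object by gene id
#' @param models a `gene_models`.
#' @param gene_ids ids to keep.
#' @export
subset_gene_models <- function(models, gene_ids) {
  structure(list(
    genes = models$genes[models$genes$gene_id %in% gene_ids, , drop = FALSE],
    exons = models$exons[models$exons$gene_id %in% gene_ids, , drop = FALSE],
    subfeatures = models$subfeatures[models$subfeatures$gene_id %in% gene_ids,
                                     , drop = FALSE]), class = "gene_models")
}

# exon table with oriented sequences: gene_id, exon_index, chrom, start,
# end, strand, seq
exon_sequence_table <- function(genome, models = genome$models) {
  ex <- models$exons
  ex$seq <- vapply(seq_len(nrow(ex)), function(i)
    exon_sequence(genome, ex[i, ]), "")
  ex
}

.kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Scan TE sequences against gene exons for capture events
#'
#' Every (TE, exon) pair whose best local alignment has
#' E-value < `evalue_threshold` yields one alignment hit. The E-value
#' search space uses m = TE length and n = total exon-set length. A
#' shared-k-mer prefilter (exact match, default k = 11) can skip pairs
#' with no k-mer in common; with it disabled the scan is exhaustive.
#'
#' @param te_seqs named character vector of TE sequences (reading
#'   orientation), names are te_ids.
#' @param exon_tab exon table from [exon_sequence_table()] (gene_id,
#'   exon_index, chrom, start, end, strand, seq).
#' @param scheme a [scoring_scheme()].
#' @param evalue_threshold E-value screen (default 1e-40).
#' @param kmer_prefilter logical; use the shared-k-mer prefilter.
#' @param k prefilter k-mer size.
#' @return data.frame of hits: te_id, gene_id, exon_index, raw_score,
#'   bit_score, evalue, te_start, te_end, exon_start, exon_end,
#'   identity (local intervals, 0-based half-open).
#' @export
scan_captures <- function(te_seqs, exon_tab, scheme = scoring_scheme(),
                          evalue_threshold = 1e-40, kmer_prefilter = TRUE,
                          k = 11L) {
  if (evalue_threshold <= 0) stop("evalue_threshold must be > 0")
  n_space <- sum(nchar(exon_tab$seq))
  empty <- data.frame(te_id = character(), gene_id = character(),
                      exon_index = integer(), raw_score = integer(),
                      bit_score = numeric(), evalue = numeric(),
                      te_start = integer(), te_end = integer(),
                      exon_start = integer(), exon_end = integer(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (length(te_seqs) == 0 || nrow(exon_tab) == 0 || n_space == 0)
    return(empty)
  kmer_index <- NULL
  if (kmer_prefilter) {
    kl <- lapply(exon_tab$seq, .kmer_set, k = k)
    kmer_index <- data.table(kmer = unlist(kl),
                             exon = rep(seq_along(kl), lengths(kl)))
    setkey(kmer_index, kmer)
  }
  hits <- list()
  for (ti in seq_along(te_seqs)) {
    te_seq <- toupper(te_seqs[[ti]])
    m <- nchar(te_seq)
    if (m == 0) next
    # minimum raw score that can pass the screen for this TE
    bit_min <- log2(m * n_space / evalue_threshold)
    s_min <- ceiling((bit_min * log(2) + log(scheme$k_param)) / scheme$lambda)
    cand <- seq_len(nrow(exon_tab))
    if (kmer_prefilter) {
      tk <- .kmer_set(te_seq, k)
      cand <- if (length(tk))
        sort(unique(kmer_index[.(tk), exon, nomatch = NULL])) else integer()
    }
    if (!length(cand)) next
    scores <- sw_score_batch_cpp(te_seq, exon_tab$seq[cand], scheme$match,
                                 scheme$mismatch, scheme$gap_open,
                                 scheme$gap_extend)
    pass <- which(scores >= s_min)
    for (pj in pass) {
      ei <- cand[pj]
      al <- smith_waterman(te_seq, exon_tab$seq[ei], scheme)
      st <- hit_statistics(al$raw_score, m, n_space, scheme)
      if (st$evalue >= evalue_threshold) next
      hits[[length(hits) + 1]] <- data.frame(
        te_id = names(te_seqs)[ti], gene_id = exon_tab$gene_id[ei],
        exon_index = exon_tab$exon_index[ei], raw_score = al$raw_score,
        bit_score = st$bit_score, evalue = st$evalue,
        te_start = al$query_interval[1], te_end = al$query_interval[2],
        exon_start = al$subject_interval[1],
        exon_end = al$subject_interval[2],
        identity = al$identity, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else empty
  rownames(out) <- NULL
  out
}

# cluster hits on one TE into capture loci by >=1 bp overlap of their
# TE-local intervals (transitively closed); returns a locus id vector
.cluster_loci <- function(te_start, te_end) {
  ord <- order(te_start, te_end)
  locus <- integer(length(te_start))
  cur <- 0L; cur_end <- -1L
  for (i in ord) {
    if (te_start[i] >= cur_end) { cur <- cur + 1L; cur_end <- te_end[i] }
    else cur_end <- max(cur_end, te_end[i])
    locus[i] <- cur
  }
  locus
}

#' Resolve donor genes from alignment hits
#'
#' Hits on each TE are clustered into capture loci by overlap of their
#' TE-local intervals. Within each locus the hit(s) with the maximal bit
#' score become capture events; several genes with identical bit score
#' (and E-value) are all retained and flagged `is_tie`. A TE hitting two
#' exons of one gene at one locus yields a single event (highest-bit
#' exon kept). Distinct loci on one TE yield distinct events
#' (multi-capture).
#'
#' @param hits hit table from [scan_captures()].
#' @param exon_tab exon table (for genomic fragment coordinates).
#' @return events data.frame: event_id, te_id, locus, donor_gene_id,
#'   exon_index, chrom, frag_start, frag_end, te_start, te_end,
#'   raw_score, bit_score, evalue, identity, captured_length, is_tie.
#' @export
assign_donors <- function(hits, exon_tab) {
  empty <- data.frame(event_id = character(), te_id = character(),
                      locus = integer(), donor_gene_id = character(),
                      exon_index = integer(), chrom = character(),
                      frag_start = integer(), frag_end = integer(),
                      te_start = integer(), te_end = integer(),
                      raw_score = integer(), bit_score = numeric(),
                      evalue = numeric(), identity = numeric(),
                      captured_length = integer(), is_tie = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  events <- list()
  for (te in unique(hits$te_id)) {
    h <- hits[hits$te_id == te, , drop = FALSE]
    h$locus <- .cluster_loci(h$te_start, h$te_end)
    for (lc in sort(unique(h$locus))) {
      hl <- h[h$locus == lc, , drop = FALSE]
      best <- max(hl$bit_score)
      top <- hl[hl$bit_score == best, , drop = FALSE]
      # one event per gene at the locus; ties across genes all retained
      top <- top[order(top$gene_id, top$exon_index), , drop = FALSE]
      top <- top[!duplicated(top$gene_id), , drop = FALSE]
      tie <- nrow(top) > 1
      for (i in seq_len(nrow(top))) {
        ei <- which(exon_tab$gene_id == top$gene_id[i] &
                    exon_tab$exon_index == top$exon_index[i])[1]
        ex <- exon_tab[ei, ]
        lo <- top$exon_start[i]; hi <- top$exon_end[i]
        if (ex$strand == "+") {
          fs <- ex$start + lo; fe <- ex$start + hi
        } else {
          fs <- ex$end - hi; fe <- ex$end - lo
        }
        events[[length(events) + 1]] <- data.frame(
          te_id = te, locus = lc, donor_gene_id = top$gene_id[i],
          exon_index = top$exon_index[i], chrom = ex$chrom,
          frag_start = fs, frag_end = fe,
          te_start = top$te_start[i], te_end = top$te_end[i],
          raw_score = top$raw_score[i], bit_score = top$bit_score[i],
          evalue = top$evalue[i], identity = top$identity[i],
          captured_length = hi - lo, is_tie = tie, stringsAsFactors = FALSE)
      }
    }
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$te_id, ev$locus, ev$donor_gene_id), , drop = FALSE]
  ev <- data.frame(event_id = sprintf("ev_%04d", seq_len(nrow(ev))), ev,
                   stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev
}

#' Classify capture multiplicity of TEs
#'
#' A TE is a multiple gene-capturing TE iff it hosts two or more capture
#' loci; otherwise single.
#'
#' @param events event table from [assign_donors()].
#' @param tes TE annotation (for mean length per class).
#' @return list(per_te, summary) where per_te has te_id, n_loci, class
#'   and summary carries counts, proportions, mean TE length per class
#'   and captured-length min/mean/max.
#' @export
classify_capture_multiplicity <- function(events, tes = NULL) {
  if (nrow(events) == 0)
    return(list(per_te = data.frame(te_id = character(), n_loci = integer(),
                                    class = character()),
                summary = list(n_single = 0L, n_multiple = 0L,
                               prop_single = NA_real_,
                               prop_multiple = NA_real_)))
  n_loci <- tapply(events$locus, events$te_id,
                   function(x) length(unique(x)))
  per_te <- data.frame(te_id = names(n_loci), n_loci = as.integer(n_loci),
                       class = ifelse(n_loci >= 2, "multiple", "single"),
                       stringsAsFactors = FALSE)
  rownames(per_te) <- NULL
  n_s <- sum(per_te$class == "single"); n_m <- sum(per_te$class == "multiple")
  mean_len <- function(cls) {
    if (is.null(tes)) return(NA_real_)
    ids <- per_te$te_id[per_te$class == cls]
    if (!length(ids)) return(NA_real_)
    mean(tes$length[tes$te_id %in% ids])
  }
  list(per_te = per_te,
       summary = list(
         n_single = n_s, n_multiple = n_m,
         prop_single = n_s / (n_s + n_m), prop_multiple = n_m / (n_s + n_m),
         mean_te_length_single = mean_len("single"),
         mean_te_length_multiple = mean_len("multiple"),
         captured_length_min = min(events$captured_length),
         captured_length_mean = mean(events$captured_length),
         captured_length_max = max(events$captured_length)))
}

#' Run the full capture-detection stage on a genome set
#'
#' Applies the physical-overlap exclusion, extracts TE and exon
#' sequences, scans with the E-value screen, assigns donors and builds
#' the capture catalog.
#'
#' @param genome a `genome_set` (sequences present).
#' @param scheme a [scoring_scheme()].
#' @param evalue_threshold E-value screen.
#' @param kmer_prefilter,k see [scan_captures()].
#' @return a `capture_catalog`: list(events, hits, capturing_te_ids,
#'   donor_gene_ids, captured_gene_ids, free_te_ids, free_gene_ids,
#'   multiplicity, filter_log).
#' @export
detect_captures <- function(genome, scheme = scoring_scheme(),
                            evalue_threshold = 1e-40, kmer_prefilter = TRUE,
                            k = 11L) {
  filt <- exclude_overlaps(genome$models, genome$tes)
  exon_tab <- exon_sequence_table(genome, filt$models)
  te_seqs <- setNames(vapply(seq_len(nrow(filt$tes)), function(i)
    te_sequence(genome, filt$tes[i, ]), ""), filt$tes$te_id)
  hits <- scan_captures(te_seqs, exon_tab, scheme, evalue_threshold,
                        kmer_prefilter, k)
  events <- assign_donors(hits, exon_tab)
  capturing <- unique(events$te_id)
  donors <- unique(events$donor_gene_id)
  captured <- unique(hits$gene_id)
  catalog <- list(
    events = events, hits = hits,
    capturing_te_ids = capturing, donor_gene_ids = donors,
    captured_gene_ids = captured,
    free_te_ids = setdiff(filt$tes$te_id, capturing),
    free_gene_ids = setdiff(filt$models$genes$gene_id, captured),
    multiplicity = classify_capture_multiplicity(events, filt$tes),
    filter_log = c(removed_genes = filt$removed_genes,
                   removed_tes = filt$removed_tes,
                   n_hits = nrow(hits), n_events = nrow(events)))
  class(catalog) <- "capture_catalog"
  catalog
}

#' @export
print.capture_catalog <- function(x, ...) {
  cat("capture_catalog:", nrow(x$events), "events on",
      length(x$capturing_te_ids), "TEs;", length(x$donor_gene_ids),
      "donor genes of", length(x$captured_gene_ids), "captured;",
      length(x$free_gene_ids), "free genes\n")
  invisible(x)
}
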