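# Plant gene-capture events: copy exon sub-fragments into TE sequences
# ("peel-and-paste" semantics: the donor gene is left untouched).

#' Plant capture events into a synthetic genome
#'
#' Selects capturing TEs (a configured fraction carrying two or more
#' fragments), copies exon sub-fragments into them at random
#' non-overlapping TE-local offsets with per-base substitutions at the
#' configured divergence, and records the ground truth. Fragments are
#' written in the TE's own orientation, so a TE sequence extracted in
#' reading direction contains the fragment as the exon (transcription
#' direction) reads.
#'
#' @param genome a `genome_set` from [generate_genome()].
#' @param out_dir optional; when given, rewrites `genome.fa` (sequences
#'   now carry the planted fragments) and writes `capture_truth.tsv`.
#' @return list(genome = modified `genome_set`, truth = data.frame with
#'   te_id, gene_id, exon_index, chrom, frag_start, frag_end,
#'   te_local_start, te_local_end, length, divergence_applied).
#' @export
plant_captures <- function(genome, out_dir = NULL) {
  cfg <- genome$config
  set.seed(derive_seed(cfg$seed, "captures"))
  n_events <- cfg$n_captures
  truth_cols <- data.frame(te_id = character(), gene_id = character(),
                           exon_index = integer(), chrom = character(),
                           frag_start = integer(), frag_end = integer(),
                           te_local_start = integer(),
                           te_local_end = integer(), length = integer(),
                           divergence_applied = numeric(),
                           stringsAsFactors = FALSE)
  if (n_events == 0) {
    if (!is.null(out_dir)) .write_captures(genome, truth_cols, out_dir)
    return(list(genome = genome, truth = truth_cols))
  }
  mf <- cfg$multi_capture_fraction
  n_capturing <- max(1L, as.integer(round(n_events / (1 + mf))))
  n_capturing <- min(n_capturing, n_events)
  n_multi <- min(as.integer(round(mf * n_capturing)), n_events - n_capturing)
  # events per TE: singles get 1, the extra events go to the multi TEs
  per_te <- rep(1L, n_capturing)
  extra <- n_events - n_capturing
  if (n_multi > 0) {
    add <- rep(extra %/% n_multi, n_multi)
    rem <- extra %% n_multi
    if (rem > 0) add[seq_len(rem)] <- add[seq_len(rem)] + 1L
    per_te[seq_len(n_multi)] <- per_te[seq_len(n_multi)] + add
  }

  eligible <- which(genome$tes$length >= cfg$fragment_length_min + 20L)
  if (length(eligible) < n_capturing)
    stop("not enough TEs long enough to host the requested captures")
  te_pick <- sample(eligible, n_capturing)

  exons <- genome$models$exons
  ok_exons <- which(exons$end - exons$start >= cfg$fragment_length_min)
  if (!length(ok_exons))
    stop("no exon reaches fragment_length_min; captures impossible")

  truth <- list()
  for (t in seq_along(te_pick)) {
    te <- genome$tes[te_pick[t], ]
    used <- matrix(integer(), ncol = 2)  # local intervals already planted
    planted <- 0L
    tries <- 0L
    while (planted < per_te[t] && tries < 200L) {
      tries <- tries + 1L
      ei <- ok_exons[sample.int(length(ok_exons), 1)]
      ex <- exons[ei, ]
      ex_len <- ex$end - ex$start
      fmax <- min(cfg$fragment_length_max, ex_len, te$length)
      if (fmax < cfg$fragment_length_min) {
        warning("fragment does not fit TE ", te$te_id, "; resampling")
        next
      }
      flen <- as.integer(round(runif(1, cfg$fragment_length_min, fmax)))
      ex_off <- sample.int(ex_len - flen + 1L, 1) - 1L
      lo <- sample.int(te$length - flen + 1L, 1) - 1L
      hi <- lo + flen
      if (nrow(used) && any(pmax(used[, 1], lo) < pmin(used[, 2], hi))) next
      # exon-local (transcription-oriented) fragment -> genomic interval
      if (ex$strand == "+") {
        fs <- ex$start + ex_off; fe <- fs + flen
      } else {
        fe <- ex$end - ex_off; fs <- fe - flen
      }
      frag <- genome_seq(genome, ex$chrom, fs, fe, ex$strand)
      mut <- mutate_seq(frag, cfg$divergence)
      obs_div <- mean(strsplit(frag, "")[[1]] != strsplit(mut, "")[[1]])
      # write into the TE in its own orientation
      if (te$strand == "-") {
        g0 <- te$end - hi; g1 <- te$end - lo
        piece <- revcomp(mut)
      } else {
        g0 <- te$start + lo; g1 <- te$start + hi
        piece <- mut
      }
      s <- genome$seqs[[te$chrom]]
      substr(s, g0 + 1L, g1) <- piece
      genome$seqs[[te$chrom]] <- s
      used <- rbind(used, c(lo, hi))
      planted <- planted + 1L
      truth[[length(truth) + 1]] <- data.frame(
        te_id = te$te_id, gene_id = ex$gene_id, exon_index = ex$exon_index,
        chrom = ex$chrom, frag_start = fs, frag_end = fe,
        te_local_start = lo, te_local_end = hi, length = flen,
        divergence_applied = obs_div, stringsAsFactors = FALSE)
    }
    if (planted < per_te[t])
      warning("could not place all fragments on ", te$te_id)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else truth_cols
  rownames(truth) <- NULL
  if (!is.null(out_dir)) .write_captures(genome, truth, out_dir)
  list(genome = genome, truth = truth)
}

.write_captures <- function(genome, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, file.path(dir, "genome.fa"), width = 80L)
  data.table::fwrite(truth, file.path(dir, "capture_truth.tsv"), sep = "\t")
  invisible(NULL)
}
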