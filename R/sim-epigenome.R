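# Three-genotype methylome and 24-nt siRNA library simulator.
#
# Methylation is a phenomenological class-level model: every cytosine
# takes a per-context baseline for its feature class (gene body, TE,
# intergenic; flanks are intergenic), donor genes are shifted up by
# crosstalk_delta in every genotype (their captured fragment region sits
# crosstalk_delta above the TE baseline, mimicking siRNA crosstalk), and
# RAC relaxes donor genes and capturing TEs by the factor
# rac_relaxation. Read sampling is binomial at Poisson depth.

# per-chromosome cytosine table: pos (0-based), strand, context
.cytosine_table <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  nxt1 <- c(v[-1], "N"); nxt2 <- c(v[-(1:2)], "N", "N")
  prv1 <- c("N", v[-n]); prv2 <- c("N", "N", v[-((n - 1):n)])
  isC <- v == "C"; isG <- v == "G"
  ctx_plus <- ifelse(nxt1 == "G", "CG", ifelse(nxt2 == "G", "CHG", "CHH"))
  ctx_minus <- ifelse(prv1 == "C", "CG", ifelse(prv2 == "C", "CHG", "CHH"))
  data.table(
    pos = c(which(isC), which(isG)) - 1L,
    strand = rep(c("+", "-"), c(sum(isC), sum(isG))),
    context = c(ctx_plus[isC], ctx_minus[isG]))
}

# assign a per-cytosine percent level for one chromosome and genotype
.meth_levels <- function(cy, cfg, spans, genotype) {
  base <- cfg$baseline_meth
  p <- unname(unlist(base$intergenic)[cy$context])
  set_in <- function(p, iv, values) {
    if (is.null(iv) || nrow(iv) == 0) return(p)
    gr <- IRanges::IRanges(iv$start + 1L, iv$end)
    hits <- IRanges::findOverlaps(IRanges::IRanges(cy$pos + 1L, cy$pos + 1L), gr)
    i <- queryHits(hits)
    p[i] <- values[cy$context[i]]
    p
  }
  mul_in <- function(p, iv, f) {
    if (is.null(iv) || nrow(iv) == 0 || f == 1) return(p)
    gr <- IRanges::IRanges(iv$start + 1L, iv$end)
    hits <- IRanges::findOverlaps(IRanges::IRanges(cy$pos + 1L, cy$pos + 1L), gr)
    p[unique(queryHits(hits))] <- p[unique(queryHits(hits))] * f
    p
  }
  p <- set_in(p, spans$gene, unlist(base$gene))
  p <- set_in(p, spans$te, unlist(base$te))
  p <- set_in(p, spans$donor, unlist(base$gene) + cfg$crosstalk_delta)
  p <- set_in(p, spans$fragment, unlist(base$te) + cfg$crosstalk_delta)
  if (genotype == "RAC") {
    p <- mul_in(p, spans$donor, cfg$rac_relaxation)
    p <- mul_in(p, spans$fragment, cfg$rac_relaxation)
    p <- mul_in(p, spans$capturing_te, cfg$rac_relaxation)
  }
  pmin(pmax(p, 0), 100)
}

#' Simulate three-genotype methylomes and siRNA libraries
#'
#' Writes one CX report and one collapsed 24-nt siRNA BED per genotype
#' (AC, RAC, NAC) and replicate. The AC siRNA library is built by
#' generating parental An-side and Cn-side libraries and mixing them 1:1
#' through [make_in_silico_hybrid()]; the AC methylome is the union of
#' the parental subgenome calls (each parent's reads cover only its own
#' subgenome).
#'
#' @param genome a `genome_set` (after [plant_captures()]).
#' @param truth capture truth table from [plant_captures()].
#' @param out_dir output directory.
#' @return list with `cx` and `sirna` named path vectors (one per
#'   genotype x replicate, names like `AC_rep1`) and the sample sheet.
#' @export
simulate_epigenomes <- function(genome, truth, out_dir) {
  cfg <- genome$config
  if (cfg$depth <= 0) stop("depth must be > 0")
  set.seed(derive_seed(cfg$seed, "epigenome"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genotypes <- c("AC", "RAC", "NAC")
  reps <- seq_len(cfg$n_replicates)

  donor_ids <- unique(truth$gene_id)
  capturing <- unique(truth$te_id)
  g <- genome$models$genes
  spans_by_chrom <- function(df) split(df[, c("start", "end")], df$chrom)
  gene_sp <- spans_by_chrom(g[!(g$gene_id %in% donor_ids), ])
  donor_sp <- spans_by_chrom(g[g$gene_id %in% donor_ids, ])
  te_sp <- spans_by_chrom(genome$tes[!(genome$tes$te_id %in% capturing), ])
  cte_sp <- spans_by_chrom(genome$tes[genome$tes$te_id %in% capturing, ])
  frag_sp <- if (nrow(truth)) spans_by_chrom(
    data.frame(chrom = truth$chrom, start = truth$frag_start,
               end = truth$frag_end)) else list()

  # capturing TEs keep the TE baseline; include them in the te class too
  all_te_sp <- spans_by_chrom(genome$tes)

  cx_paths <- character(); sirna_paths <- character()
  cy_by_chrom <- lapply(genome$seqs, .cytosine_table)
  for (gt in genotypes) {
    # per-chromosome true levels for this genotype
    lev <- lapply(names(cy_by_chrom), function(ch) {
      spans <- list(gene = gene_sp[[ch]], te = all_te_sp[[ch]],
                    donor = donor_sp[[ch]], fragment = frag_sp[[ch]],
                    capturing_te = cte_sp[[ch]])
      .meth_levels(cy_by_chrom[[ch]], cfg, spans, gt)
    })
    names(lev) <- names(cy_by_chrom)
    for (r in reps) {
      rec <- rbindlist(lapply(names(cy_by_chrom), function(ch) {
        cy <- cy_by_chrom[[ch]]
        depth_i <- rpois(nrow(cy), cfg$depth)
        n_meth <- rbinom(nrow(cy), depth_i, lev[[ch]] / 100)
        data.table(chrom = ch, pos = cy$pos, strand = cy$strand,
                   context = cy$context, n_meth = n_meth, n_total = depth_i)
      }))
      p <- file.path(out_dir, sprintf("cx_%s_rep%d.tsv", gt, r))
      write_cx_report(rec, p)
      cx_paths[sprintf("%s_rep%d", gt, r)] <- p
    }
  }

  # siRNA libraries
  for (gt in genotypes) {
    relax <- if (gt == "RAC") cfg$rac_relaxation else 1
    for (r in reps) {
      if (gt == "AC") {
        a <- .sirna_library(genome, truth,
                            round(cfg$sirna_library_size * 0.55), 1,
                            subgenome = "An")
        c_ <- .sirna_library(genome, truth,
                             round(cfg$sirna_library_size * 0.5), 1,
                             subgenome = "Cn")
        lib <- make_in_silico_hybrid(a, c_,
                                     seed = derive_seed(cfg$seed, "epigenome") +
                                       97L * r)
      } else {
        lib <- .sirna_library(genome, truth, cfg$sirna_library_size, relax)
      }
      p <- file.path(out_dir, sprintf("sirna_%s_rep%d.bed", gt, r))
      write_sirna_bed(lib, p)
      sirna_paths[sprintf("%s_rep%d", gt, r)] <- p
    }
  }
  samples <- expand.grid(replicate = reps, genotype = genotypes,
                         stringsAsFactors = FALSE)[, 2:1]
  list(cx = cx_paths, sirna = sirna_paths, samples = samples)
}

# one collapsed 24-nt library; relax scales capturing-TE and donor-
# fragment weights (RAC). subgenome restricts to one parental side.
.sirna_library <- function(genome, truth, size, relax, subgenome = NULL) {
  tes <- genome$tes
  tr <- truth
  chroms <- names(genome$seqs)
  if (!is.null(subgenome)) {
    keep <- subgenome_of(chroms) == subgenome
    chroms <- chroms[keep]
    tes <- tes[tes$chrom %in% chroms, , drop = FALSE]
    tr <- tr[tr$chrom %in% chroms, , drop = FALSE]
  }
  cfg <- genome$config
  capturing <- unique(truth$te_id)
  w_te <- tes$length * ifelse(tes$te_id %in% capturing, relax, 1)
  n_te <- round(size * cfg$sirna_te_fraction)
  n_ct <- if (nrow(tr)) round(size * cfg$sirna_crosstalk_fraction * relax) else 0
  n_bg <- size - n_te - n_ct
  rows <- list()
  if (n_te > 0 && nrow(tes)) {
    i <- sample.int(nrow(tes), n_te, replace = TRUE, prob = w_te)
    off <- floor(runif(n_te) * (tes$length[i] - 24L))
    rows$te <- data.frame(chrom = tes$chrom[i],
                          start = tes$start[i] + as.integer(off))
  }
  if (n_ct > 0) {
    i <- sample.int(nrow(tr), n_ct, replace = TRUE)
    off <- floor(runif(n_ct) * pmax(1L, tr$length[i] - 24L))
    rows$ct <- data.frame(chrom = tr$chrom[i],
                          start = tr$frag_start[i] + as.integer(off))
  }
  if (n_bg > 0) {
    ch <- sample(chroms, n_bg, replace = TRUE)
    off <- floor(runif(n_bg) * (unname(genome$chrom_lengths[ch]) - 24L))
    rows$bg <- data.frame(chrom = ch, start = as.integer(off))
  }
  df <- do.call(rbind, rows)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  data.frame(chrom = df$chrom, start = df$start, end = df$start + 24L,
             name = sprintf("r%07d", seq_len(nrow(df))), copies = 1L,
             strand = sample(c("+", "-"), nrow(df), replace = TRUE),
             read_length = 24L, stringsAsFactors = FALSE)
}

#' Simulate expression counts for genes and TEs
#'
#' Negative-binomial counts per feature and sample around a log-normal
#' per-feature base mean; donor genes follow the configured
#' genotype-dependent fold ladder (default up-regulation AC < RAC <
#' NAC). Feature length is exonic length for genes and element length
#' for TEs.
#'
#' @param genome a `genome_set`.
#' @param truth capture truth table.
#' @param out_dir optional; writes `counts.tsv`.
#' @return a `count_matrix`: list(counts, samples, lengths, feature_ids).
#' @export
simulate_expression <- function(genome, truth, out_dir = NULL) {
  cfg <- genome$config
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  set.seed(derive_seed(cfg$seed, "expression"))
  ex <- genome$models$exons
  glen <- tapply(ex$end - ex$start, ex$gene_id, sum)
  ids <- c(names(glen), genome$tes$te_id)
  lens <- c(as.integer(glen), genome$tes$length)
  donor <- ids %in% unique(truth$gene_id)
  base <- cfg$nb_mean * exp(rnorm(length(ids), 0, 0.5))
  genotypes <- c("AC", "RAC", "NAC")
  samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                         genotype = genotypes,
                         stringsAsFactors = FALSE)[, 2:1]
  counts <- matrix(0L, nrow = length(ids), ncol = nrow(samples),
                   dimnames = list(ids, sprintf("%s_rep%d", samples$genotype,
                                                samples$replicate)))
  for (s in seq_len(nrow(samples))) {
    fold <- ifelse(donor, cfg$expression_fold_ladder[[samples$genotype[s]]], 1)
    counts[, s] <- rnbinom(length(ids), mu = base * fold,
                           size = 1 / cfg$nb_dispersion)
  }
  cm <- structure(list(counts = counts, samples = samples,
                       lengths = setNames(lens, ids), feature_ids = ids),
                  class = "count_matrix")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_count_matrix(cm, file.path(out_dir, "counts.tsv"))
  }
  cm
}

#' Read/write a count matrix TSV
#'
#' TSV with columns feature_id, length, then one `<genotype>_rep<i>`
#' column per sample.
#' @param path TSV file.
#' @export
read_count_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  ids <- dt$feature_id
  lens <- dt$length
  mat <- as.matrix(dt[, -(1:2)])
  rownames(mat) <- ids
  if (any(mat < 0) || any(mat != round(mat)))
    stop("counts must be non-negative integers")
  parts <- strsplit(colnames(mat), "_rep", fixed = TRUE)
  samples <- data.frame(genotype = vapply(parts, `[`, "", 1),
                        replicate = as.integer(vapply(parts, `[`, "", 2)),
                        stringsAsFactors = FALSE)
  structure(list(counts = mat, samples = samples,
                 lengths = setNames(lens, ids), feature_ids = ids),
            class = "count_matrix")
}

#' @rdname read_count_matrix
#' @param cm a `count_matrix`.
#' @export
write_count_matrix <- function(cm, path) {
  dt <- data.table(feature_id = cm$feature_ids,
                   length = unname(cm$lengths[cm$feature_ids]))
  out <- cbind(dt, as.data.table(cm$counts))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
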