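# Synthetic two-subgenome genome with gene models, Helitron-like TEs,
# homoeolog pairs and pseudogene intervals.

# map transcript-coordinate range [t0, t1) of a gene onto genomic pieces
# exons: data.frame in transcription order with start, end, strand
transcript_to_genomic <- function(exons, t0, t1) {
  lens <- exons$end - exons$start
  cum <- cumsum(c(0, lens))
  out <- list()
  for (i in seq_len(nrow(exons))) {
    a <- max(t0, cum[i]); b <- min(t1, cum[i + 1])
    if (a >= b) next
    l <- a - cum[i]; r <- b - cum[i]
    if (exons$strand[i] == "+") {
      gs <- exons$start[i] + l; ge <- exons$start[i] + r
    } else {
      gs <- exons$end[i] - r; ge <- exons$end[i] - l
    }
    out[[length(out) + 1]] <- data.frame(chrom = exons$chrom[i],
                                         start = gs, end = ge,
                                         strand = exons$strand[i])
  }
  do.call(rbind, out)
}

# one structural + sequence template for a gene
.gene_template <- function(cfg) {
  n_ex <- max(1L, rpois(1, cfg$exon_number_mean - 1) + 1L)
  ex_len <- pmax(60L, as.integer(round(rnorm(n_ex, cfg$exon_length_mean,
                                             cfg$exon_length_sd))))
  in_len <- if (n_ex > 1) sample(100:400, n_ex - 1, replace = TRUE) else integer()
  E <- sum(ex_len)
  u5 <- as.integer(floor(E * cfg$utr_fraction / 2))
  cds <- as.integer((E - 2 * u5) %/% 3 * 3)
  u3 <- E - u5 - cds
  exonic <- paste0(random_dna(u5), random_cds(cds %/% 3), random_dna(u3))
  list(exon_lengths = ex_len, intron_lengths = in_len,
       u5 = u5, cds = cds, u3 = u3, exonic = exonic)
}

.homoeolog_template <- function(tpl, cfg) {
  exonic <- paste0(
    mutate_seq(substr(tpl$exonic, 1, tpl$u5), cfg$homoeolog_divergence),
    mutate_cds(substr(tpl$exonic, tpl$u5 + 1, tpl$u5 + tpl$cds),
               cfg$homoeolog_divergence),
    mutate_seq(substr(tpl$exonic, tpl$u5 + tpl$cds + 1, nchar(tpl$exonic)),
               cfg$homoeolog_divergence))
  tpl$exonic <- exonic
  tpl
}

# spread feature lengths over a chromosome with a minimum gap
.place_lengths <- function(lengths, chrom_length, min_gap = 200L) {
  k <- length(lengths)
  if (k == 0) return(integer())
  slack <- chrom_length - sum(lengths) - (k + 1L) * min_gap
  if (slack < 0)
    stop("infeasible packing: ", sum(lengths), " feature bases + gaps exceed ",
         "chromosome length ", chrom_length)
  cuts <- sort(runif(k + 1))
  extra <- floor(slack * diff(c(0, cuts)) / cuts[k + 1])[seq_len(k)]
  starts <- integer(k)
  pos <- 0L
  for (i in seq_len(k)) {
    pos <- pos + min_gap + as.integer(extra[i])
    starts[i] <- pos
    pos <- pos + lengths[i]
  }
  starts
}

#' Generate a synthetic two-subgenome genome
#'
#' Builds chromosome sequences, non-overlapping gene models (with
#' exon/intron structure, UTR/CDS split and stop-free CDS), Helitron-like
#' TEs placed outside genes, 1:1 An/Cn homoeolog pairs at the configured
#' sequence divergence, and pseudogene intervals covering a configured
#' fraction of TEs. Deterministic for a fixed config seed.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `genome.fa`,
#'   `genes.gff3`, `tes.gff3`, `pseudogenes.bed` and `homoeologs.tsv`.
#' @return a `genome_set` list: config, seqs (named chromosome strings),
#'   models (`gene_models`), tes, pseudogenes, homoeologs, chrom_lengths.
#' @export
generate_genome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  k <- config$chroms_per_subgenome
  chroms <- c(sprintf("chrA%02d", seq_len(k)), sprintf("chrC%02d", seq_len(k)))
  # chromosome lengths vary around the configured mean (mirrors real
  # karyotypes and keeps count-vs-length statistics non-degenerate)
  scale_f <- if (k == 1) 1 else seq(0.7, 1.3, length.out = k)
  chrom_lengths <- setNames(as.integer(round(config$chrom_length *
                                             rep(scale_f, 2))), chroms)

  nA <- config$n_genes %/% 2L
  nC <- config$n_genes - nA
  n_pairs <- as.integer(round(config$homoeolog_fraction * nA))
  n_pairs <- min(n_pairs, nA, nC)

  # templates: A genes fresh; first n_pairs C genes copy an A template
  tplA <- lapply(seq_len(nA), function(i) .gene_template(config))
  pairedA <- if (n_pairs > 0) sample(seq_len(nA), n_pairs) else integer()
  tplC <- vector("list", nC)
  for (j in seq_len(nC)) {
    tplC[[j]] <- if (j <= n_pairs) .homoeolog_template(tplA[[pairedA[j]]], config)
                 else .gene_template(config)
  }
  ids_A <- sprintf("gene_A%03d", seq_len(nA))
  ids_C <- sprintf("gene_C%03d", seq_len(nC))
  homoeologs <- if (n_pairs > 0)
    data.frame(gene_an = ids_A[pairedA], gene_cn = ids_C[seq_len(n_pairs)],
               stringsAsFactors = FALSE)
  else data.frame(gene_an = character(), gene_cn = character())

  gene_len <- function(t) sum(t$exon_lengths) + sum(t$intron_lengths)
  all_ids <- c(ids_A, ids_C)
  all_tpl <- c(tplA, tplC)
  chrA <- chroms[seq_len(k)]; chrC <- chroms[k + seq_len(k)]
  gene_chrom <- c(sample(chrA, nA, replace = TRUE,
                         prob = chrom_lengths[chrA]),
                  sample(chrC, nC, replace = TRUE,
                         prob = chrom_lengths[chrC]))
  gene_strand <- sample(c("+", "-"), length(all_ids), replace = TRUE)

  genes <- list(); exons <- list(); subfeat <- list()
  free_space <- list()  # per chrom: data.frame(start, end) outside genes
  for (ch in chroms) {
    idx <- which(gene_chrom == ch)
    ord <- if (length(idx)) sample(idx) else integer()
    lens <- vapply(all_tpl[ord], gene_len, 0)
    starts <- .place_lengths(lens, chrom_lengths[[ch]], min_gap = 200L)
    occ <- data.frame(start = integer(), end = integer())
    for (t in seq_along(ord)) {
      gi <- ord[t]; tpl <- all_tpl[[gi]]
      gstart <- starts[t]; gend <- gstart + as.integer(gene_len(tpl))
      occ <- rbind(occ, data.frame(start = gstart, end = gend))
      n_ex <- length(tpl$exon_lengths)
      # exon genomic layout left-to-right
      ex_start <- gstart + cumsum(c(0L, head(tpl$exon_lengths, -1) +
                                          tpl$intron_lengths))
      ex <- data.frame(chrom = ch, start = as.integer(ex_start),
                       end = as.integer(ex_start + tpl$exon_lengths),
                       strand = gene_strand[gi], stringsAsFactors = FALSE)
      # transcription order
      ex_t <- if (gene_strand[gi] == "-") ex[rev(seq_len(n_ex)), , drop = FALSE] else ex
      exons[[gi]] <- data.frame(gene_id = all_ids[gi],
                                exon_index = seq_len(n_ex), ex_t,
                                stringsAsFactors = FALSE)
      E <- sum(tpl$exon_lengths)
      bounds <- list(five_prime_UTR = c(0L, tpl$u5),
                     CDS = c(tpl$u5, tpl$u5 + tpl$cds),
                     three_prime_UTR = c(tpl$u5 + tpl$cds, E))
      for (kind in names(bounds)) {
        b <- bounds[[kind]]
        if (b[1] >= b[2]) next
        pieces <- transcript_to_genomic(ex_t, b[1], b[2])
        subfeat[[length(subfeat) + 1]] <-
          data.frame(gene_id = all_ids[gi], kind = kind, pieces,
                     stringsAsFactors = FALSE)
      }
      genes[[gi]] <- data.frame(gene_id = all_ids[gi], chrom = ch,
                                start = gstart, end = gend,
                                strand = gene_strand[gi],
                                subgenome = subgenome_of(ch),
                                stringsAsFactors = FALSE)
    }
    occ <- occ[order(occ$start), , drop = FALSE]
    fs <- data.frame(start = c(0L, occ$end),
                     end = c(occ$start, chrom_lengths[[ch]]))
    free_space[[ch]] <- fs[fs$end - fs$start > 0, , drop = FALSE]
  }
  genes_df <- do.call(rbind, genes); rownames(genes_df) <- NULL
  exons_df <- do.call(rbind, exons); rownames(exons_df) <- NULL
  subfeat_df <- if (length(subfeat)) do.call(rbind, subfeat) else
    empty_gene_models()$subfeatures
  rownames(subfeat_df) <- NULL
  models <- structure(list(genes = genes_df, exons = exons_df,
                           subfeatures = subfeat_df), class = "gene_models")

  # TEs into the intergenic gaps, margin 100 bp from genes
  te_chrom <- sample(chroms, config$n_tes, replace = TRUE,
                     prob = chrom_lengths)
  te_len <- as.integer(round(runif(config$n_tes, config$te_length_min,
                                   config$te_length_max)))
  te_strand <- sample(c("+", "-"), config$n_tes, replace = TRUE)
  te_rows <- list()
  for (i in seq_len(config$n_tes)) {
    fs <- free_space[[te_chrom[i]]]
    cap <- fs$end - fs$start - 2L * 100L - te_len[i]
    ok <- which(cap >= 0)
    if (!length(ok))
      stop("infeasible packing: no intergenic gap fits a TE of ",
           te_len[i], " bp on ", te_chrom[i])
    slot <- ok[sample.int(length(ok), 1)]
    off <- 100L + sample.int(cap[slot] + 1L, 1) - 1L
    s <- fs$start[slot] + off; e <- s + te_len[i]
    # split the gap
    fs <- rbind(fs[-slot, , drop = FALSE],
                data.frame(start = fs$start[slot], end = s),
                data.frame(start = e, end = fs$end[slot]))
    free_space[[te_chrom[i]]] <- fs[fs$end - fs$start > 0, , drop = FALSE]
    te_rows[[i]] <- data.frame(te_id = sprintf("te_%04d", i),
                               chrom = te_chrom[i], start = s, end = e,
                               strand = te_strand[i],
                               superfamily = "Helitron", length = te_len[i],
                               stringsAsFactors = FALSE)
  }
  tes <- do.call(rbind, te_rows); rownames(tes) <- NULL

  # pseudogene intervals around a fraction of TEs
  n_pg <- as.integer(round(config$te_pseudogene_fraction * nrow(tes)))
  pg_idx <- if (n_pg > 0) sort(sample(seq_len(nrow(tes)), n_pg)) else integer()
  pseudogenes <- data.frame(
    chrom = tes$chrom[pg_idx],
    start = pmax(0L, tes$start[pg_idx] - 200L),
    end = pmin(unname(chrom_lengths[tes$chrom[pg_idx]]), tes$end[pg_idx] + 200L),
    name = sprintf("pg_%04d", seq_along(pg_idx)), stringsAsFactors = FALSE)

  # chromosome sequences; exon sequences written in, introns/intergenic random
  seqs <- setNames(vector("character", length(chroms)), chroms)
  for (ch in chroms) {
    v <- sample(.BASES, chrom_lengths[[ch]], replace = TRUE)
    idx <- which(genes_df$chrom == ch)
    for (gi in idx) {
      gid <- genes_df$gene_id[gi]
      tpl <- all_tpl[[match(gid, all_ids)]]
      ex_t <- exons_df[exons_df$gene_id == gid, , drop = FALSE]
      lens <- ex_t$end - ex_t$start
      cum <- cumsum(c(0, lens))
      for (e in seq_len(nrow(ex_t))) {
        piece <- substr(tpl$exonic, cum[e] + 1, cum[e + 1])
        if (ex_t$strand[e] == "-") piece <- revcomp(piece)
        v[(ex_t$start[e] + 1):ex_t$end[e]] <- strsplit(piece, "")[[1]]
      }
    }
    seqs[[ch]] <- paste(v, collapse = "")
  }

  genome <- structure(list(config = config, seqs = seqs, models = models,
                           tes = tes, pseudogenes = pseudogenes,
                           homoeologs = homoeologs,
                           chrom_lengths = chrom_lengths),
                      class = "genome_set")
  if (!is.null(out_dir)) write_genome_set(genome, out_dir)
  genome
}

#' Write a genome set to standard files
#' @param genome a `genome_set`.
#' @param dir output directory (created if needed).
#' @return named character vector of paths.
#' @export
write_genome_set <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.gff3"),
             tes = file.path(dir, "tes.gff3"),
             pseudogenes = file.path(dir, "pseudogenes.bed"),
             homoeologs = file.path(dir, "homoeologs.tsv"))
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, paths[["fasta"]], width = 80L)
  write_gene_models(genome$models, paths[["genes"]])
  write_te_annotations(genome$tes, paths[["tes"]])
  write_feature_bed(genome$pseudogenes, paths[["pseudogenes"]])
  data.table::fwrite(genome$homoeologs, paths[["homoeologs"]], sep = "\t")
  invisible(paths)
}

# oriented sequence of a genomic interval (0-based half-open)
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome$seqs[[chrom]], start + 1L, end)
  if (identical(strand, "-")) revcomp(s) else s
}

# oriented TE sequence
te_sequence <- function(genome, te_row) {
  genome_seq(genome, te_row$chrom, te_row$start, te_row$end,
             if (te_row$strand %in% c("+", "-")) te_row$strand else "+")
}

# oriented exon sequence (transcription direction)
exon_sequence <- function(genome, exon_row) {
  genome_seq(genome, exon_row$chrom, exon_row$start, exon_row$end,
             exon_row$strand)
}
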