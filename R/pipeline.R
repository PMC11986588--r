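# End-to-end orchestration: simulate -> detect -> characterize -> kaks
# -> epi -> diff -> homoeolog -> report, with a machine-readable
# manifest. All randomness derives from the config seed, so a rerun
# with the same config reproduces identical outputs.

#' Pre-flight input validation
#'
#' Checks that every path in a named list exists; all problems are
#' reported at once.
#'
#' @param paths named list/vector of file paths.
#' @return invisibly TRUE; errors with the full list of missing paths.
#' @export
preflight_check <- function(paths) {
  paths <- unlist(paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("pre-flight failure; missing input(s):\n  ",
         paste(names(missing), "=", missing, collapse = "\n  "))
  invisible(TRUE)
}

.write_tsv <- function(df, path) {
  data.table::fwrite(as.data.frame(df), path, sep = "\t")
  path
}

#' Run the full capture-analysis pipeline on simulated data
#'
#' Generates the genome and multi-omics data from `config`, runs capture
#' detection, characterization, Ka/Ks, epigenetic profiling,
#' differential calling and the homoeolog analysis, writing one
#' directory of TSVs per stage plus `manifest.json`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param evalue_threshold detection E-value screen (default 1e-40).
#' @param near_threshold positional NEAR distance (default 2000).
#' @param flank flank width for profiles (default 2000).
#' @param density_window per-chromosome density window (default 1e5 at
#'   fixture scale).
#' @param inputs optional named list of pre-existing input files
#'   (checked by [preflight_check()]) overriding the simulated
#'   epigenomes: elements `cx` and `sirna` as named path vectors.
#' @return the manifest (invisibly written as JSON).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         evalue_threshold = 1e-40, near_threshold = 2000L,
                         flank = 2000L, density_window = 100000L,
                         inputs = NULL) {
  t_start <- Sys.time()
  if (!is.null(inputs)) preflight_check(inputs)  # before any computation
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_dir <- function(s) {
    d <- file.path(out_dir, s); dir.create(d, showWarnings = FALSE); d
  }
  manifest <- list(package = "helicap",
                   version = as.character(utils::packageVersion("helicap")),
                   seed = config$seed,
                   params = list(evalue_threshold = evalue_threshold,
                                 near_threshold = near_threshold,
                                 flank = flank,
                                 density_window = density_window),
                   stages = list())
  stamp <- function(name, files, t0) {
    manifest$stages[[name]] <<- list(
      files = as.list(files),
      wall_time_s = round(as.numeric(difftime(Sys.time(), t0,
                                              units = "secs")), 2))
  }

  ## simulate ----------------------------------------------------------
  t0 <- Sys.time()
  sim_dir <- stage_dir("sim")
  genome <- generate_genome(config, sim_dir)
  pc <- plant_captures(genome, sim_dir)
  genome <- pc$genome; truth <- pc$truth
  if (is.null(inputs)) {
    epi <- simulate_epigenomes(genome, truth, sim_dir)
  } else {
    epi <- list(cx = unlist(inputs$cx), sirna = unlist(inputs$sirna))
  }
  cm <- simulate_expression(genome, truth, sim_dir)
  write_sim_config(config, file.path(sim_dir, "config.yaml"))
  stamp("simulate", c(file.path(sim_dir, c("genome.fa", "genes.gff3",
                                           "tes.gff3", "pseudogenes.bed",
                                           "homoeologs.tsv",
                                           "capture_truth.tsv",
                                           "counts.tsv", "config.yaml")),
                      epi$cx, epi$sirna), t0)

  ## detect ------------------------------------------------------------
  t0 <- Sys.time()
  det_dir <- stage_dir("detect")
  catalog <- detect_captures(genome, evalue_threshold = evalue_threshold)
  f_events <- .write_tsv(catalog$events, file.path(det_dir, "events.tsv"))
  f_perte <- .write_tsv(catalog$multiplicity$per_te,
                        file.path(det_dir, "te_multiplicity.tsv"))
  counts_tab <- data.frame(
    quantity = c("events", "capturing_tes", "donor_genes", "captured_genes",
                 "free_genes", "free_tes", "single_tes", "multiple_tes"),
    value = c(nrow(catalog$events), length(catalog$capturing_te_ids),
              length(catalog$donor_gene_ids),
              length(catalog$captured_gene_ids),
              length(catalog$free_gene_ids), length(catalog$free_te_ids),
              catalog$multiplicity$summary$n_single,
              catalog$multiplicity$summary$n_multiple))
  f_counts <- .write_tsv(counts_tab, file.path(det_dir, "catalog_summary.tsv"))
  stamp("detect", c(f_events, f_perte, f_counts), t0)

  ## characterize ------------------------------------------------------
  t0 <- Sys.time()
  ch_dir <- stage_dir("characterize")
  ev <- classify_captured_region(catalog$events, genome$models)
  pcl <- positional_class(ev, genome$tes, genome$models$genes,
                          near_threshold)
  ev$positional_class <- NA_character_
  ev$positional_class[match(pcl$events$event_id, ev$event_id)] <-
    pcl$events$positional_class
  f_ev <- .write_tsv(ev, file.path(ch_dir, "events_classified.tsv"))
  cap_tes <- genome$tes[genome$tes$te_id %in% catalog$capturing_te_ids, ]
  free_tes <- genome$tes[genome$tes$te_id %in% catalog$free_te_ids, ]
  genes_df <- genome$models$genes
  dens <- rbind(
    data.frame(feature = "gene",
               feature_density(genes_df, genome$chrom_lengths,
                               density_window)),
    data.frame(feature = "capturing_te",
               feature_density(cap_tes, genome$chrom_lengths,
                               density_window)),
    data.frame(feature = "free_te",
               feature_density(free_tes, genome$chrom_lengths,
                               density_window)))
  f_dens <- .write_tsv(dens, file.path(ch_dir, "density.tsv"))
  pg <- pseudogene_overlap(cap_tes, genome$pseudogenes)
  donor_ids <- catalog$donor_gene_ids
  free_ids <- catalog$free_gene_ids
  exst <- donor_vs_free_exon_stats(genome$models, donor_ids, free_ids,
                                   seed = derive_seed(config$seed,
                                                      "analysis"))
  per_chrom <- function(df) {
    cnt <- table(factor(df$chrom, levels = names(genome$chrom_lengths)))
    setNames(as.integer(cnt), names(cnt))
  }
  cor_or_na <- function(counts) {
    tryCatch(count_length_correlation(counts, genome$chrom_lengths),
             error = function(e) list(statistic = NA_real_,
                                      p_value = NA_real_,
                                      degenerate = TRUE))
  }
  cor_te <- cor_or_na(per_chrom(cap_tes))
  cor_dg <- cor_or_na(per_chrom(genes_df[genes_df$gene_id %in% donor_ids, ]))
  gc_cap <- mean(gc_content(vapply(seq_len(nrow(cap_tes)), function(i)
    te_sequence(genome, cap_tes[i, ]), "")), na.rm = TRUE)
  gc_free <- mean(gc_content(vapply(seq_len(nrow(free_tes)), function(i)
    te_sequence(genome, free_tes[i, ]), "")), na.rm = TRUE)
  summ <- data.frame(
    quantity = c("prop_utr", "prop_cds", "prop_mixed",
                 paste0("pos_", names(pcl$class_counts)),
                 "pos_excluded", "pseudogene_fraction",
                 "gc_capturing_te", "gc_free_te",
                 "p_exon_length", "p_exon_count",
                 "r_capturing_te_vs_length", "r_donor_gene_vs_length"),
    value = c(mean(ev$region_kind == "UTR"), mean(ev$region_kind == "CDS"),
              mean(ev$region_kind == "mixed"),
              as.numeric(pcl$class_counts), pcl$n_excluded, pg$fraction,
              gc_cap, gc_free, exst$p_exon_length, exst$p_exon_count,
              cor_te$statistic, cor_dg$statistic))
  f_summ <- .write_tsv(summ, file.path(ch_dir, "characterization.tsv"))
  stamp("characterize", c(f_ev, f_dens, f_summ), t0)

  ## kaks --------------------------------------------------------------
  t0 <- Sys.time()
  kk_dir <- stage_dir("kaks")
  kk <- homoeolog_kaks(genome, genome$homoeologs, donor_ids)
  f_kk <- .write_tsv(kk, file.path(kk_dir, "kaks.tsv"))
  stamp("kaks", f_kk, t0)

  ## epi ---------------------------------------------------------------
  t0 <- Sys.time()
  ep_dir <- stage_dir("epi")
  genes_feat <- data.frame(feature_id = genes_df$gene_id,
                           chrom = genes_df$chrom, start = genes_df$start,
                           end = genes_df$end, strand = genes_df$strand,
                           class = ifelse(genes_df$gene_id %in% donor_ids,
                                          "donor", "free"),
                           kind = "gene", stringsAsFactors = FALSE)
  tes_feat <- data.frame(feature_id = genome$tes$te_id,
                         chrom = genome$tes$chrom, start = genome$tes$start,
                         end = genome$tes$end, strand = genome$tes$strand,
                         class = ifelse(genome$tes$te_id %in%
                                        catalog$capturing_te_ids,
                                        "capturing", "free"),
                         kind = "te", stringsAsFactors = FALSE)
  feats <- rbind(genes_feat, tes_feat)
  prof <- list(); fragpair <- list(); metas <- list(); hists <- list()
  for (nm in names(epi$cx)) {
    gt <- sub("_rep.*", "", nm)
    rp <- as.integer(sub(".*_rep", "", nm))
    rec <- read_cx_report(epi$cx[[nm]])
    lib <- read_sirna_bed(epi$sirna[[nm]])
    fl <- filter_sirna_reads(lib)
    lsz <- sum(fl$reads$copies)
    fp <- feature_epi_profile(feats, rec, fl$reads, lsz, flank = flank)
    fp$genotype <- gt; fp$replicate <- rp
    fp$class <- feats$class[match(fp$feature_id, feats$feature_id)]
    fp$kind <- feats$kind[match(fp$feature_id, feats$feature_id)]
    prof[[nm]] <- fp
    pr <- fragment_pair_profile(catalog$events, genome$tes, rec,
                                fl$reads, lsz)
    if (nrow(pr)) { pr$genotype <- gt; pr$replicate <- rp }
    fragpair[[nm]] <- pr
    if (rp == 1L) {
      for (cls in c("donor", "free")) {
        gsub_ <- genes_feat[genes_feat$class == cls, ]
        mp <- metaprofile(gsub_, rec, "CG", flank = flank)
        metas[[paste(gt, cls)]] <- data.frame(genotype = gt, class = cls,
                                              context = "CG", mp)
      }
      body <- fp[fp$region == "body", ]
      for (knd in c("gene", "te")) {
        h <- methylation_histogram(body$meth_cg[body$kind == knd])
        hists[[paste(gt, knd)]] <- data.frame(
          genotype = gt, kind = knd, bin = names(h$counts),
          count = as.integer(h$counts), proportion = h$proportions,
          stringsAsFactors = FALSE)
      }
    }
  }
  profiles <- do.call(rbind, c(prof, make.row.names = FALSE))
  f_prof <- .write_tsv(profiles, file.path(ep_dir, "profiles.tsv"))
  f_frag <- .write_tsv(do.call(rbind, c(fragpair, make.row.names = FALSE)),
                       file.path(ep_dir, "fragment_pairs.tsv"))
  f_meta <- .write_tsv(do.call(rbind, c(metas, make.row.names = FALSE)),
                       file.path(ep_dir, "metaprofile.tsv"))
  f_hist <- .write_tsv(do.call(rbind, c(hists, make.row.names = FALSE)),
                       file.path(ep_dir, "methylation_histogram.tsv"))
  tpm <- tpm_normalize(cm)
  tpm_long <- data.frame(feature_id = rep(rownames(tpm$tpm),
                                          ncol(tpm$tpm)),
                         sample = rep(colnames(tpm$tpm),
                                      each = nrow(tpm$tpm)),
                         tpm = as.numeric(tpm$tpm))
  f_tpm <- .write_tsv(tpm_long, file.path(ep_dir, "tpm.tsv"))
  stamp("epi", c(f_prof, f_frag, f_meta, f_hist, f_tpm), t0)

  ## diff --------------------------------------------------------------
  t0 <- Sys.time()
  df_dir <- stage_dir("diff")
  classes <- setNames(feats$class, feats$feature_id)
  deg <- call_differential_sets(cm, "DEG", classes = classes)
  body <- profiles[profiles$region == "body", ]
  long <- function(col) data.frame(feature_id = body$feature_id,
                                   genotype = body$genotype,
                                   replicate = body$replicate,
                                   value = body[[col]],
                                   stringsAsFactors = FALSE)
  dml <- call_differential_sets(long("meth_cg"), "DML", classes = classes)
  dsi <- call_differential_sets(long("sirna_rpm"), "DEsiRNA",
                                classes = classes)
  f_deg <- .write_tsv(deg$calls, file.path(df_dir, "deg.tsv"))
  f_dml <- .write_tsv(dml$calls, file.path(df_dir, "dml_cg.tsv"))
  f_dsi <- .write_tsv(dsi$calls, file.path(df_dir, "desirna.tsv"))
  prop_all <- rbind(data.frame(mode = "DEG", deg$proportions),
                    data.frame(mode = "DML_CG", dml$proportions),
                    data.frame(mode = "DEsiRNA", dsi$proportions))
  f_prop <- .write_tsv(prop_all, file.path(df_dir, "proportions.tsv"))
  stamp("diff", c(f_deg, f_dml, f_dsi, f_prop), t0)

  ## homoeolog ---------------------------------------------------------
  t0 <- Sys.time()
  ho_dir <- stage_dir("homoeolog")
  vp <- venn_partition_by_donor_subgenome(genome$homoeologs, donor_ids)
  f_venn <- .write_tsv(data.frame(partition = names(vp$counts),
                                  count = as.integer(vp$counts)),
                       file.path(ho_dir, "venn.tsv"))
  six <- build_six_classes(genome$homoeologs, donor_ids)
  f_cls <- .write_tsv(six$classes, file.path(ho_dir, "six_classes.tsv"))
  gene_body <- body[body$kind == "gene", ]
  rep_mean <- function(col) {
    agg <- stats::aggregate(gene_body[[col]],
                            by = list(feature_id = gene_body$feature_id,
                                      genotype = gene_body$genotype),
                            FUN = mean, na.rm = TRUE)
    names(agg)[3] <- "value"; agg
  }
  comp <- list()
  for (mt in c("sirna_rpm", "meth_cg", "meth_chg", "meth_chh"))
    comp[[mt]] <- compare_class_epigenetics(six$classes, rep_mean(mt), mt)
  tpm_prof <- data.frame(feature_id = tpm_long$feature_id,
                         genotype = sub("_rep.*", "", tpm_long$sample),
                         value = tpm_long$tpm)
  tpm_prof <- stats::aggregate(value ~ feature_id + genotype,
                               data = tpm_prof, FUN = mean)
  comp$tpm <- compare_class_epigenetics(six$classes, tpm_prof, "tpm")
  f_comp <- .write_tsv(do.call(rbind, c(comp, make.row.names = FALSE)),
                       file.path(ho_dir, "class_comparison.tsv"))
  stamp("homoeolog", c(f_venn, f_cls, f_comp), t0)

  manifest$total_wall_time_s <-
    round(as.numeric(difftime(Sys.time(), t_start, units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ## report ------------------------------------------------------------
  summarize_report(file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Build the summary report from a pipeline manifest
#'
#' Reads the stage outputs listed in the manifest (no recomputation)
#' and writes the headline tables — event and gene counts,
#' single/multiple and UTR/CDS proportions, positional classes,
#' pseudogene fraction, per-contrast differential-call proportions and
#' the six-class comparisons — under `report/`, plus a combined
#' `summary.txt`. Sections whose stage outputs are missing are skipped
#' with a flag.
#'
#' @param manifest_path path to `manifest.json`.
#' @return list of summary tables (invisibly).
#' @export
summarize_report <- function(manifest_path) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  out_dir <- dirname(manifest_path)
  rp_dir <- file.path(out_dir, "report")
  dir.create(rp_dir, showWarnings = FALSE)
  tables <- list(); flags <- character()
  grab <- function(stage, file) {
    fs <- unlist(manifest$stages[[stage]]$files)
    p <- fs[basename(fs) == file]
    if (length(p) != 1 || !file.exists(p)) return(NULL)
    as.data.frame(data.table::fread(p, sep = "\t"))
  }
  tables$counts <- grab("detect", "catalog_summary.tsv")
  tables$characterization <- grab("characterize", "characterization.tsv")
  tables$proportions <- grab("diff", "proportions.tsv")
  tables$venn <- grab("homoeolog", "venn.tsv")
  tables$class_comparison <- grab("homoeolog", "class_comparison.tsv")
  kk <- grab("kaks", "kaks.tsv")
  if (!is.null(kk)) {
    tables$kaks_summary <- do.call(rbind, lapply(split(kk, kk$group),
      function(g) data.frame(group = g$group[1], n = nrow(g),
                             median_ks = median(g$Ks, na.rm = TRUE),
                             median_ratio = median(g$ratio, na.rm = TRUE))))
    rownames(tables$kaks_summary) <- NULL
  }
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) { flags <- c(flags, nm); next }
    .write_tsv(tables[[nm]], file.path(rp_dir, paste0(nm, ".tsv")))
  }
  con <- file(file.path(rp_dir, "summary.txt"), "w")
  on.exit(close(con))
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) {
      writeLines(sprintf("== %s: MISSING ==", nm), con); next
    }
    writeLines(sprintf("== %s ==", nm), con)
    writeLines(utils::capture.output(print(tables[[nm]], row.names = FALSE)),
               con)
    writeLines("", con)
  }
  invisible(tables)
}
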