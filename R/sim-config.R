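#' Simulation configuration
#'
#' Parameters of the synthetic study system: a two-subgenome (An/Cn)
#' genome with gene models and Helitron-like TEs, planted gene-capture
#' events, and a three-genotype (AC in-silico hybrid, resynthesized RAC,
#' natural NAC) series of methylomes, 24-nt siRNA libraries and
#' expression counts. Defaults define the package's reference fixture:
#' 2 chromosomes per subgenome of 500 kb, 200 genes, 300 TEs and 60
#' planted captures, with fragment lengths of 100-600 bp at up to 5%
#' divergence and about a third of capturing TEs carrying multiple
#' fragments.
#'
#' The epigenetic effects are phenomenological level shifts, not a
#' mechanistic RdDM model: donor genes are hypermethylated by
#' `crosstalk_delta` percentage points in every genotype (the captured
#' fragment region sits `crosstalk_delta` above the TE baseline), and in
#' RAC only, donor genes and capturing TEs have their methylation — and
#' their siRNA targeting weight — multiplied by `rac_relaxation`.
#'
#' @param seed integer master seed; every downstream stage derives its
#'   own stream from it.
#' @param chroms_per_subgenome,chrom_length genome shape.
#' @param n_genes total genes (split evenly between subgenomes).
#' @param exon_number_mean mean exon count per gene (min 1, Poisson).
#' @param exon_length_mean,exon_length_sd exon length distribution (bp).
#' @param utr_fraction fraction of exonic bases in UTR (split between
#'   the 5' and 3' ends).
#' @param homoeolog_fraction fraction of An genes paired 1:1 with a
#'   near-identical Cn homoeolog.
#' @param homoeolog_divergence per-base substitution rate between
#'   homoeolog copies (CDS substitutions avoid stop codons).
#' @param n_tes,te_length_min,te_length_max TE complement; TEs are
#'   placed outside genes.
#' @param n_captures planted capture events.
#' @param multi_capture_fraction fraction of capturing TEs carrying two
#'   or more fragments.
#' @param fragment_length_min,fragment_length_max captured fragment
#'   length range (bp).
#' @param divergence per-base substitution probability applied to the
#'   captured copy inside the TE (0-0.2).
#' @param te_pseudogene_fraction fraction of TEs lying inside an
#'   annotated pseudogene interval.
#' @param baseline_meth named list of per-context percent levels for the
#'   feature classes `gene`, `te`, `intergenic` (flanks are intergenic).
#' @param crosstalk_delta methylation boost (percentage points) on donor
#'   genes.
#' @param rac_relaxation multiplicative factor in (0, 1] applied in RAC.
#' @param depth mean per-cytosine read depth (Poisson).
#' @param sirna_library_size 24-nt reads per sample.
#' @param sirna_te_fraction,sirna_crosstalk_fraction share of each
#'   library placed on TEs and on donor-gene fragments; the remainder is
#'   uniform background.
#' @param nb_mean,nb_dispersion expression count model (negative
#'   binomial; dispersion is the NB alpha so variance = mu + alpha*mu^2).
#' @param expression_fold_ladder donor-gene expression fold changes for
#'   AC, RAC, NAC.
#' @param n_replicates replicates per genotype.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chroms_per_subgenome = 2L,
                       chrom_length = 500000L,
                       n_genes = 200L,
                       exon_number_mean = 4,
                       exon_length_mean = 250,
                       exon_length_sd = 80,
                       utr_fraction = 0.3,
                       homoeolog_fraction = 0.4,
                       homoeolog_divergence = 0.03,
                       n_tes = 300L,
                       te_length_min = 500L,
                       te_length_max = 3000L,
                       n_captures = 60L,
                       multi_capture_fraction = 0.35,
                       fragment_length_min = 100L,
                       fragment_length_max = 600L,
                       divergence = 0.05,
                       te_pseudogene_fraction = 0.5,
                       baseline_meth = list(
                         gene = c(CG = 40, CHG = 10, CHH = 5),
                         te = c(CG = 85, CHG = 65, CHH = 15),
                         intergenic = c(CG = 20, CHG = 10, CHH = 5)),
                       crosstalk_delta = 20,
                       rac_relaxation = 0.7,
                       depth = 30,
                       sirna_library_size = 100000L,
                       sirna_te_fraction = 0.7,
                       sirna_crosstalk_fraction = 0.05,
                       nb_mean = 100,
                       nb_dispersion = 0.1,
                       expression_fold_ladder = c(AC = 1, RAC = 1.5, NAC = 2),
                       n_replicates = 3L) {
  cfg <- as.list(environment())
  stopifnot(cfg$chroms_per_subgenome >= 1, cfg$chrom_length > 0,
            cfg$n_genes >= 0, cfg$n_tes >= 0, cfg$n_captures >= 0,
            cfg$utr_fraction >= 0, cfg$utr_fraction <= 1,
            cfg$multi_capture_fraction >= 0, cfg$multi_capture_fraction <= 1,
            cfg$divergence >= 0, cfg$divergence <= 0.2,
            cfg$rac_relaxation > 0, cfg$rac_relaxation <= 1,
            cfg$fragment_length_min <= cfg$fragment_length_max,
            cfg$n_replicates >= 1)
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$depth <= 0) stop("depth must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "-", 2 * x$chroms_per_subgenome,
      "chroms x", x$chrom_length, "bp,", x$n_genes, "genes,", x$n_tes,
      "TEs,", x$n_captures, "captures\n")
  invisible(x)
}

#' Read/write a simulation configuration as YAML
#' @param path YAML file.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$baseline_meth))
    vals$baseline_meth <- lapply(vals$baseline_meth, unlist)
  if (!is.null(vals$expression_fold_ladder))
    vals$expression_fold_ladder <- unlist(vals$expression_fold_ladder)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  vals <- unclass(config)
  vals$baseline_meth <- lapply(vals$baseline_meth, as.list)
  vals$expression_fold_ladder <- as.list(vals$expression_fold_ladder)
  yaml::write_yaml(vals, path)
  invisible(path)
}

# deterministic per-stage seed derivation (kept below 2^31)
derive_seed <- function(seed, stage) {
  offs <- c(genome = 11L, captures = 23L, epigenome = 37L,
            expression = 53L, analysis = 71L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% 2000000011L
}
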