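# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, plus
# codon-aware pairwise alignment of CDS pairs.

.GENETIC_CODE <- Biostrings::GENETIC_CODE

.codon_split <- function(s) {
  n <- nchar(s) %/% 3
  substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

.aa <- function(codon) unname(.GENETIC_CODE[codon])

# fraction of synonymous sites per codon (changes to stops count as
# nonsynonymous), memoised over the 61 sense codons
.syn_sites_one <- function(codon) {
  aa0 <- .aa(codon)
  s <- 0
  v <- strsplit(codon, "", fixed = TRUE)[[1]]
  for (p in 1:3) for (b in setdiff(.BASES, v[p])) {
    w <- v; w[p] <- b
    cod2 <- paste(w, collapse = "")
    if (.aa(cod2) != "*" && .aa(cod2) == aa0) s <- s + 1 / 3
  }
  s
}
.SYN_SITES <- local({
  v <- vapply(.SENSE_CODONS, .syn_sites_one, 0)
  setNames(v, .SENSE_CODONS)
})

# pathway-averaged synonymous/nonsynonymous differences for one codon
# pair; pathways crossing stop codons are excluded and the remainder
# reweighted. Falls back to all pathways if every one is blocked.
.codon_diffs <- function(ca, cb) {
  va <- strsplit(ca, "", fixed = TRUE)[[1]]
  vb <- strsplit(cb, "", fixed = TRUE)[[1]]
  pos <- which(va != vb)
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- switch(k, list(1L), list(1:2, 2:1),
                  { p <- list(); for (i in 1:3) for (j in setdiff(1:3, i))
                      p[[length(p) + 1]] <- c(i, j, setdiff(1:3, c(i, j)))
                    p })
  path_counts <- function(allow_stops) {
    res <- list()
    for (ord in perms) {
      cur <- va; sd <- 0; nd <- 0; ok <- TRUE
      for (step in ord) {
        p <- pos[step]
        nxt <- cur; nxt[p] <- vb[p]
        a1 <- .aa(paste(cur, collapse = "")); a2 <- .aa(paste(nxt, collapse = ""))
        if (a2 == "*" && !allow_stops) { ok <- FALSE; break }
        if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) res[[length(res) + 1]] <- c(sd, nd)
    }
    res
  }
  res <- path_counts(FALSE)
  if (!length(res)) res <- path_counts(TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

#' NG86 site and difference counts
#'
#' Synonymous (S) and nonsynonymous (N) site counts averaged over the
#' two sequences (each codon position contributes the fraction of its
#' three possible substitutions that are synonymous; substitutions to
#' stop codons count as nonsynonymous), and synonymous/nonsynonymous
#' differences (Sd, Nd) averaged over all equally weighted substitution
#' pathways, excluding pathways through stop codons.
#'
#' @param cds_a,cds_b aligned gap-free CDS strings of equal length
#'   divisible by 3, without internal stop codons. Codons containing an
#'   ambiguous base are skipped (counted in `n_skipped`).
#' @return list(S, N, Sd, Nd, n_codons, n_skipped).
#' @export
ng86_sites_and_diffs <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("aligned CDS lengths differ")
  if (nchar(cds_a) %% 3 != 0) stop("aligned length not divisible by 3")
  ca <- .codon_split(cds_a); cb <- .codon_split(cds_b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  n_skipped <- sum(!clean)
  ca <- ca[clean]; cb <- cb[clean]
  if (any(.aa(ca) == "*") || any(.aa(cb) == "*"))
    stop("internal stop codon in aligned CDS")
  S <- (sum(.SYN_SITES[ca]) + sum(.SYN_SITES[cb])) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) .codon_diffs(ca[i], cb[i]), c(0, 0))
  list(S = S, N = N, Sd = sum(d[1, ]), Nd = sum(d[2, ]),
       n_codons = length(ca), n_skipped = n_skipped)
}

#' NG86 Ka/Ks with Jukes-Cantor correction
#'
#' pS = Sd/S and pN = Nd/N are corrected by
#' d = -(3/4) ln(1 - 4p/3); the ratio is Ka/Ks. Flags mark an undefined
#' ratio (Ks = 0) and an undefined correction (p >= 3/4).
#'
#' @inheritParams ng86_sites_and_diffs
#' @return list(S, N, Sd, Nd, pS, pN, Ka, Ks, ratio, flags).
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  sn <- ng86_sites_and_diffs(cds_a, cds_b)
  pS <- if (sn$S > 0) sn$Sd / sn$S else NA_real_
  pN <- if (sn$N > 0) sn$Nd / sn$N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ka <- jc(pN); Ks <- jc(pS)
  flags <- c(ks_zero = isTRUE(Ks == 0),
             jc_undefined = (is.na(Ka) && !is.na(pN)) ||
                            (is.na(Ks) && !is.na(pS)))
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  c(sn[c("S", "N", "Sd", "Nd")],
    list(pS = pS, pN = pN, Ka = Ka, Ks = Ks, ratio = ratio, flags = flags))
}

#' Codon-aware pairwise CDS alignment
#'
#' Aligns the translations globally and back-threads the protein
#' alignment onto the nucleotide sequences; codon columns containing a
#' gap are removed, leaving a gap-free codon alignment for NG86. A
#' trailing stop codon is trimmed; an internal stop is an error.
#'
#' @param cds_a,cds_b CDS strings (length divisible by 3).
#' @return list(cds_a, cds_b) of equal-length gap-free codon sequences.
#' @export
codon_align <- function(cds_a, cds_b) {
  trim <- function(s) {
    s <- toupper(s)
    if (nchar(s) %% 3 != 0) stop("CDS length not divisible by 3")
    cods <- .codon_split(s)
    if (length(cods) && .aa(cods[length(cods)]) %in% "*")
      cods <- cods[-length(cods)]
    aas <- .aa(cods)
    if (any(aas == "*", na.rm = TRUE)) stop("internal stop codon in CDS")
    cods
  }
  ca <- trim(cds_a); cb <- trim(cds_b)
  pa <- paste(.aa(ca), collapse = ""); pb <- paste(.aa(cb), collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L; keep_a <- character(); keep_b <- character()
  for (i in seq_along(sa)) {
    ga <- sa[i] == "-"; gb <- sb[i] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      keep_a <- c(keep_a, ca[ia]); keep_b <- c(keep_b, cb[ib])
    }
  }
  list(cds_a = paste(keep_a, collapse = ""),
       cds_b = paste(keep_b, collapse = ""))
}

# CDS sequence of one gene from its subfeature pieces, in
# transcription/reading order
cds_sequence <- function(genome, gene_id) {
  sf <- genome$models$subfeatures
  p <- sf[sf$gene_id == gene_id & sf$kind == "CDS", , drop = FALSE]
  if (nrow(p) == 0) return("")
  p <- if (p$strand[1] == "-") p[order(-p$start), , drop = FALSE]
       else p[order(p$start), , drop = FALSE]
  paste(vapply(seq_len(nrow(p)), function(i)
    genome_seq(genome, p$chrom[i], p$start[i], p$end[i], p$strand[i]), ""),
    collapse = "")
}

#' Partition homoeologous pairs by capture state
#'
#' A pair is a donor pair when at least one side is a donor gene; it is
#' free only when both sides are free. Pairs involving genes absent
#' from the annotation are dropped with a warning.
#'
#' @param pairs data.frame gene_an, gene_cn.
#' @param donor_gene_ids donor gene ids from the capture catalog.
#' @param known_gene_ids optional universe for the presence check.
#' @return pairs with a `group` column in donor/free.
#' @export
classify_homoeolog_pairs <- function(pairs, donor_gene_ids,
                                     known_gene_ids = NULL) {
  if (!is.null(known_gene_ids)) {
    ok <- pairs$gene_an %in% known_gene_ids & pairs$gene_cn %in% known_gene_ids
    if (any(!ok)) {
      warning(sum(!ok), " homoeolog pair(s) dropped: gene absent from ",
              "annotation")
      pairs <- pairs[ok, , drop = FALSE]
    }
  }
  pairs$group <- ifelse(pairs$gene_an %in% donor_gene_ids |
                        pairs$gene_cn %in% donor_gene_ids, "donor", "free")
  rownames(pairs) <- NULL
  pairs
}

#' Ka/Ks for homoeologous gene pairs
#'
#' Extracts each pair's CDS from the genome, builds a codon-aware
#' alignment and computes NG86 Ka/Ks; pairs are grouped donor/free via
#' [classify_homoeolog_pairs()].
#'
#' @param genome a `genome_set`.
#' @param pairs data.frame gene_an, gene_cn.
#' @param donor_gene_ids donor gene ids.
#' @return data.frame per pair: gene_an, gene_cn, group, S, N, Sd, Nd,
#'   Ka, Ks, ratio.
#' @export
homoeolog_kaks <- function(genome, pairs, donor_gene_ids) {
  pairs <- classify_homoeolog_pairs(pairs, donor_gene_ids,
                                    genome$models$genes$gene_id)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    al <- codon_align(cds_sequence(genome, pairs$gene_an[i]),
                      cds_sequence(genome, pairs$gene_cn[i]))
    r <- ng86_kaks(al$cds_a, al$cds_b)
    data.frame(gene_an = pairs$gene_an[i], gene_cn = pairs$gene_cn[i],
               group = pairs$group[i], S = r$S, N = r$N, Sd = r$Sd,
               Nd = r$Nd, Ka = r$Ka, Ks = r$Ks, ratio = r$ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
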