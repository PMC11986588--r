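#' Chromosome-to-subgenome assignment
#'
#' Maps chromosome names to the An (B. rapa-derived) or Cn (B.
#' oleracea-derived) subgenome of an allotetraploid by configurable
#' name patterns. Anything matching neither pattern (unplaced scaffolds,
#' organellar contigs) is labelled `"other"`.
#'
#' @param chrom character vector of chromosome/scaffold names.
#' @param a_pattern,c_pattern regular expressions identifying An and Cn
#'   chromosomes. Defaults match names like `chrA03` / `chrC07`.
#' @return character vector with values in `c("An", "Cn", "other")`.
#' @examples
#' subgenome_of(c("chrA03", "chrC07", "scaffold_1182"))
#' @export
subgenome_of <- function(chrom, a_pattern = "^chrA[0-9]+$",
                         c_pattern = "^chrC[0-9]+$") {
  out <- rep("other", length(chrom))
  out[grepl(a_pattern, chrom)] <- "An"
  out[grepl(c_pattern, chrom)] <- "Cn"
  out
}

#' Read gene models from GFF3
#'
#' Parses a gene/mRNA/exon/CDS/UTR hierarchy into a `gene_models` object.
#' GFF3 1-based closed coordinates are converted to the package-internal
#' 0-based half-open convention at this boundary. For multi-isoform genes
#' the transcript with the largest total exon length defines the model.
#' Exons are indexed from 1 in transcription order (strand-aware).
#'
#' @param path GFF3 file.
#' @param a_pattern,c_pattern subgenome name patterns, see [subgenome_of()].
#' @return an object of class `gene_models`: a list with data.frames
#'   `genes` (gene_id, chrom, start, end, strand, subgenome),
#'   `exons` (gene_id, exon_index, chrom, start, end, strand) and
#'   `subfeatures` (gene_id, kind, chrom, start, end, strand), with
#'   kind in five_prime_UTR/CDS/three_prime_UTR.
#' @export
read_gene_models <- function(path, a_pattern = "^chrA[0-9]+$",
                             c_pattern = "^chrC[0-9]+$") {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 '", path,
                                          "': ", conditionMessage(e)))
  if (length(gr) == 0) return(empty_gene_models())
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   strand = as.character(strand(gr)),
                   type = as.character(gr$type),
                   id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
                   stringsAsFactors = FALSE)
  par <- gr$Parent
  df$parent <- if (is.null(par)) NA_character_ else
    vapply(as.list(par), function(p) if (length(p)) p[[1]] else NA_character_, "")

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  parts <- df[df$type %in% c("exon", "CDS", "five_prime_UTR",
                             "three_prime_UTR"), , drop = FALSE]
  if (nrow(genes) && (anyNA(genes$id) || anyDuplicated(genes$id)))
    stop("malformed GFF3 hierarchy: genes must carry unique ID attributes")
  bad <- !(mrnas$parent %in% genes$id)
  if (any(bad))
    stop("malformed GFF3 hierarchy: transcript '", mrnas$id[which(bad)[1]],
         "' has no gene parent")
  bad <- !(parts$parent %in% mrnas$id)
  if (any(bad))
    stop("malformed GFF3 hierarchy: feature of type '",
         parts$type[which(bad)[1]], "' (parent '", parts$parent[which(bad)[1]],
         "') has no transcript parent")
  if (nrow(genes) == 0) return(empty_gene_models())

  # longest transcript (total exon length) defines the gene's model
  exonic <- parts[parts$type == "exon", , drop = FALSE]
  tx_len <- tapply(exonic$end - exonic$start, exonic$parent, sum)
  mrnas$exlen <- as.numeric(tx_len[mrnas$id])
  mrnas$exlen[is.na(mrnas$exlen)] <- 0
  ord <- order(mrnas$parent, -mrnas$exlen, mrnas$id)
  mrnas <- mrnas[ord, , drop = FALSE]
  chosen <- mrnas[!duplicated(mrnas$parent), , drop = FALSE]
  tx2gene <- setNames(chosen$parent, chosen$id)

  keep <- parts$parent %in% chosen$id
  parts <- parts[keep, , drop = FALSE]
  parts$gene_id <- unname(tx2gene[parts$parent])

  ex <- parts[parts$type == "exon", , drop = FALSE]
  ex <- ex[order(ex$gene_id, ex$start), , drop = FALSE]
  # validate non-overlap within transcript
  by_gene <- split(seq_len(nrow(ex)), ex$gene_id)
  for (ix in by_gene) {
    if (length(ix) > 1 && any(ex$start[ix][-1] < ex$end[ix][-length(ix)]))
      stop("overlapping exons within transcript of gene '",
           ex$gene_id[ix[1]], "'")
  }
  # transcription order: 5'-most first
  ex_list <- lapply(by_gene, function(ix) {
    sub <- ex[ix, , drop = FALSE]
    if (sub$strand[1] == "-") sub <- sub[rev(seq_len(nrow(sub))), , drop = FALSE]
    sub$exon_index <- seq_len(nrow(sub))
    sub
  })
  exons <- do.call(rbind, ex_list)
  rownames(exons) <- NULL

  sub <- parts[parts$type != "exon", , drop = FALSE]
  subfeatures <- data.frame(gene_id = sub$gene_id, kind = sub$type,
                            chrom = sub$chrom, start = sub$start,
                            end = sub$end, strand = sub$strand,
                            stringsAsFactors = FALSE)
  genes_df <- data.frame(gene_id = genes$id, chrom = genes$chrom,
                         start = genes$start, end = genes$end,
                         strand = genes$strand,
                         subgenome = subgenome_of(genes$chrom, a_pattern,
                                                  c_pattern),
                         stringsAsFactors = FALSE)
  genes_df <- genes_df[order(genes_df$gene_id), , drop = FALSE]
  rownames(genes_df) <- NULL
  exons <- exons[order(exons$gene_id, exons$exon_index),
                 c("gene_id", "exon_index", "chrom", "start", "end", "strand")]
  rownames(exons) <- NULL
  subfeatures <- subfeatures[order(subfeatures$gene_id, subfeatures$start), ,
                             drop = FALSE]
  rownames(subfeatures) <- NULL
  structure(list(genes = genes_df, exons = exons, subfeatures = subfeatures),
            class = "gene_models")
}

empty_gene_models <- function() {
  structure(list(
    genes = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), subgenome = character(),
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = character(), exon_index = integer(),
                       chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       stringsAsFactors = FALSE),
    subfeatures = data.frame(gene_id = character(), kind = character(),
                             chrom = character(), start = integer(),
                             end = integer(), strand = character(),
                             stringsAsFactors = FALSE)), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$subfeatures), "subfeatures\n")
  invisible(x)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()]: emits a gene/mRNA/exon/CDS/UTR
#' hierarchy (one transcript per gene, ID `<gene_id>.t1`), converting the
#' internal 0-based half-open coordinates back to 1-based closed GFF3.
#'
#' @param models a `gene_models` object.
#' @param path output file.
#' @export
write_gene_models <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes; e <- models$exons; s <- models$subfeatures
  tx_id <- paste0(g$gene_id, ".t1")
  lines <- c(
    sprintf("%s\thelicap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
    sprintf("%s\thelicap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            g$chrom, g$start + 1L, g$end, g$strand, tx_id, g$gene_id),
    sprintf("%s\thelicap\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
            e$chrom, e$start + 1L, e$end, e$strand, e$gene_id),
    if (nrow(s)) sprintf("%s\thelicap\t%s\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
            s$chrom, s$kind, s$start + 1L, s$end, s$strand, s$gene_id))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read TE annotations from GFF3
#'
#' One record per element; the `ID` attribute (or `Name`, or a generated
#' `te_<n>`) becomes `te_id`. Coordinates are converted to 0-based
#' half-open.
#'
#' @param path GFF3 file of transposable-element annotations.
#' @param superfamily optional filter on the GFF3 `type` column
#'   (e.g. `"helitron"`, matched case-insensitively as a substring).
#' @return data.frame with te_id, chrom, start, end, strand, superfamily,
#'   length.
#' @export
read_te_annotations <- function(path, superfamily = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  if (!is.null(superfamily)) {
    keep <- grepl(superfamily, type, ignore.case = TRUE)
    gr <- gr[keep]; type <- type[keep]
  }
  id <- if (!is.null(gr$ID) && !anyNA(gr$ID)) as.character(gr$ID)
        else if (!is.null(gr$Name)) as.character(gr$Name)
        else sprintf("te_%06d", seq_along(gr))
  data.frame(te_id = id, chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             strand = sub("\\*", ".", as.character(strand(gr))),
             superfamily = type, length = width(gr),
             stringsAsFactors = FALSE)
}

#' Write TE annotations to GFF3
#' @param tes data.frame as returned by [read_te_annotations()].
#' @param path output file.
#' @export
write_te_annotations <- function(tes, path) {
  strand <- ifelse(tes$strand %in% c("+", "-"), tes$strand, ".")
  lines <- sprintf("%s\thelicap\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   tes$chrom, tes$superfamily, tes$start + 1L, tes$end,
                   strand, tes$te_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
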