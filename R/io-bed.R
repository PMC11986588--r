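#' Read genomic intervals from BED
#'
#' Reads BED3+ (tab-separated, 0-based half-open). A 4th column is kept
#' as `name`, a 5th as `score`, a 6th as `strand`. Every interval is
#' validated; an invalid line is reported by number.
#'
#' @param path BED file.
#' @return data.frame with chrom, start, end and any of name, score,
#'   strand present in the input. Empty input gives a 0-row frame.
#' @export
read_feature_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  ncol_used <- min(ncol(dt), 6L)
  dt <- dt[, seq_len(ncol_used), with = FALSE]
  data.table::setnames(dt, cols[seq_len(ncol_used)])
  df <- as.data.frame(dt)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
               df$start < 0 | df$start >= df$end | df$chrom == "")
  if (length(bad))
    stop("invalid BED interval at line ", bad[1], " of '", path,
         "' (require 0 <= start < end and non-empty chrom)")
  df
}

#' Write genomic intervals to BED
#' @param df data.frame with chrom, start, end and optionally name,
#'   score, strand (columns written in BED order, stopping at the first
#'   absent one).
#' @param path output file.
#' @export
write_feature_bed <- function(df, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  keep <- character()
  for (cl in cols) { if (cl %in% names(df)) keep <- c(keep, cl) else break }
  data.table::fwrite(as.data.table(df)[, keep, with = FALSE], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a collapsed small-RNA library from BED
#'
#' BED6 where `score` carries the collapsed read multiplicity (copies)
#' and is defaulted to 1 when absent. Read length is the interval width.
#'
#' @param path BED file.
#' @return data.frame chrom, start, end, name, copies, strand,
#'   read_length.
#' @export
read_sirna_bed <- function(path) {
  df <- read_feature_bed(path)
  if (!"name" %in% names(df)) df$name <- sprintf("r%d", seq_len(nrow(df)))
  df$copies <- if ("score" %in% names(df)) as.integer(df$score) else 1L
  df$score <- NULL
  if (!"strand" %in% names(df)) df$strand <- "."
  if (any(df$copies < 1)) stop("collapsed read multiplicity must be >= 1")
  df$read_length <- df$end - df$start
  df
}

#' @rdname read_sirna_bed
#' @param reads data.frame as returned by `read_sirna_bed`.
#' @param path output file.
#' @export
write_sirna_bed <- function(reads, path) {
  out <- data.frame(chrom = reads$chrom, start = reads$start,
                    end = reads$end, name = reads$name,
                    score = reads$copies, strand = reads$strand)
  write_feature_bed(out, path)
}

# context dialect table: tokens accepted in CX-style reports
.cx_context_map <- c(CG = "CG", CpG = "CG", CHG = "CHG", CHH = "CHH")

#' Read a per-cytosine CX methylation report
#'
#' Tab-separated columns: chrom, position (1-based), strand,
#' methylated count, unmethylated count, context. Context tokens are
#' normalized through a small dialect table (`CpG` -> `CG`); unknown
#' tokens are an error, never silently dropped. Uncovered cytosines
#' (0 total reads) are retained and contribute nothing to weighted
#' levels downstream.
#'
#' @param path CX report file.
#' @return data.table chrom, pos (0-based), strand, context, n_meth,
#'   n_total.
#' @export
read_cx_report <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos1", "strand",
                                        "n_meth", "n_unmeth", "context"),
                          colClasses = list(character = c(1, 3, 6)))
  if (nrow(dt) == 0)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      n_meth = integer(), n_total = integer()))
  ctx <- .cx_context_map[dt$context]
  if (anyNA(ctx)) {
    bad <- unique(dt$context[is.na(ctx)])
    stop("unknown methylation context token(s) in '", path, "': ",
         paste(bad, collapse = ", "))
  }
  if (any(dt$n_meth < 0) || any(dt$n_unmeth < 0))
    stop("negative methylation counts in '", path, "'")
  data.table(chrom = dt$chrom, pos = as.integer(dt$pos1) - 1L,
             strand = dt$strand, context = unname(ctx),
             n_meth = as.integer(dt$n_meth),
             n_total = as.integer(dt$n_meth + dt$n_unmeth))
}

#' @rdname read_cx_report
#' @param records data.table as returned by `read_cx_report`.
#' @export
write_cx_report <- function(records, path) {
  out <- data.table(chrom = records$chrom, pos1 = records$pos + 1L,
                    strand = records$strand, n_meth = records$n_meth,
                    n_unmeth = records$n_total - records$n_meth,
                    context = records$context)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
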