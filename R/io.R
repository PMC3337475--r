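# On-disk formats. All coordinate-convention conversion between the
# package's internal 0-based half-open intervals and any 1-based display
# form happens in this file and nowhere else.

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @param to_upper Uppercase sequences on read? (default `FALSE`; case is
#'   preserved).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, to_upper = FALSE) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids", call. = FALSE)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) stop("empty FASTA record", call. = FALSE)
  bad <- grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn-]", seqs)
  if (any(bad)) {
    stop(sprintf("non-IUPAC characters in record(s): %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  if (to_upper) seqs <- toupper(seqs)
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file (3-6 columns, 0-based half-open).
#' @return Data frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")[1:max_cols(path)],
                          fill = TRUE)
  if (is.null(df$name)) df$name <- "."
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "."
  validate_bed(df)
  df
}

max_cols <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  min(max(3L, length(first)), 6L)
}

validate_bed <- function(df) {
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("BED intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("BED strand must be +, - or .", call. = FALSE)
  }
  invisible(df)
}

#' Write a BED6 file
#'
#' Records are sorted by chrom, start, end before writing.
#'
#' @param df Data frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` (0-based half-open).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  if (is.null(df$name)) df$name <- "."
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "."
  validate_bed(df)
  df <- df[order(df$chrom, df$start, df$end),
           c("chrom", "start", "end", "name", "score", "strand")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert between 1-based inclusive display and BED coordinates
#'
#' The single point of truth for the off-by-one: user-facing reports print
#' 1-based inclusive intervals, everything internal (and BED) is 0-based
#' half-open. `[5, 10]` (1-based inclusive) is BED `4 10`.
#'
#' @param start1,end1 1-based inclusive coordinates.
#' @param start,end 0-based half-open coordinates.
#' @return A list with `start`/`end` (BED) or `start1`/`end1` (display).
#' @export
one_based_to_bed <- function(start1, end1) {
  stopifnot(all(start1 >= 1), all(end1 >= start1))
  list(start = start1 - 1L, end = end1)
}

#' @rdname one_based_to_bed
#' @export
bed_to_one_based <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  list(start1 = start + 1L, end1 = end)
}

#' Site hits as a BED6 data frame
#'
#' Score is `round(100 * score)` as integer display; coordinates stay
#' 0-based half-open.
#'
#' @param hits Hit data frame from [scan_sequence()].
#' @return BED6 data frame.
#' @export
hits_to_bed <- function(hits) {
  data.frame(chrom = hits$seq_id, start = hits$start,
             end = hits$start + hits$length, name = hits$motif_id,
             score = as.integer(round(100 * hits$score)),
             strand = hits$strand, stringsAsFactors = FALSE)
}

#' Module predictions as a BED6 data frame
#'
#' Score is `100 * peak_z` capped at 1000.
#'
#' @param modules Module data frame from [predict_modules()].
#' @return BED6 data frame.
#' @export
modules_to_bed <- function(modules) {
  data.frame(chrom = modules$seq_id, start = modules$start,
             end = modules$end,
             name = sprintf("crm_%d", seq_len(nrow(modules))),
             score = pmin(1000L, as.integer(round(100 * modules$peak_z))),
             strand = rep(".", nrow(modules)), stringsAsFactors = FALSE)
}

#' Write a per-position Z track as bedGraph
#'
#' @param profile A `DensityProfile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_zscore_bedgraph <- function(profile, path) {
  z <- profile$z
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  df <- data.frame(chrom = profile$seq_id, start = starts, end = ends,
                   value = signif(r$values, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a delimited gene table
#'
#' TSV with a header row; first column is the gene id, which becomes the
#' row names / vector names.
#'
#' @param path Input file.
#' @return A named vector when the file has one value column, otherwise a
#'   numeric matrix with gene row names.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate gene ids", call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- ids
  if (ncol(vals) == 1L) stats::setNames(as.numeric(vals[, 1]), ids) else
    vals
}

#' Write a named vector or gene matrix as a TSV
#'
#' @param x Named vector or matrix with row names.
#' @param path Output file.
#' @param value_name Column name used for a vector's values.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path, value_name = "value") {
  if (is.matrix(x)) {
    df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(gene_id = names(x), stats::setNames(list(x), value_name),
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read annotation TSVs into an [annotation_map()]
#'
#' @param term_gene_path TSV with columns `term`, `gene` (header required).
#' @param edge_path Optional TSV with columns `parent`, `child`.
#' @return An `AnnotationMap`.
#' @export
read_annotation <- function(term_gene_path, edge_path = NULL) {
  tg <- utils::read.table(term_gene_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("term", "gene") %in% names(tg)))
  term_genes <- split(tg$gene, tg$term)
  edges <- NULL
  if (!is.null(edge_path)) {
    edges <- utils::read.table(edge_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    stopifnot(all(c("parent", "child") %in% names(edges)))
  }
  annotation_map(term_genes, edges)
}
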