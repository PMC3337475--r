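#' Reciprocal-best-hit ortholog pairs
#'
#' Calls orthologs from two precomputed protein hit tables (A vs B and
#' B vs A). A pair (a, b) is accepted when (i) a's best hit in B is b and
#' b's best hit in A is a; (ii) the E-value is strictly below `e_max` in
#' both directions; and (iii) the alignment covers at least `cov_min` of
#' the length of at least one of the two sequences, in both directional
#' records. Best hits break ties by lowest E-value then lexicographic
#' subject id.
#'
#' @param hits_ab,hits_ba Data frames with columns `query_id`, `subject_id`,
#'   `evalue`, `coverage_query`, `coverage_subject` (fractions in [0, 1]).
#' @param e_max E-value threshold, strict `<` (default 1e-10).
#' @param cov_min Coverage threshold, `>=`, on the better-covered sequence
#'   (default 0.6).
#' @return Data frame with columns `id_a`, `id_b`.
#' @export
rbh_orthologs <- function(hits_ab, hits_ba, e_max = 1e-10, cov_min = 0.6) {
  best_ab <- best_hits(hits_ab)
  best_ba <- best_hits(hits_ba)
  if (nrow(best_ab) == 0L || nrow(best_ba) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  }
  back <- stats::setNames(best_ba$subject_id, best_ba$query_id)
  ok <- vapply(seq_len(nrow(best_ab)), function(i) {
    a <- best_ab$query_id[i]
    b <- best_ab$subject_id[i]
    rec_b <- best_ba[best_ba$query_id == b, ]
    if (nrow(rec_b) == 0L || rec_b$subject_id != a) return(FALSE)
    pass <- function(rec) {
      rec$evalue < e_max &&
        max(rec$coverage_query, rec$coverage_subject) >= cov_min
    }
    pass(best_ab[i, ]) && pass(rec_b)
  }, TRUE)
  out <- data.frame(id_a = best_ab$query_id[ok],
                    id_b = best_ab$subject_id[ok],
                    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

# best hit per query: lowest E-value, ties by lexicographic subject id
best_hits <- function(hits) {
  stopifnot(all(c("query_id", "subject_id", "evalue",
                  "coverage_query", "coverage_subject") %in% names(hits)))
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_id, hits$evalue, hits$subject_id)
  hits <- hits[o, ]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Read a hit table (tabular BLAST-like with coverage columns)
#'
#' Expected columns: query_id, subject_id, evalue, coverage_query,
#' coverage_subject (tab-separated, no header by default).
#'
#' @param path Input file.
#' @param header Does the file carry a header row?
#' @return Data frame suitable for [rbh_orthologs()].
#' @export
read_hit_table <- function(path, header = FALSE) {
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!header) {
    names(df)[1:5] <- c("query_id", "subject_id", "evalue",
                        "coverage_query", "coverage_subject")
  }
  df
}

#' Extract a promoter with the study's conventions
#'
#' Returns the intergenic sequence immediately upstream (5') of the
#' translational start, from -1 back to the nearest neighbouring gene span
#' (regardless of the neighbour's strand) and no more than `max_len` bp.
#' For minus-strand genes the genomic region downstream of `cds_start` is
#' taken and reverse-complemented, so the returned string always reads
#' 5' to 3' toward the ATG.
#'
#' @param gene One row of a gene-model data frame: `gene_id`, `chrom`,
#'   `strand`, `cds_start` (1-based coordinate of the A of the ATG),
#'   and span columns `start`, `end` (1-based inclusive).
#' @param genome Named character vector of chromosome sequences.
#' @param neighbors Gene-model data frame of other genes (same chromosome
#'   rows are used).
#' @param max_len Maximum promoter length in bp (default 2000).
#' @return The promoter DNA string (possibly empty, with a warning).
#' @export
extract_promoter <- function(gene, genome, neighbors = NULL,
                             max_len = 2000L) {
  chrom_seq <- genome[[gene$chrom]]
  if (is.null(chrom_seq)) stop(sprintf("chromosome '%s' not in genome",
                                       gene$chrom), call. = FALSE)
  L <- nchar(chrom_seq)
  if (gene$cds_start < 1 || gene$cds_start > L) {
    stop("cds_start outside chromosome", call. = FALSE)
  }
  nb <- if (is.null(neighbors)) NULL else
    neighbors[neighbors$chrom == gene$chrom &
              neighbors$gene_id != gene$gene_id, , drop = FALSE]
  if (gene$strand == "+") {
    hi <- gene$cds_start - 1L
    lo <- max(1L, gene$cds_start - max_len)
    if (!is.null(nb) && nrow(nb) > 0L) {
      up_ends <- nb$end[nb$end < gene$cds_start]
      if (length(up_ends) > 0L) lo <- max(lo, max(up_ends) + 1L)
    }
    if (hi < lo) {
      warning("zero-length promoter region")
      return("")
    }
    substr(chrom_seq, lo, hi)
  } else {
    lo <- gene$cds_start + 1L
    hi <- min(L, gene$cds_start + max_len)
    if (!is.null(nb) && nrow(nb) > 0L) {
      down_starts <- nb$start[nb$start > gene$cds_start]
      if (length(down_starts) > 0L) hi <- min(hi, min(down_starts) - 1L)
    }
    if (hi < lo) {
      warning("zero-length promoter region")
      return("")
    }
    reverse_complement(substr(chrom_seq, lo, hi))
  }
}

#' Keep only operon-leading genes
#'
#' Genes annotated inside an operon at rank > 1 share the first gene's
#' promoter and are dropped; rank-1 operon genes and non-operon genes are
#' kept.
#'
#' @param genes Gene-model data frame with optional `operon_id`,
#'   `operon_rank` columns (`NA` = not in an operon).
#' @return The filtered data frame.
#' @export
operon_first_filter <- function(genes) {
  if (is.null(genes$operon_rank)) return(genes)
  keep <- is.na(genes$operon_rank) | genes$operon_rank <= 1L
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene models from a 8-column TSV or minimal GFF3 subset
#'
#' TSV columns: gene_id, chrom, start, end, strand, cds_start, operon_id,
#' operon_rank (header required). GFF3: `gene` features are used; `ID=` is
#' the gene id; `cds_start` defaults to the strand-appropriate span edge;
#' optional `operon=`/`operon_rank=` attributes.
#'
#' @param path Input file; format inferred from the `.gff`/`.gff3`
#'   extension.
#' @return Gene-model data frame.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    return(read_gene_models_gff(path))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("gene_id", "chrom", "start", "end", "strand", "cds_start")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$operon_id)) df$operon_id <- NA_character_
  if (is.null(df$operon_rank)) df$operon_rank <- NA_integer_
  df
}

read_gene_models_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t")
  f <- f[vapply(f, length, 1L) == 9L]
  f <- f[vapply(f, function(x) x[3] == "gene", TRUE)]
  if (length(f) == 0L) stop("no gene features in GFF", call. = FALSE)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]+)"), attrs))[[1]]
    if (length(m) == 0L) NA_character_ else m[3]
  }
  rows <- lapply(f, function(x) {
    id <- attr_get(x[9], "ID")
    cds <- attr_get(x[9], "cds_start")
    data.frame(
      gene_id = id, chrom = x[1],
      start = as.integer(x[4]), end = as.integer(x[5]), strand = x[7],
      cds_start = if (is.na(cds)) {
        if (x[7] == "+") as.integer(x[4]) else as.integer(x[5])
      } else as.integer(cds),
      operon_id = attr_get(x[9], "operon"),
      operon_rank = as.integer(attr_get(x[9], "operon_rank")),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
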