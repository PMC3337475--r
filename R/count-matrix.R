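#' Background base composition
#'
#' A validated vector of genomic background frequencies over {A,C,G,T}.
#' Used both for log-odds scoring and for the ALLR similarity statistic.
#'
#' @param freqs Named numeric vector of length 4 (names A, C, G, T) of
#'   strictly positive frequencies summing to 1 within 1e-9. Unnamed vectors
#'   are taken in A, C, G, T order.
#' @return A named numeric vector of class `Background`.
#' @export
#' @examples
#' background()             # uniform
#' background(c(A = 0.32, C = 0.18, G = 0.18, T = 0.32))  # worm-like 36% GC
background <- function(freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!is.numeric(freqs) || length(freqs) != 4L) {
    stop("background frequencies must be a numeric vector of length 4",
         call. = FALSE)
  }
  if (is.null(names(freqs))) names(freqs) <- DNA_BASES
  if (!setequal(names(freqs), DNA_BASES)) {
    stop("background frequencies must be named A, C, G, T", call. = FALSE)
  }
  freqs <- freqs[DNA_BASES]
  if (any(freqs <= 0)) stop("background frequencies must be > 0", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("background frequencies must sum to 1 (within 1e-9)", call. = FALSE)
  }
  structure(freqs, class = "Background")
}

#' Motif count matrix
#'
#' Per-column base counts describing a motif, the raw form in which
#' phylogenetic footprinting programs report discovered elements. Columns are
#' motif positions; rows are A, C, G, T.
#'
#' @param motif_id Motif identifier.
#' @param counts A 4 x W numeric matrix of non-negative counts (rows in
#'   A, C, G, T order; row names optional but checked when present).
#' @param n_sites Number of contributing sites; defaults to the maximum
#'   column total.
#' @param check_length Enforce the study's motif length range of 5-30
#'   columns. Set `FALSE` to override for toy matrices.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(motif_id, counts, n_sites = NULL,
                         check_length = TRUE) {
  assert_string(motif_id, "motif_id")
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A,C,G,T)",
                               call. = FALSE)
  if (!is.null(rownames(counts)) && !identical(rownames(counts), DNA_BASES)) {
    if (!setequal(rownames(counts), DNA_BASES)) {
      stop("count matrix rows must be A, C, G, T", call. = FALSE)
    }
    counts <- counts[DNA_BASES, , drop = FALSE]
  }
  rownames(counts) <- DNA_BASES
  if (ncol(counts) < 1L) stop("count matrix needs at least 1 column",
                              call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and >= 0", call. = FALSE)
  }
  w <- ncol(counts)
  if (check_length && (w < 5L || w > 30L)) {
    stop(sprintf(
      "motif '%s' has %d columns; expected 5-30 (use check_length = FALSE to override)",
      motif_id, w), call. = FALSE)
  }
  if (is.null(n_sites)) n_sites <- max(colSums(counts))
  structure(list(motif_id = motif_id, counts = counts,
                 n_sites = n_sites),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix '%s': %d columns, %s sites\n",
              x$motif_id, ncol(x$counts), format(x$n_sites)))
  print(x$counts)
  invisible(x)
}

#' Number of motif columns
#' @param x A `CountMatrix` or `PWM`.
#' @return Integer width.
#' @export
motif_width <- function(x) {
  if (inherits(x, "CountMatrix")) return(ncol(x$counts))
  if (inherits(x, "PWM")) return(ncol(x$weights))
  stop("motif_width() expects a CountMatrix or PWM", call. = FALSE)
}

#' Reverse complement of a count matrix or PWM
#'
#' Reverses the column order and swaps complementary base rows, so that the
#' returned matrix describes the same motif read on the opposite strand.
#'
#' @param x A `CountMatrix` or `PWM`.
#' @return An object of the same class.
#' @export
reverse_complement_matrix <- function(x) {
  flip <- function(m) {
    m <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
    rownames(m) <- DNA_BASES
    m
  }
  if (inherits(x, "CountMatrix")) {
    x$counts <- flip(x$counts)
  } else if (inherits(x, "PWM")) {
    x$weights <- flip(x$weights)
  } else {
    stop("reverse_complement_matrix() expects a CountMatrix or PWM",
         call. = FALSE)
  }
  x
}

# matrix text formats --------------------------------------------------------

#' Read motif count matrices
#'
#' Two plain-text layouts are supported. The native format has a
#' `>motif_id` header followed by one line per motif column with four
#' tab/space-separated counts in A, C, G, T order. The TRANSFAC-style format
#' uses `ID`/`P0` blocks terminated by `//`, with per-row position counts in
#' columns labelled A C G T.
#'
#' @param path File with one or more matrices.
#' @param format `"native"` or `"transfac"`.
#' @param check_length Passed through to [count_matrix()].
#' @return A named list of `CountMatrix` objects.
#' @export
read_matrices <- function(path, format = c("native", "transfac"),
                          check_length = TRUE) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "native") {
    parse_native_matrices(lines, check_length)
  } else {
    parse_transfac_matrices(lines, check_length)
  }
}

parse_native_matrices <- function(lines, check_length) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' matrix headers found", call. = FALSE)
  ends <- c(heads[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    body <- lines[seq(heads[i] + 1L, ends[i])]
    if (heads[i] + 1L > ends[i] || length(body) == 0L) {
      stop(sprintf("matrix '%s' has no columns", id), call. = FALSE)
    }
    rows <- lapply(strsplit(body, "[\t ]+"), as.numeric)
    if (any(vapply(rows, length, 1L) != 4L) || anyNA(unlist(rows))) {
      stop(sprintf("matrix '%s': each column line needs 4 numeric counts", id),
           call. = FALSE)
    }
    counts <- t(do.call(rbind, rows))  # 4 x W, rows A,C,G,T
    out[[id]] <- count_matrix(id, counts, check_length = check_length)
  }
  if (anyDuplicated(names(out))) stop("duplicate motif ids", call. = FALSE)
  out
}

parse_transfac_matrices <- function(lines, check_length) {
  out <- list()
  id <- NULL
  rows <- NULL
  order_bases <- NULL
  in_block <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (grepl("^(ID|AC|NA)\\s", ln) && is.null(id)) {
      id <- sub("^(ID|AC|NA)\\s+", "", ln)
    } else if (grepl("^P0", ln)) {
      order_bases <- toupper(strsplit(ln, "\\s+")[[1]][-1])[1:4]
      in_block <- TRUE
      rows <- list()
    } else if (grepl("^//", ln)) {
      if (!is.null(rows) && length(rows) > 0L) {
        counts <- t(do.call(rbind, rows))
        rownames(counts) <- order_bases
        counts <- counts[DNA_BASES, , drop = FALSE]
        if (is.null(id)) id <- sprintf("matrix_%d", length(out) + 1L)
        out[[id]] <- count_matrix(id, counts, check_length = check_length)
      }
      id <- NULL; rows <- NULL; in_block <- FALSE
    } else if (in_block && grepl("^[0-9]+\\s", ln)) {
      vals <- strsplit(ln, "\\s+")[[1]]
      rows[[length(rows) + 1L]] <- as.numeric(vals[2:5])
    }
  }
  if (length(out) == 0L) stop("no TRANSFAC matrix blocks found", call. = FALSE)
  out
}

#' Write motif count matrices in the native text format
#'
#' @param matrices A `CountMatrix` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrices <- function(matrices, path) {
  if (inherits(matrices, "CountMatrix")) matrices <- list(matrices)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in matrices) {
    writeLines(paste0(">", m$motif_id), con)
    apply(m$counts, 2, function(col) {
      writeLines(paste(format(col, trim = TRUE), collapse = "\t"), con)
    })
  }
  invisible(path)
}
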