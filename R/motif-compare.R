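#' Per-column ALLR similarity
#'
#' The average log likelihood ratio between two motif columns relative to a
#' common background:
#' \deqn{ALLR = \frac{\sum_b n_b^{(a)} \ln(\hat p_b^{(b)}/q_b) +
#'                    \sum_b n_b^{(b)} \ln(\hat p_b^{(a)}/q_b)}{N_a + N_b}}
#' where counts of one column are scored against the smoothed frequency
#' estimate of the other. Smoothing follows the same pseudocount convention
#' as [counts_to_pwm()] so there is a single smoothing policy in the
#' package. ALLR is symmetric in its two arguments; it is positive for
#' similar informative columns and negative for dissimilar ones.
#'
#' @param col_a,col_b Numeric vectors of 4 base counts (A,C,G,T); positive
#'   totals required.
#' @param bg A [background()] vector.
#' @param pseudo Per-base pseudocount used in the frequency estimates.
#' @return The ALLR value (natural-log units).
#' @export
allr_column <- function(col_a, col_b, bg = background(), pseudo = 0.25) {
  stopifnot(length(col_a) == 4L, length(col_b) == 4L)
  if (sum(col_a) <= 0 || sum(col_b) <= 0) {
    stop("ALLR requires columns with positive total counts", call. = FALSE)
  }
  q <- as.numeric(unclass(background(unclass(bg))))
  pa <- smoothed_freqs(col_a, bg, pseudo)
  pb <- smoothed_freqs(col_b, bg, pseudo)
  # bases with zero count contribute nothing (0 * log 0 = 0 convention,
  # relevant only for unsmoothed estimates)
  term <- function(n, p) sum(n[n > 0] * log(p[n > 0] / q[n > 0]))
  (term(col_a, pb) + term(col_b, pa)) / (sum(col_a) + sum(col_b))
}

#' Optimal ungapped alignment of two count matrices
#'
#' Maximizes the summed per-column ALLR over all relative offsets with at
#' least `min_overlap` overlapping columns, in both the same orientation and
#' with `b` reverse-complemented. Ties are broken deterministically: prefer
#' orientation "same", then the smaller absolute offset, then the larger
#' overlap.
#'
#' @param a,b `CountMatrix` objects.
#' @param bg A [background()] vector.
#' @param pseudo Per-base pseudocount for the ALLR terms.
#' @param min_overlap Minimum overlapping columns considered (default 5, the
#'   shortest motif length in the study; 1-column overlaps give meaningless
#'   ALLR). Capped at the shorter matrix length.
#' @return A list of class `MatrixAlignment` with fields `id_a`, `id_b`,
#'   `offset` (start of `b` relative to `a`, after any reverse complement),
#'   `orientation` ("same" or "rc"), `overlap_cols`, `allr_total`, and
#'   `olap` (= overlap / shorter length).
#' @export
align_matrices <- function(a, b, bg = background(), pseudo = 0.25,
                           min_overlap = 5L) {
  stopifnot(inherits(a, "CountMatrix"), inherits(b, "CountMatrix"))
  la <- ncol(a$counts)
  lb <- ncol(b$counts)
  min_overlap <- min(min_overlap, la, lb)
  best <- NULL
  for (orient in c("same", "rc")) {
    bc <- if (orient == "same") b$counts else
      reverse_complement_matrix(b)$counts
    for (off in seq(-(lb - min_overlap), la - min_overlap)) {
      cols_a <- max(1L, off + 1L):min(la, off + lb)
      cols_b <- cols_a - off
      ov <- length(cols_a)
      if (ov < min_overlap) next
      tot <- 0
      for (k in seq_len(ov)) {
        tot <- tot + allr_column(a$counts[, cols_a[k]], bc[, cols_b[k]],
                                 bg, pseudo)
      }
      cand <- list(id_a = a$motif_id, id_b = b$motif_id, offset = off,
                   orientation = orient, overlap_cols = ov,
                   allr_total = tot, olap = ov / min(la, lb))
      if (is.null(best) || better_alignment(cand, best)) best <- cand
    }
  }
  structure(best, class = "MatrixAlignment")
}

# strict improvement under the deterministic tie-break order
better_alignment <- function(x, y) {
  if (x$allr_total != y$allr_total) return(x$allr_total > y$allr_total)
  if (x$orientation != y$orientation) return(x$orientation == "same")
  if (abs(x$offset) != abs(y$offset)) return(abs(x$offset) < abs(y$offset))
  x$overlap_cols > y$overlap_cols
}

#' Redundancy call for an aligned matrix pair
#'
#' Two matrices are redundant when both the total ALLR and the overlap
#' fraction strictly exceed their thresholds. The defaults are the
#' published calibration constants (best specificity on a curated PWM
#' family benchmark); note the strict inequalities.
#'
#' @param aln A `MatrixAlignment`.
#' @param allr_min ALLR threshold (default 6.57).
#' @param olap_min Overlap-fraction threshold (default 0.681).
#' @return `TRUE` iff `allr_total > allr_min` and `olap > olap_min`.
#' @export
is_redundant <- function(aln, allr_min = 6.57, olap_min = 0.681) {
  stopifnot(inherits(aln, "MatrixAlignment"))
  aln$allr_total > allr_min && aln$olap > olap_min
}

#' Greedy consolidation of redundant motif matrices
#'
#' The highest-ranked matrix is picked as a representative; every remaining
#' matrix redundant to it (per [is_redundant()] on the optimal alignment) is
#' absorbed into its cluster and removed; the next-ranked survivor is picked,
#' and so on until all matrices are consumed. Rank ties break
#' lexicographically on motif id, so the output is deterministic and
#' independent of input order.
#'
#' @param matrices List of `CountMatrix` objects.
#' @param rank_score Numeric vector, one score per matrix (higher = better;
#'   e.g. the discovery program's total ALLR score for the matrix).
#' @param bg A [background()] vector.
#' @param allr_min,olap_min Redundancy thresholds, see [is_redundant()].
#' @param pseudo Per-base pseudocount for the ALLR terms.
#' @param min_overlap Minimum alignment overlap, see [align_matrices()].
#' @return A list of `MotifCluster` objects, each with fields
#'   `representative_id`, `member_ids` (representative first),
#'   `merged_counts` (member counts summed in the representative frame), and
#'   `alignments` (per absorbed member).
#' @export
consolidate_greedy <- function(matrices, rank_score, bg = background(),
                               allr_min = 6.57, olap_min = 0.681,
                               pseudo = 0.25, min_overlap = 5L) {
  if (length(matrices) == 0L) return(list())
  stopifnot(length(rank_score) == length(matrices))
  ids <- vapply(matrices, function(m) m$motif_id, "")
  if (anyDuplicated(ids)) stop("duplicate motif ids", call. = FALSE)
  ord <- order(-rank_score, ids)
  remaining <- ord
  clusters <- list()
  while (length(remaining) > 0L) {
    rep_i <- remaining[1]
    remaining <- remaining[-1]
    rep_m <- matrices[[rep_i]]
    members <- ids[rep_i]
    merged <- rep_m$counts
    alns <- list()
    keep <- logical(length(remaining))
    for (k in seq_along(remaining)) {
      j <- remaining[k]
      aln <- align_matrices(rep_m, matrices[[j]], bg, pseudo, min_overlap)
      if (is_redundant(aln, allr_min, olap_min)) {
        members <- c(members, ids[j])
        merged <- add_aligned_counts(merged, matrices[[j]], aln)
        alns[[ids[j]]] <- aln
      } else {
        keep[k] <- TRUE
      }
    }
    remaining <- remaining[keep]
    clusters[[length(clusters) + 1L]] <- structure(
      list(representative_id = ids[rep_i], member_ids = members,
           merged_counts = count_matrix(paste0(ids[rep_i], "_merged"),
                                        merged, check_length = FALSE),
           alignments = alns),
      class = "MotifCluster")
  }
  clusters
}

# Sum a member's counts into the representative frame over the aligned
# overlap (reverse-complemented first when the alignment says so).
add_aligned_counts <- function(merged, member, aln) {
  mc <- if (aln$orientation == "same") member$counts else
    reverse_complement_matrix(member)$counts
  la <- ncol(merged)
  lb <- ncol(mc)
  cols_a <- max(1L, aln$offset + 1L):min(la, aln$offset + lb)
  cols_b <- cols_a - aln$offset
  merged[, cols_a] <- merged[, cols_a] + mc[, cols_b]
  merged
}

#' Membership table for a consolidation result
#'
#' @param clusters Result of [consolidate_greedy()].
#' @return Data frame with columns `member_id`, `representative_id`, `allr`,
#'   `olap`, `offset`, `orientation` (alignment columns `NA` for the
#'   representatives themselves).
#' @export
membership_table <- function(clusters) {
  rows <- lapply(clusters, function(cl) {
    data.frame(
      member_id = cl$member_ids,
      representative_id = cl$representative_id,
      allr = c(NA, vapply(cl$alignments, function(a) a$allr_total, 0)),
      olap = c(NA, vapply(cl$alignments, function(a) a$olap, 0)),
      offset = c(NA, vapply(cl$alignments, function(a) a$offset, 0L)),
      orientation = c(NA, vapply(cl$alignments, function(a) a$orientation, "")),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
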