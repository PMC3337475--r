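#' Per-position binding-site density
#'
#' Counts, for every position of a sequence, how many predicted sites cover
#' it (coverage convention: a hit at 0-based `start` of length `len` covers
#' positions `start .. start+len-1`).
#'
#' @param hits Site-hit data frame from [scan_sequence()] (columns `start`,
#'   `length` used).
#' @param seq_len Sequence length in bp.
#' @return Integer vector of length `seq_len`.
#' @export
site_density <- function(hits, seq_len) {
  stopifnot(is.numeric(seq_len), seq_len >= 1)
  counts <- integer(seq_len)
  if (is.null(hits) || nrow(hits) == 0L) return(counts)
  if (any(hits$start < 0) || any(hits$start + hits$length > seq_len)) {
    stop("site hit out of sequence bounds", call. = FALSE)
  }
  # difference-array coverage accumulation
  d <- integer(seq_len + 1L)
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i] + 1L
    e <- hits$start[i] + hits$length[i]
    d[s] <- d[s] + 1L
    d[e + 1L] <- d[e + 1L] - 1L
  }
  cumsum(d[seq_len(seq_len)])
}

#' Z-score profile of a density vector
#'
#' Standardizes the per-position site counts against the mean and population
#' standard deviation computed over the positions of the same sequence
#' (per-sequence normalization). A flat profile (sd = 0) has no local
#' enrichment, so all its Z values are defined as 0.
#'
#' @param counts Per-position counts (non-empty numeric vector).
#' @param seq_id Identifier stored on the profile.
#' @return A list of class `DensityProfile` with fields `seq_id`, `counts`,
#'   `mean`, `sd` and `z`.
#' @export
zscore_profile <- function(counts, seq_id = "seq") {
  if (length(counts) == 0L) stop("empty density vector", call. = FALSE)
  m <- mean(counts)
  s <- sqrt(mean((counts - m)^2))  # population SD
  z <- if (s > 0) (counts - m) / s else numeric(length(counts))
  structure(list(seq_id = seq_id, counts = counts, mean = m, sd = s, z = z),
            class = "DensityProfile")
}

#' Peak positions of a density profile
#'
#' All positions whose Z score meets the threshold (inclusive `>=`;
#' the default 3.09 corresponds to an upper-tail normal p-value of 0.001).
#'
#' @param profile A `DensityProfile`.
#' @param z_min Z threshold (default 3.09).
#' @return 0-based positions in ascending order.
#' @export
find_peaks <- function(profile, z_min = 3.09) {
  stopifnot(inherits(profile, "DensityProfile"))
  which(profile$z >= z_min) - 1L
}

#' Grow peaks into predicted modules
#'
#' Peaks are processed from the highest Z down (ties by ascending
#' coordinate). Each unconsumed peak is extended in both directions: the
#' boundary repeatedly jumps to the nearest position with Z > 0 lying
#' strictly less than `max_gap` bp beyond the current boundary. A peak that
#' falls inside a previously grown module is consumed and seeds nothing.
#' Overlapping modules are merged at the end.
#'
#' @param profile A `DensityProfile`.
#' @param peaks 0-based peak positions (subset of positions with
#'   `z >= z_min`); defaults to [find_peaks()].
#' @param max_gap Extension gap bound in bp (default 30, the longest motif
#'   length; "strictly less than" semantics).
#' @param z_min Threshold recorded for diagnostics.
#' @return Data frame of module predictions with columns `seq_id`, `start`,
#'   `end` (0-based half-open), `peak_z`, `n_peaks`.
#' @export
extend_peaks <- function(profile, peaks = find_peaks(profile, z_min),
                         max_gap = 30L, z_min = 3.09) {
  stopifnot(inherits(profile, "DensityProfile"))
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), peak_z = numeric(),
                      n_peaks = integer(), stringsAsFactors = FALSE)
  if (length(peaks) == 0L) return(empty)
  z <- profile$z
  pos_idx <- peaks + 1L  # 1-based
  ord <- order(-z[pos_idx], pos_idx)
  pos_positive <- which(z > 0)  # 1-based, ascending
  modules <- list()
  consumed <- rep(FALSE, length(pos_idx))
  for (k in ord) {
    p <- pos_idx[k]
    if (consumed[k]) next
    # consumed if inside an existing module
    inside <- FALSE
    for (m in modules) if (p >= m[1] && p <= m[2]) { inside <- TRUE; break }
    if (inside) { consumed[k] <- TRUE; next }
    lb <- p
    rb <- p
    repeat {
      nxt <- pos_positive[pos_positive > rb & pos_positive - rb < max_gap]
      if (length(nxt) == 0L) break
      rb <- nxt[length(nxt)]  # absorb every qualifying position up to furthest
    }
    repeat {
      prv <- pos_positive[pos_positive < lb & lb - pos_positive < max_gap]
      if (length(prv) == 0L) break
      lb <- prv[1]
    }
    consumed[k] <- TRUE
    modules[[length(modules) + 1L]] <- c(lb, rb)
  }
  if (length(modules) == 0L) return(empty)
  # merge overlapping/adjacent-by-overlap intervals (inclusive coords)
  mm <- do.call(rbind, modules)
  mm <- mm[order(mm[, 1], mm[, 2]), , drop = FALSE]
  merged <- list(mm[1, ])
  if (nrow(mm) > 1L) {
    for (i in 2:nrow(mm)) {
      last <- merged[[length(merged)]]
      if (mm[i, 1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], mm[i, 2]))
      } else {
        merged[[length(merged)]] <- last
        merged[[length(merged) + 1L]] <- mm[i, ]
      }
    }
  }
  out <- do.call(rbind, lapply(merged, function(m) {
    in_mod <- pos_idx >= m[1] & pos_idx <= m[2]
    data.frame(seq_id = profile$seq_id,
               start = m[1] - 1L,          # back to 0-based, half-open
               end = m[2],
               peak_z = max(z[m[1]:m[2]]),
               n_peaks = sum(in_mod),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Predict cis-regulatory modules from clustered PWM sites
#'
#' The full detector: scan every sequence with every PWM on both strands,
#' accumulate per-position site coverage, standardize to a per-sequence
#' Z profile, call peaks at `z_min`, and grow them into modules with the
#' gap-bounded extension rule. Output is sorted by sequence id then start.
#'
#' @param seqs Named character vector of promoter sequences.
#' @param pwms List of `PWM`s (each needs a cutoff, or pass `p_site`).
#' @param z_min Peak threshold (default 3.09).
#' @param max_gap Extension gap in bp (default 30).
#' @param p_site If given, recompute every PWM's cutoff at this site
#'   probability before scanning.
#' @return Data frame of module predictions (see [extend_peaks()]).
#' @export
predict_modules <- function(seqs, pwms, z_min = 3.09, max_gap = 30L,
                            p_site = NULL) {
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  if (length(seqs) == 0L) stop("no sequences", call. = FALSE)
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), peak_z = numeric(),
                      n_peaks = integer(), stringsAsFactors = FALSE)
  if (length(pwms) == 0L) return(empty)
  if (!is.null(p_site)) {
    pwms <- lapply(pwms, function(p) {
      p$cutoff <- default_cutoff(p, p$background, p_site)
      p
    })
  }
  out <- list()
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    hits <- do.call(rbind, lapply(pwms, scan_sequence, seq = s,
                                  seq_id = sid))
    prof <- zscore_profile(site_density(hits, nchar(s)), sid)
    out[[sid]] <- extend_peaks(prof, find_peaks(prof, z_min), max_gap, z_min)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) return(empty)
  res <- res[order(res$seq_id, res$start, res$end), ]
  rownames(res) <- NULL
  res
}
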