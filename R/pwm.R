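#' Smoothed base frequencies for one motif column
#'
#' The single smoothing policy used throughout: a per-base pseudocount
#' `pseudo` is distributed in proportion to the background, i.e.
#' p_hat(b) = (n_b + 4 * pseudo * q_b) / (N + 4 * pseudo). With uniform
#' background this reduces to plain Laplace smoothing of `pseudo` per base;
#' the default `pseudo = 0.25` adds one total pseudo-observation per column.
#'
#' @param col Numeric vector of 4 base counts (A,C,G,T).
#' @param bg A [background()] vector.
#' @param pseudo Per-base pseudocount, >= 0.
#' @return Vector of 4 smoothed frequencies summing to 1.
#' @keywords internal
smoothed_freqs <- function(col, bg, pseudo) {
  total <- sum(col)
  if (total + 4 * pseudo <= 0) {
    stop("degenerate column: zero total counts and zero pseudocount",
         call. = FALSE)
  }
  (col + 4 * pseudo * unclass(bg)) / (total + 4 * pseudo)
}

#' Convert a count matrix to a log-odds PWM
#'
#' Weight of base b in column j is `ln(p_hat_bj / q_b)` with the smoothed
#' frequency convention of [smoothed_freqs()]. Natural-log units throughout.
#'
#' @param counts A [count_matrix()].
#' @param bg A [background()] vector.
#' @param pseudo Per-base pseudocount (default 0.25, i.e. one total
#'   pseudo-observation per column split by background).
#' @param p_site If non-`NULL`, a site probability passed to
#'   [default_cutoff()] to store a scanning cutoff on the PWM.
#' @return An object of class `PWM` with fields `motif_id`, `weights`
#'   (4 x W log-odds matrix), `background`, and `cutoff` (may be `NA`).
#' @export
#' @examples
#' cm <- count_matrix("m1", matrix(c(10, 0, 0, 0), 4, 6), check_length = TRUE)
#' pwm <- counts_to_pwm(cm, background())
counts_to_pwm <- function(counts, bg = background(), pseudo = 0.25,
                          p_site = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  bg <- background(unclass(bg))
  assert_number(pseudo, "pseudo")
  if (pseudo < 0) stop("`pseudo` must be >= 0", call. = FALSE)
  w <- apply(counts$counts, 2, function(col) {
    log(smoothed_freqs(col, bg, pseudo) / unclass(bg))
  })
  w <- matrix(w, nrow = 4, dimnames = list(DNA_BASES, NULL))
  pwm <- structure(list(motif_id = counts$motif_id, weights = w,
                        background = bg, cutoff = NA_real_),
                   class = "PWM")
  if (!is.null(p_site)) pwm$cutoff <- default_cutoff(pwm, bg, p_site)
  pwm
}

#' Construct a PWM directly from a weight matrix
#'
#' For tests and for motifs whose log-odds form is already known.
#'
#' @param motif_id Motif identifier.
#' @param weights 4 x W numeric matrix of natural-log odds (rows A,C,G,T).
#' @param bg A [background()] vector.
#' @param cutoff Optional scanning cutoff.
#' @return A `PWM`.
#' @export
pwm_from_weights <- function(motif_id, weights, bg = background(),
                             cutoff = NA_real_) {
  assert_string(motif_id, "motif_id")
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == 4L, all(is.finite(weights)))
  rownames(weights) <- DNA_BASES
  structure(list(motif_id = motif_id, weights = weights,
                 background = background(unclass(bg)), cutoff = cutoff),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s': %d columns, cutoff %s\n", x$motif_id,
              ncol(x$weights),
              if (is.na(x$cutoff)) "unset" else format(x$cutoff)))
  print(round(x$weights, 3))
  invisible(x)
}

# sequence encoding ----------------------------------------------------------

# Encode an ACGTN string as integers 1..5 (5 = N / other IUPAC ambiguity).
encode_dna <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  code <- match(v, DNA_BASES)
  code[is.na(code)] <- 5L
  code
}

# Per-column weights extended with a 5th entry: the background-expected
# weight, used for N bases so masked sequence scores neutrally.
extended_weights <- function(pwm) {
  expected <- colSums(pwm$weights * as.numeric(unclass(pwm$background)))
  rbind(pwm$weights, N = expected)
}

#' Reverse-complement a DNA string
#' @param seq DNA string (ACGTN, case-insensitive; case preserved).
#' @return The reverse complement.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(seq, "")[[1]]),
                                       collapse = ""))
}

#' Score one site with a PWM
#'
#' Sum of per-column log-odds weights. `N` (or any ambiguity code)
#' contributes the background-expected weight of its column, a neutral
#' contribution that avoids spurious hits in masked sequence.
#'
#' @param pwm A `PWM`.
#' @param site DNA string of exactly `motif_width(pwm)` characters.
#' @return The log-odds score (natural log).
#' @export
score_site <- function(pwm, site) {
  stopifnot(inherits(pwm, "PWM"))
  code <- encode_dna(site)
  w <- ncol(pwm$weights)
  if (length(code) != w) {
    stop(sprintf("site length %d != PWM width %d", length(code), w),
         call. = FALSE)
  }
  ew <- extended_weights(pwm)
  sum(ew[cbind(code, seq_len(w))])
}

# Vector of window scores at every start of the + strand (0-based starts
# 0..L-W). Internal workhorse for scanning and occupancy.
window_scores <- function(pwm, code) {
  w <- ncol(pwm$weights)
  L <- length(code)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  ew <- extended_weights(pwm)
  scores <- numeric(n)
  idx <- seq_len(n)
  for (j in seq_len(w)) {
    scores <- scores + ew[cbind(code[idx + j - 1L], j)]
  }
  scores
}

#' Scan a sequence on both strands for PWM hits
#'
#' Every start position is scored on the forward strand and, via the
#' reverse-complemented PWM, on the reverse strand. A hit is any window with
#' score >= `cutoff` (ties kept). Coordinates are 0-based; a minus-strand
#' hit's `start` is the leftmost base of the window on the forward strand.
#'
#' @param pwm A `PWM`.
#' @param seq DNA string; sequences shorter than the motif yield an empty
#'   hit table (not an error).
#' @param cutoff Score threshold; defaults to the PWM's stored cutoff.
#' @param seq_id Sequence identifier recorded in the hits.
#' @return A data frame of site hits with columns `seq_id`, `start`,
#'   `strand`, `score`, `motif_id`, `length`, sorted by start then strand.
#' @export
scan_sequence <- function(pwm, seq, cutoff = pwm$cutoff, seq_id = "seq") {
  stopifnot(inherits(pwm, "PWM"))
  if (is.na(cutoff)) stop("no cutoff: set `cutoff` or build the PWM with `p_site`",
                          call. = FALSE)
  code <- encode_dna(seq)
  w <- ncol(pwm$weights)
  empty <- data.frame(seq_id = character(), start = integer(),
                      strand = character(), score = numeric(),
                      motif_id = character(), length = integer(),
                      stringsAsFactors = FALSE)
  if (length(code) < w) return(empty)
  fwd <- window_scores(pwm, code)
  rev_ <- window_scores(reverse_complement_matrix(pwm), code)
  fi <- which(fwd >= cutoff)
  ri <- which(rev_ >= cutoff)
  hits <- rbind(
    data.frame(start = fi - 1L, strand = rep("+", length(fi)),
               score = fwd[fi], stringsAsFactors = FALSE),
    data.frame(start = ri - 1L, strand = rep("-", length(ri)),
               score = rev_[ri], stringsAsFactors = FALSE)
  )
  if (nrow(hits) == 0L) return(empty)
  hits$seq_id <- seq_id
  hits$motif_id <- pwm$motif_id
  hits$length <- w
  hits <- hits[order(hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits[, c("seq_id", "start", "strand", "score", "motif_id", "length")]
}

#' Scan many sequences with many PWMs
#'
#' @param pwms List of `PWM`s.
#' @param seqs Named character vector of sequences.
#' @param cutoff Optional common cutoff; by default each PWM's own.
#' @return Combined hit data frame (see [scan_sequence()]).
#' @export
scan_set <- function(pwms, seqs, cutoff = NULL) {
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  res <- list()
  for (sid in names(seqs)) {
    for (p in pwms) {
      co <- if (is.null(cutoff)) p$cutoff else cutoff
      res[[length(res) + 1L]] <- scan_sequence(p, seqs[[sid]], co, sid)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- scan_sequence(pwms[[1]], "", 0)  # empty frame
  rownames(out) <- NULL
  out
}

# score-distribution cutoff ---------------------------------------------------

#' Exact-DP scanning cutoff for a target site probability
#'
#' Computes, by dynamic programming over the discretized per-column score
#' distributions, the smallest score s such that a random background site
#' scores >= s with probability <= `p_site`. Scores are discretized to
#' `delta` natural-log units (default 0.01), fine enough that the
#' discretization error is negligible against any downstream decision
#' boundary.
#'
#' @param pwm A `PWM`.
#' @param bg A [background()] vector (defaults to the PWM's own).
#' @param p_site Target per-site tail probability in (0, 1].
#' @param delta Discretization bin width in natural-log units.
#' @return The cutoff score (centre of the selected discretization bin).
#' @export
default_cutoff <- function(pwm, bg = pwm$background, p_site = 1e-3,
                           delta = 0.01) {
  stopifnot(inherits(pwm, "PWM"))
  assert_number(p_site, "p_site")
  if (p_site <= 0 || p_site > 1) stop("`p_site` must be in (0, 1]",
                                      call. = FALSE)
  bg <- as.numeric(unclass(background(unclass(bg))))
  bins <- round(pwm$weights / delta)  # integer bin per weight
  # prefix distribution: mass 1 at bin 0, convolved column by column
  cur <- c(1)
  cur_lo <- 0L
  for (j in seq_len(ncol(bins))) {
    col <- bins[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(cur) - 1L + max(col)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + col[b] - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + bg[b] * cur
    }
    cur <- new
    cur_lo <- new_lo
  }
  tail_prob <- rev(cumsum(rev(cur)))  # P(score_bin >= bin at index)
  ok <- which(tail_prob <= p_site + 1e-12)
  if (length(ok) == 0L) return((cur_lo + length(cur)) * delta)  # unattainable
  # snap up to the smallest attainable score with a valid tail, so the
  # cutoff is a real site score (same hit set, cleaner semantics)
  support <- which(cur > 0)
  support <- support[support >= ok[1]]
  if (length(support) == 0L) return((cur_lo + length(cur)) * delta)
  (cur_lo + support[1] - 1L) * delta
}
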