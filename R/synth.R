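# Seeded generators with planted ground truth. Every generator is a pure
# function of (parameters, seed): RNG state is isolated via with_seed().

#' Generate random promoter sequences
#'
#' I.i.d. bases with a specified GC content; the default 0.36 matches the
#' composition of worm intergenic DNA. Sequence ids are `prom001`,
#' `prom002`, ...
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp (default 2000, the study's promoter
#'   window).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return Named character vector of sequences.
#' @export
gen_promoters <- function(n, length = 2000L, gc = 0.36, seed = 1L) {
  stopifnot(gc > 0, gc < 1, n >= 0)
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, length, replace = TRUE, prob = probs),
            collapse = "")
    }, "")
    stats::setNames(seqs, sprintf("prom%03d", seq_len(n)))
  })
}

# per-column base probabilities implied by a PWM (p_b = q_b * e^{w_b},
# renormalized against discretization/pseudocount drift)
pwm_site_probs <- function(pwm) {
  p <- pwm$weights
  q <- as.numeric(unclass(pwm$background))
  p <- exp(p) * q
  sweep(p, 2, colSums(p), "/")
}

#' Plant motif sites into a window of each sequence
#'
#' Writes `count_per_window` non-overlapping sites into the given window of
#' every sequence, sampling each site's bases from the PWM's per-column
#' probability model (not always the consensus, so planted sites have a
#' realistic score spread) and placing it on a random strand. Positions are
#' drawn uniformly among the non-overlapping arrangements.
#'
#' @param seqs Named character vector of sequences.
#' @param pwm A `PWM` whose probability model generates the sites.
#' @param count_per_window Sites to plant per sequence.
#' @param window Integer vector `c(start, end)`: 0-based half-open window
#'   that must fit in every sequence and hold all sites.
#' @param seed Integer seed.
#' @return List with `seqs` (modified sequences) and `truth`, a data frame
#'   of planted sites (`seq_id`, `start`, `strand`, `motif_id`, `length`).
#' @export
plant_sites <- function(seqs, pwm, count_per_window, window, seed = 1L) {
  stopifnot(inherits(pwm, "PWM"), length(window) == 2L)
  w <- ncol(pwm$weights)
  win_len <- window[2] - window[1]
  if (count_per_window * w > win_len) {
    stop("window too small for the requested number of sites", call. = FALSE)
  }
  if (any(nchar(seqs) < window[2])) {
    stop("window does not fit in every sequence", call. = FALSE)
  }
  if (count_per_window == 0L) {
    return(list(seqs = seqs,
                truth = data.frame(seq_id = character(), start = integer(),
                                   strand = character(), motif_id = character(),
                                   length = integer(), stringsAsFactors = FALSE)))
  }
  probs <- pwm_site_probs(pwm)
  with_seed(seed, {
    truth <- list()
    out <- seqs
    for (sid in names(seqs)) {
      # uniform non-overlapping placement: distribute the slack among gaps
      slack <- win_len - count_per_window * w
      offs <- sort(sample.int(slack + 1L, count_per_window,
                              replace = TRUE) - 1L)
      starts <- window[1] + offs + (seq_len(count_per_window) - 1L) * w
      s <- out[[sid]]
      for (i in seq_len(count_per_window)) {
        site <- paste(vapply(seq_len(w), function(j) {
          sample(DNA_BASES, 1L, prob = probs[, j])
        }, ""), collapse = "")
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") site <- reverse_complement(site)
        substr(s, starts[i] + 1L, starts[i] + w) <- site
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = sid, start = starts[i], strand = strand,
          motif_id = pwm$motif_id, length = w, stringsAsFactors = FALSE)
      }
      out[[sid]] <- s
    }
    list(seqs = out, truth = do.call(rbind, truth))
  })
}

#' Generate an expression matrix with planted coherent clusters
#'
#' Members of each planted cluster share a common mean profile (drawn with
#' spread `between_sd` per condition) perturbed by `within_sd` noise;
#' all other genes are independent draws with spread `between_sd`.
#'
#' @param genes Character vector of all gene ids (rows).
#' @param clusters List of character vectors (planted coherent gene sets;
#'   may be empty for a pure-noise matrix).
#' @param n_conditions Number of conditions (columns), >= 2.
#' @param within_sd Within-cluster noise SD (must be < `between_sd` for a
#'   coherent planting).
#' @param between_sd Between-gene spread SD.
#' @param seed Integer seed.
#' @return Numeric matrix, genes x conditions.
#' @export
gen_expression <- function(genes, clusters = list(), n_conditions = 10L,
                           within_sd = 0.2, between_sd = 1, seed = 1L) {
  stopifnot(n_conditions >= 2, between_sd > 0)
  with_seed(seed, {
    m <- matrix(stats::rnorm(length(genes) * n_conditions, sd = between_sd),
                nrow = length(genes),
                dimnames = list(genes,
                                sprintf("cond%02d", seq_len(n_conditions))))
    for (cl in clusters) {
      cl <- intersect(cl, genes)
      if (length(cl) == 0L) next
      centre <- stats::rnorm(n_conditions, sd = between_sd)
      noise <- matrix(stats::rnorm(length(cl) * n_conditions, sd = within_sd),
                      nrow = length(cl))
      m[cl, ] <- matrix(centre, nrow = length(cl), ncol = n_conditions,
                        byrow = TRUE) + noise
    }
    m
  })
}

#' Generate an assay vector with a target correlation to occupancy
#'
#' Mixes the standardized occupancy vector with independent Gaussian noise
#' so that the population correlation equals `r_target`.
#'
#' @param occ Named numeric occupancy vector.
#' @param r_target Target correlation, |r| < 1.
#' @param seed Integer seed.
#' @return Named numeric assay vector (same names as `occ`).
#' @export
gen_assay <- function(occ, r_target, seed = 1L) {
  stopifnot(abs(r_target) < 1)
  z <- as.numeric(scale(occ))
  with_seed(seed, {
    noise <- stats::rnorm(length(occ))
    stats::setNames(r_target * z + sqrt(1 - r_target^2) * noise, names(occ))
  })
}

#' Default planted-module world
#'
#' The stated synthetic world used by the end-to-end recovery checks:
#' 20 promoters of 2 kb at worm-like 36% GC, each with one 150-bp module of
#' 12 planted sites of a well-conserved 10-bp motif, plus 20 unplanted
#' control promoters from the same background.
#'
#' The scan stringency is part of the stated world: a single-motif scan at
#' per-site probability `p_site = 1e-5` keeps the expected number of
#' background hits per 2-kb control promoter far below 1 (so the false
#' module rate stays near zero), while the strongly conserved planted motif
#' still places essentially all of its sampled sites above the cutoff. The
#' looser genome-scale scanning default (1e-3) presumes pooling thousands
#' of matrices, where isolated single hits are absorbed into a dense
#' background instead of standing out.
#'
#' @param seed Integer seed.
#' @param n_planted,n_control Promoter counts.
#' @param prom_len Promoter length (bp).
#' @param window 0-based half-open planted window.
#' @param sites_per_window Planted sites per promoter.
#' @param gc Background GC content.
#' @param p_site Scan stringency carried with the world.
#' @return List with `planted` (sequences), `control` (sequences), `pwm`
#'   (cutoff set at `p_site`), `truth` (planted site table), `window`,
#'   `p_site`.
#' @export
synth_module_world <- function(seed = 1L, n_planted = 20L, n_control = 20L,
                               prom_len = 2000L, window = c(900L, 1050L),
                               sites_per_window = 12L, gc = 0.36,
                               p_site = 1e-5) {
  cm <- synth_motif()
  bg <- background(c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                     T = (1 - gc) / 2))
  pwm <- counts_to_pwm(cm, bg, p_site = p_site)
  planted0 <- gen_promoters(n_planted, prom_len, gc, seed = seed)
  control <- gen_promoters(n_control, prom_len, gc, seed = seed + 1000L)
  names(control) <- sub("prom", "ctrl", names(control))
  pl <- plant_sites(planted0, pwm, sites_per_window, window,
                    seed = seed + 2000L)
  list(planted = pl$seqs, control = control, pwm = pwm, truth = pl$truth,
       window = window, p_site = p_site)
}

#' The planted-module world's motif
#'
#' A strongly conserved 12-bp synthetic motif (100 sites deep; 97% dominant
#' base per column).
#'
#' @return A `CountMatrix`.
#' @export
synth_motif <- function() {
  consensus <- c("T", "G", "A", "T", "A", "A", "G", "C", "A", "T", "C", "A")
  counts <- sapply(consensus, function(b) {
    col <- c(A = 1, C = 1, G = 1, T = 1)
    col[b] <- 97
    col
  })
  colnames(counts) <- NULL
  count_matrix("synthTF1", counts, n_sites = 100)
}
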