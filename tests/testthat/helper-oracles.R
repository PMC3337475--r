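# Independent brute-force oracles. These deliberately avoid the package's
# vectorized/DP code paths: naive loops, enumeration, and closed forms only.

# score one window by explicit per-column lookup
oracle_score <- function(weights, bg, site_chars) {
  s <- 0
  for (j in seq_along(site_chars)) {
    b <- site_chars[j]
    s <- s + if (b %in% rownames(weights)) {
      weights[b, j]
    } else {
      sum(bg * weights[, j])  # N: background expectation
    }
  }
  s
}

# exhaustive double-loop both-strand scan
oracle_scan <- function(pwm, seq, cutoff) {
  w <- ncol(pwm$weights)
  chars <- strsplit(toupper(seq), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  bg <- as.numeric(unclass(pwm$background))
  rows <- list()
  if (length(chars) >= w) {
    for (start in 0:(length(chars) - w)) {
      win <- chars[(start + 1):(start + w)]
      s_plus <- oracle_score(pwm$weights, bg, win)
      s_minus <- oracle_score(pwm$weights, bg, rev(comp[win]))
      if (s_plus >= cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(start = start, strand = "+",
                                                score = s_plus)
      }
      if (s_minus >= cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(start = start, strand = "-",
                                                score = s_minus)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# interval-stabbing coverage counter
oracle_density <- function(hits, seq_len) {
  counts <- integer(seq_len)
  for (pos in seq_len(seq_len)) {
    if (nrow(hits) > 0) {
      for (i in seq_len(nrow(hits))) {
        if (hits$start[i] < pos && pos <= hits$start[i] + hits$length[i]) {
          counts[pos] <- counts[pos] + 1L
        }
      }
    }
  }
  counts
}

# enumerate all offsets x orientations, track the best alignment with the
# package's published tie-break order, using only allr_column()
oracle_align <- function(a, b, bg, pseudo = 0.25, min_overlap = 5L) {
  la <- ncol(a$counts)
  lb <- ncol(b$counts)
  min_overlap <- min(min_overlap, la, lb)
  rc <- function(m) {
    m2 <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m)))]
    rownames(m2) <- c("A", "C", "G", "T")
    m2
  }
  cands <- list()
  for (orient in c("same", "rc")) {
    bc <- if (orient == "same") b$counts else rc(b$counts)
    for (off in -(lb - 1):(la - 1)) {
      tot <- 0
      ov <- 0
      for (ja in seq_len(la)) {
        jb <- ja - off
        if (jb >= 1 && jb <= lb) {
          tot <- tot + cermod::allr_column(a$counts[, ja], bc[, jb], bg,
                                           pseudo)
          ov <- ov + 1
        }
      }
      if (ov >= min_overlap) {
        cands[[length(cands) + 1L]] <- list(offset = off, orientation = orient,
                                            overlap = ov, allr = tot)
      }
    }
  }
  best <- cands[[1]]
  for (c_ in cands[-1]) {
    if (c_$allr > best$allr ||
        (c_$allr == best$allr && c_$orientation == "same" &&
         best$orientation == "rc") ||
        (c_$allr == best$allr && c_$orientation == best$orientation &&
         abs(c_$offset) < abs(best$offset)) ||
        (c_$allr == best$allr && c_$orientation == best$orientation &&
         abs(c_$offset) == abs(best$offset) && c_$overlap > best$overlap)) {
      best <- c_
    }
  }
  best
}

# upper-tail hypergeometric by explicit enumeration of overlap outcomes
oracle_hyper_tail <- function(N, K, n, k) {
  tot <- choose(N, n)
  s <- 0
  for (x in k:min(K, n)) {
    s <- s + choose(K, x) * choose(N - K, n - x)
  }
  s / tot
}

# two-sided Fisher p by enumerating all tables with fixed margins
oracle_fisher_two_sided <- function(a, b, c_, d) {
  r1 <- a + b
  c1 <- a + c_
  N <- a + b + c_ + d
  p_of <- function(x) {
    choose(c1, x) * choose(N - c1, r1 - x) / choose(N, r1)
  }
  p_obs <- p_of(a)
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  sum(vapply(xs, p_of, 0)[vapply(xs, p_of, 0) <= p_obs * (1 + 1e-7)])
}

# random toy matrices / PWMs -------------------------------------------------

random_count_matrix <- function(id, width, depth = 20) {
  counts <- replicate(width, as.numeric(stats::rmultinom(1, depth,
                                                         rep(0.25, 4))))
  rownames(counts) <- c("A", "C", "G", "T")
  cermod::count_matrix(id, counts, check_length = FALSE)
}

# motif-like matrix: each column dominated (90%) by one random base
conserved_count_matrix <- function(id, width, depth = 40) {
  counts <- sapply(seq_len(width), function(j) {
    p <- rep(0.1 / 3, 4)
    p[sample.int(4, 1)] <- 0.9
    as.numeric(stats::rmultinom(1, depth, p))
  })
  rownames(counts) <- c("A", "C", "G", "T")
  cermod::count_matrix(id, counts, check_length = FALSE)
}

random_pwm <- function(id, width, bg = cermod::background()) {
  cermod::counts_to_pwm(random_count_matrix(id, width), bg)
}

random_dna <- function(len, gc = 0.5) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
        collapse = "")
}

expect_same_hits <- function(hits, oracle) {
  expect_equal(nrow(hits), nrow(oracle))
  if (nrow(hits) > 0) {
    expect_equal(hits$start, oracle$start)
    expect_equal(hits$strand, oracle$strand)
    expect_equal(hits$score, oracle$score, tolerance = 1e-12)
  }
}
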