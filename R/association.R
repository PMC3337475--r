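#' Predicted promoter occupancy
#'
#' Sums `exp(score)` over every window position on both strands of the
#' promoter, with no cutoff applied. The result is proportional to the
#' thermodynamically expected occupancy of the promoter by the factor whose
#' specificity the PWM describes; the proportionality constant is
#' deliberately left unfixed because downstream use is via correlation.
#'
#' @param seq Promoter DNA string.
#' @param pwm A `PWM`.
#' @return The occupancy score (> 0 for any sequence at least as long as
#'   the motif; 0 with a warning for shorter sequences).
#' @export
occupancy <- function(seq, pwm) {
  stopifnot(inherits(pwm, "PWM"))
  code <- encode_dna(seq)
  if (length(code) < ncol(pwm$weights)) {
    warning("sequence shorter than motif: occupancy 0")
    return(0)
  }
  fwd <- window_scores(pwm, code)
  rev_ <- window_scores(reverse_complement_matrix(pwm), code)
  sum(exp(fwd)) + sum(exp(rev_))
}

#' Occupancy vector over a promoter set
#'
#' @param seqs Named character vector of promoters.
#' @param pwm A `PWM`.
#' @return Named numeric vector of occupancy scores.
#' @export
occupancy_vector <- function(seqs, pwm) {
  vapply(seqs, occupancy, 0, pwm = pwm)
}

#' Correlation screen of occupancy against an assay vector
#'
#' Pearson correlation on the genes shared between the two named vectors,
#' with the usual t statistic `t = r * sqrt(n-2) / sqrt(1-r^2)` and a
#' two-sided p-value on n-2 degrees of freedom. Perfect correlation is
#' reported with a `t = Inf` sentinel.
#'
#' @param occ Named numeric vector (e.g. from [occupancy_vector()]).
#' @param assay Named numeric vector of per-gene measurements.
#' @return List with `r`, `t`, `n`, `p`.
#' @export
correlate <- function(occ, assay) {
  shared <- intersect(names(occ), names(assay))
  x <- occ[shared]
  y <- assay[shared]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 shared genes with finite values", call. = FALSE)
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    return(list(r = sign(r), t = Inf * sign(r), n = n, p = 0))
  }
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  list(r = r, t = t, n = n, p = p)
}

# Euclidean distance between two profiles, dropping conditions where either
# value is missing (pairwise deletion, no rescaling).
profile_distance <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) return(NA_real_)
  sqrt(sum((a[ok] - b[ok])^2))
}

# Threshold distance: the `pair_quantile` quantile of Euclidean distances
# over gene pairs from the whole matrix (all pairs when feasible, otherwise
# a random sample of `max_pairs`).
threshold_distance <- function(expr, pair_quantile, max_pairs = 20000L) {
  n <- nrow(expr)
  n_all <- n * (n - 1) / 2
  if (n_all <= max_pairs) {
    d <- stats::dist(expr)
    return(stats::quantile(as.numeric(d), pair_quantile, names = FALSE,
                           na.rm = TRUE))
  }
  i <- sample.int(n, max_pairs, replace = TRUE)
  j <- sample.int(n, max_pairs, replace = TRUE)
  keep <- i != j
  d <- sqrt(rowSums((expr[i[keep], , drop = FALSE] -
                     expr[j[keep], , drop = FALSE])^2))
  stats::quantile(d, pair_quantile, names = FALSE, na.rm = TRUE)
}

#' Expression coherence of a gene cluster
#'
#' The expression coherence (EC) score is the fraction of within-cluster
#' gene pairs whose expression-profile Euclidean distance falls below a
#' threshold distance D, where D is the `pair_quantile` quantile of
#' pair distances over the whole matrix. Significance is assessed by Monte
#' Carlo: `n_null` random gene sets of the same size are drawn from the
#' matrix and the p-value is the add-one-smoothed fraction with EC at least
#' as large as observed, `p = (b + 1) / (n_null + 1)`.
#'
#' @param cluster Character vector of gene ids.
#' @param expr Numeric matrix, genes in rows (row names = gene ids),
#'   conditions in columns (>= 2).
#' @param pair_quantile Quantile defining the threshold distance
#'   (default 0.05).
#' @param n_null Number of Monte Carlo null clusters (default 999; must be
#'   >= 1).
#' @param seed Integer seed for the Monte Carlo draw.
#' @return List with `ec`, `p`, `n_genes` (cluster genes found in the
#'   matrix), `threshold` (the distance D).
#' @export
expression_coherence <- function(cluster, expr, pair_quantile = 0.05,
                                 n_null = 999L, seed = 1L) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  if (pair_quantile <= 0 || pair_quantile >= 1) {
    stop("`pair_quantile` must be in (0, 1)", call. = FALSE)
  }
  if (n_null < 1L) stop("`n_null` must be >= 1", call. = FALSE)
  genes <- intersect(cluster, rownames(expr))
  m <- length(genes)
  if (m < 2L) stop("cluster shares < 2 genes with the expression matrix",
                   call. = FALSE)
  with_seed(seed, {
    D <- threshold_distance(expr, pair_quantile)
    # coherence indicator over all matrix gene pairs, computed once
    B <- as.matrix(stats::dist(expr)) <= D
    diag(B) <- FALSE
    idx <- match(genes, rownames(expr))
    npair <- m * (m - 1)
    ec_of <- function(ii) sum(B[ii, ii]) / npair
    ec <- ec_of(idx)
    null_ec <- vapply(seq_len(n_null), function(i) {
      ec_of(sample.int(nrow(expr), m))
    }, 0)
    p <- (sum(null_ec >= ec) + 1) / (n_null + 1)
    list(ec = ec, p = p, n_genes = m, threshold = D)
  })
}

# annotation -----------------------------------------------------------------

#' Annotation map with hierarchy propagation
#'
#' Builds a term-to-gene annotation with parent-to-child edges and computes
#' the propagated gene sets: each term's set is its direct genes plus the
#' genes of all its descendant terms.
#'
#' @param term_genes Named list: term id -> character vector of gene ids.
#' @param edges Optional data frame with columns `parent`, `child` (term
#'   ids); must be acyclic.
#' @return A list of class `AnnotationMap` with `direct`, `edges`, and
#'   `propagated` gene-set lists.
#' @export
annotation_map <- function(term_genes, edges = NULL) {
  stopifnot(is.list(term_genes))
  if (is.null(edges)) {
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  }
  terms <- union(names(term_genes), union(edges$parent, edges$child))
  direct <- lapply(stats::setNames(terms, terms), function(t) {
    unique(term_genes[[t]] %||% character())
  })
  children <- split(edges$child, factor(edges$parent, levels = terms))
  prop <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  propagate <- function(t) {
    if (!is.null(prop[[t]])) return(prop[[t]])
    if (!is.null(visiting[[t]])) stop("annotation hierarchy contains a cycle",
                                      call. = FALSE)
    visiting[[t]] <- TRUE
    g <- direct[[t]]
    for (ch in children[[t]]) g <- union(g, propagate(ch))
    rm(list = t, envir = visiting)
    prop[[t]] <- g
    g
  }
  propagated <- lapply(stats::setNames(terms, terms), propagate)
  structure(list(direct = direct, edges = edges, propagated = propagated),
            class = "AnnotationMap")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hypergeometric term enrichment with child propagation
#'
#' For every annotation term (after propagating descendant gene sets up the
#' hierarchy), computes the upper-tail cumulative hypergeometric p-value of
#' the overlap between the cluster and the term's gene set: with universe
#' size N, term size K, cluster size n and overlap k,
#' `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`.
#'
#' @param cluster Character vector of gene ids (must lie in `universe`).
#' @param ann An [annotation_map()].
#' @param universe Character vector: the gene universe.
#' @return Data frame with `term`, `term_size`, `overlap`, `p`, sorted by
#'   `p`.
#' @export
hypergeom_enrichment <- function(cluster, ann, universe) {
  stopifnot(inherits(ann, "AnnotationMap"))
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  cluster <- unique(cluster)
  if (!all(cluster %in% universe)) {
    stop("cluster contains genes outside the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(cluster)
  rows <- lapply(names(ann$propagated), function(t) {
    term_set <- intersect(ann$propagated[[t]], universe)
    K <- length(term_set)
    k <- length(intersect(term_set, cluster))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, term_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Fisher exact enrichment of a cluster in a gene category
#'
#' Two-sided Fisher exact test on the 2x2 table of cluster membership vs
#' category membership within the universe. The odds ratio is the simple
#' cross-product ratio, with a Haldane correction (+0.5 to every cell) when
#' any cell is zero.
#'
#' @param cluster,category Character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe Gene universe.
#' @return List with `odds_ratio`, `p`, and the `table`.
#' @export
fisher_enrichment <- function(cluster, category, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  cluster <- unique(intersect(cluster, universe))
  category <- unique(intersect(category, universe))
  a <- length(intersect(cluster, category))
  b <- length(setdiff(cluster, category))
  c_ <- length(setdiff(category, cluster))
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("in_cluster", "out_cluster"),
                                c("in_category", "out_category")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(odds_ratio = or, p = p, table = tab)
}

#' Multiple-testing correction
#'
#' Bonferroni: `min(1, m * p)` with m the number of tests. The conservative
#' default used for all reported screens.
#'
#' @param pvals Numeric vector of raw p-values in [0, 1].
#' @param method Only `"bonferroni"`.
#' @return Corrected p-values, same length and order.
#' @export
multitest_correct <- function(pvals, method = "bonferroni") {
  method <- match.arg(method)
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  pmin(1, length(pvals) * pvals)
}
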