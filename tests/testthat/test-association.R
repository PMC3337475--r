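test_that("occupancy sums exponentiated scores over both strands", {
  # all-zero PWM, sequence of motif length: one window x two strands x e^0
  p0 <- pwm_from_weights("z", matrix(0, 4, 4))
  expect_equal(occupancy("ACGT", p0), 2)

  # brute force over all placements on both strands
  set.seed(71)
  for (i in 1:15) {
    w <- sample(2:5, 1)
    pwm <- random_pwm("m", w)
    seq <- random_dna(sample(8:20, 1))
    want <- sum(exp(oracle_scan(pwm, seq, -Inf)$score))
    expect_equal(occupancy(seq, pwm), want, tolerance = 1e-10)
  }

  # appending strongly negative-scoring bases barely changes occupancy
  pwm <- counts_to_pwm(count_matrix("c", matrix(c(5e5, 0, 0, 0), 4, 6),
                                    check_length = FALSE))
  base <- occupancy(strrep("A", 30), pwm)
  ext <- occupancy(paste0(strrep("A", 30), "CCCCCC"), pwm)
  expect_lt((ext - base) / base, 1e-6)
  expect_gt(ext, base)  # strictly increasing in added windows

  # invariant under reverse complementing the promoter
  seq <- random_dna(40)
  expect_equal(occupancy(seq, pwm), occupancy(reverse_complement(seq), pwm),
               tolerance = 1e-12)
  expect_warning(o <- occupancy("ACG", pwm), "shorter")
  expect_equal(o, 0)
})

test_that("correlate reports Pearson r, t and two-sided p", {
  set.seed(81)
  g <- sprintf("g%02d", 1:20)
  x <- stats::setNames(stats::rnorm(20), g)
  y <- stats::setNames(stats::rnorm(20), g)
  res <- correlate(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ref$estimate))
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_equal(res$n, 20L)
  # t formula at r = 0.8, n = 20: 0.8 * sqrt(18) / sqrt(0.36) ~ 5.657
  expect_equal(0.8 * sqrt(18) / sqrt(1 - 0.64), 5.656854, tolerance = 1e-6)

  # affine transform: perfect correlation sentinel
  res2 <- correlate(x, 3 * x + 2)
  expect_equal(res2$r, 1)
  expect_equal(res2$t, Inf)

  # exact zero correlation -> t = 0
  x0 <- stats::setNames(c(-1, 0, 1, 0), sprintf("h%d", 1:4))
  y0 <- stats::setNames(c(0, 1, 0, -1), sprintf("h%d", 1:4))
  expect_equal(correlate(x0, y0)$t, 0)

  expect_error(correlate(x[1:2], y[1:2]), ">= 3")
})

test_that("hypergeom_enrichment equals tail enumeration and propagates", {
  universe <- sprintf("g%02d", 1:10)
  ann <- annotation_map(list(t1 = universe[1:5]))
  res <- hypergeom_enrichment(universe[1:4], ann, universe)
  # N=10, K=5, n=4, k=4 -> C(5,4)C(5,0)/C(10,4) = 5/210
  expect_equal(res$p[res$term == "t1"], 5 / 210)

  # cluster = universe: every term has p = 1
  res2 <- hypergeom_enrichment(universe, ann, universe)
  expect_true(all(res2$p == 1))

  # randomized instances vs the enumeration oracle (N <= 12)
  set.seed(91)
  for (i in 1:50) {
    N <- sample(5:12, 1)
    uni <- sprintf("x%02d", 1:N)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    ann_i <- annotation_map(list(tt = sample(uni, K)))
    cl <- sample(uni, n)
    got <- hypergeom_enrichment(cl, ann_i, uni)
    k <- length(intersect(cl, ann_i$propagated$tt))
    expect_equal(got$p[got$term == "tt"], oracle_hyper_tail(N, K, n, k),
                 tolerance = 1e-12)
  }

  # child propagation: parent's propagated set contains the child's
  ann3 <- annotation_map(
    list(parent = c("g01"), child = c("g02", "g03"),
         grandchild = c("g04")),
    edges = data.frame(parent = c("parent", "child"),
                       child = c("child", "grandchild")))
  expect_setequal(ann3$propagated$parent, c("g01", "g02", "g03", "g04"))
  expect_setequal(ann3$propagated$child, c("g02", "g03", "g04"))
  expect_true(all(ann3$propagated$child %in% ann3$propagated$parent))
  # cycles are rejected
  expect_error(annotation_map(list(a = "g01"),
                              edges = data.frame(parent = c("a", "b"),
                                                 child = c("b", "a"))),
               "cycle")
  expect_error(hypergeom_enrichment("zz", ann, universe), "outside")
})

test_that("fisher_enrichment matches fixed-margin enumeration", {
  # table [[3,1],[1,3]]
  uni <- sprintf("g%02d", 1:8)
  cluster <- uni[1:4]
  category <- c(uni[1:3], uni[5])
  res <- fisher_enrichment(cluster, category, uni)
  expect_equal(res$p, oracle_fisher_two_sided(3, 1, 1, 3), tolerance = 1e-9)
  expect_equal(unname(res$table[1, 1]), 3)

  # no-association case: category splits cluster and complement evenly
  uni2 <- sprintf("h%02d", 1:8)
  res2 <- fisher_enrichment(uni2[1:4], c(uni2[1:2], uni2[5:6]), uni2)
  expect_equal(res2$p, 1)

  # randomized tables vs enumeration
  set.seed(101)
  for (i in 1:40) {
    N <- sample(6:14, 1)
    u <- sprintf("u%02d", 1:N)
    cl <- sample(u, sample(1:N, 1))
    cat_ <- sample(u, sample(1:N, 1))
    got <- fisher_enrichment(cl, cat_, u)
    a <- length(intersect(cl, cat_))
    b <- length(setdiff(cl, cat_))
    cc <- length(setdiff(cat_, cl))
    d <- N - a - b - cc
    expect_equal(got$p, oracle_fisher_two_sided(a, b, cc, d),
                 tolerance = 1e-7)
  }

  # Haldane-corrected odds ratio when a cell is zero
  res3 <- fisher_enrichment(c("u01", "u02"), c("u01", "u02"),
                            sprintf("u%02d", 1:6))
  expect_equal(res3$odds_ratio, (2.5 * 4.5) / (0.5 * 0.5))
  expect_error(fisher_enrichment("a", "a", character()), "empty")
})

test_that("multitest_correct applies Bonferroni", {
  expect_equal(multitest_correct(0.02), 0.02)              # m = 1
  expect_equal(multitest_correct(rep(0.01, 50))[1], 0.5)   # m * p
  p <- c(0.5, 0.001, 0.2, 0.9)
  expect_equal(order(multitest_correct(p)), order(p))      # order preserved
  expect_true(all(multitest_correct(p) <= 1))
})

test_that("expression_coherence scores planted structure correctly", {
  genes <- sprintf("g%03d", 1:120)
  # identical member profiles -> EC = 1
  expr <- gen_expression(genes, list(genes[1:10]), n_conditions = 8,
                         within_sd = 0, seed = 7)
  res <- expression_coherence(genes[1:10], expr, n_null = 99, seed = 11)
  expect_equal(res$ec, 1)
  expect_lt(res$p, 0.05)

  # strongly coherent planting is significant
  expr2 <- gen_expression(genes, list(genes[1:10]), n_conditions = 8,
                          within_sd = 0.1, between_sd = 1, seed = 8)
  res2 <- expression_coherence(genes[1:10], expr2, n_null = 199, seed = 12)
  expect_lt(res2$p, 0.05)

  expect_error(expression_coherence(genes[1:10], expr2, n_null = 0),
               "n_null")
  expect_error(expression_coherence(genes[1], expr2), "< 2 genes")
})

test_that("mean EC of random clusters approximates the pair quantile", {
  genes <- sprintf("g%03d", 1:150)
  expr <- gen_expression(genes, list(), n_conditions = 12, seed = 17)
  set.seed(19)
  ecs <- vapply(1:200, function(i) {
    expression_coherence(sample(genes, 15), expr, pair_quantile = 0.05,
                         n_null = 1, seed = i)$ec
  }, 0)
  # calibration: random clusters' mean EC ~ pair_quantile
  expect_lt(abs(mean(ecs) - 0.05), 0.02)
})
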