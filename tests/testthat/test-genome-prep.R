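hits_df <- function(q, s, e, cq, cs) {
  data.frame(query_id = q, subject_id = s, evalue = e,
             coverage_query = cq, coverage_subject = cs,
             stringsAsFactors = FALSE)
}

test_that("rbh_orthologs applies the three criteria", {
  # mutual best hits, good e-value, coverage 0.8/0.5: accepted
  ab <- hits_df("a1", "b1", 1e-20, 0.8, 0.5)
  ba <- hits_df("b1", "a1", 1e-20, 0.5, 0.8)
  expect_equal(rbh_orthologs(ab, ba),
               data.frame(id_a = "a1", id_b = "b1",
                          stringsAsFactors = FALSE))

  # e-value at 1e-9 fails the strict < 1e-10 bound
  expect_equal(nrow(rbh_orthologs(hits_df("a1", "b1", 1e-9, 0.9, 0.9),
                                  hits_df("b1", "a1", 1e-9, 0.9, 0.9))), 0L)
  # boundary: exactly 1e-10 is rejected, just under passes
  expect_equal(nrow(rbh_orthologs(hits_df("a1", "b1", 1e-10, 0.9, 0.9),
                                  hits_df("b1", "a1", 1e-10, 0.9, 0.9))), 0L)
  # coverage must reach 0.6 on at least one sequence
  expect_equal(nrow(rbh_orthologs(hits_df("a1", "b1", 1e-20, 0.5, 0.59),
                                  hits_df("b1", "a1", 1e-20, 0.59, 0.5))), 0L)
})

test_that("rbh_orthologs on a 4-gene toy table matches the manual trace", {
  # a1's best is b1 but b1's best is a2 -> (a1,b1) rejected;
  # (a2,b1) mutual; (a3,b2) mutual
  ab <- rbind(hits_df("a1", "b1", 1e-30, 0.9, 0.9),
              hits_df("a2", "b1", 1e-40, 0.9, 0.9),
              hits_df("a3", "b2", 1e-25, 0.7, 0.4),
              hits_df("a3", "b1", 1e-12, 0.5, 0.5))
  ba <- rbind(hits_df("b1", "a2", 1e-40, 0.9, 0.9),
              hits_df("b1", "a1", 1e-30, 0.9, 0.9),
              hits_df("b2", "a3", 1e-25, 0.4, 0.7))
  got <- rbh_orthologs(ab, ba)
  expect_equal(got$id_a, c("a2", "a3"))
  expect_equal(got$id_b, c("b1", "b2"))

  # symmetry: swapped tables give the mirrored pair set
  rev_ <- rbh_orthologs(ba, ab)
  expect_setequal(paste(rev_$id_a, rev_$id_b),
                  paste(got$id_b, got$id_a))

  # best-hit ties break by lowest e-value then lexicographic subject
  tie_ab <- rbind(hits_df("a1", "b2", 1e-30, 0.9, 0.9),
                  hits_df("a1", "b1", 1e-30, 0.9, 0.9))
  tie_ba <- rbind(hits_df("b1", "a1", 1e-30, 0.9, 0.9),
                  hits_df("b2", "a1", 1e-30, 0.9, 0.9))
  got2 <- rbh_orthologs(tie_ab, tie_ba)
  expect_equal(got2$id_b, "b1")
})

genome_toy <- function() {
  # 50-bp contig
  list(chrI = "ACGTACGTACGTACGTACGTAAAAACCCCCGGGGGTTTTTACGTACGTAC")
}

test_that("extract_promoter respects neighbours, the 2-kb cap and strand", {
  genome <- genome_toy()
  plus_gene <- data.frame(gene_id = "gp", chrom = "chrI", strand = "+",
                          start = 31, end = 45, cds_start = 31,
                          stringsAsFactors = FALSE)
  # no neighbours: promoter runs to the contig start, max_len capped
  p <- extract_promoter(plus_gene, genome, max_len = 10)
  expect_equal(p, substr(genome$chrI, 21, 30))
  expect_equal(nchar(extract_promoter(plus_gene, genome, max_len = 2000)), 30)

  # neighbour 10 bp upstream truncates the promoter
  nb <- data.frame(gene_id = "up", chrom = "chrI", strand = "+",
                   start = 1, end = 20, cds_start = 1,
                   stringsAsFactors = FALSE)
  p2 <- extract_promoter(plus_gene, genome, nb)
  expect_equal(p2, substr(genome$chrI, 21, 30))
  expect_equal(nchar(p2), 10)

  # minus-strand gene: upstream is to the right, reverse-complemented
  minus_gene <- data.frame(gene_id = "gm", chrom = "chrI", strand = "-",
                           start = 5, end = 20, cds_start = 20,
                           stringsAsFactors = FALSE)
  p3 <- extract_promoter(minus_gene, genome, max_len = 5)
  # genomic [21,25] = "AAAAA" -> revcomp "TTTTT"
  expect_equal(p3, "TTTTT")
  nb2 <- data.frame(gene_id = "dn", chrom = "chrI", strand = "+",
                    start = 24, end = 40, cds_start = 24,
                    stringsAsFactors = FALSE)
  p4 <- extract_promoter(minus_gene, genome, nb2, max_len = 2000)
  expect_equal(p4, reverse_complement(substr(genome$chrI, 21, 23)))

  # abutting neighbour: zero-length promoter with a warning
  nb3 <- nb
  nb3$end <- 30
  expect_warning(p5 <- extract_promoter(plus_gene, genome, nb3), "zero")
  expect_equal(p5, "")
})

test_that("promoters never overlap neighbours and never exceed 2 kb", {
  set.seed(131)
  chrom <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  genome <- list(chr = chrom)
  for (i in 1:20) {
    cds <- sample(2500:5500, 1)
    gene <- data.frame(gene_id = "g", chrom = "chr",
                       strand = sample(c("+", "-"), 1),
                       start = cds, end = min(6000, cds + 100),
                       cds_start = cds, stringsAsFactors = FALSE)
    nb_end <- sample(1:2400, 1)
    nb <- data.frame(gene_id = "n", chrom = "chr", strand = "+",
                     start = nb_end - 100, end = nb_end, cds_start = nb_end,
                     stringsAsFactors = FALSE)
    p <- extract_promoter(gene, genome, nb)
    expect_lte(nchar(p), 2000)
    if (gene$strand == "+") {
      # the promoter is immediately 5' of the ATG
      expect_equal(p, substr(chrom, cds - nchar(p), cds - 1))
      expect_gt(cds - nchar(p), nb_end)  # no overlap with the neighbour
    } else {
      expect_equal(p, reverse_complement(substr(chrom, cds + 1,
                                                cds + nchar(p))))
    }
  }
})

test_that("operon_first_filter drops distal operon genes only", {
  genes <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    chrom = "chrI", strand = "+", start = 1, end = 10, cds_start = 1,
    operon_id = c(NA, "op1", "op1", "op1", NA, "op2"),
    operon_rank = c(NA, 1, 2, 3, NA, 1),
    stringsAsFactors = FALSE)
  kept <- operon_first_filter(genes)
  expect_equal(kept$gene_id, c("g1", "g2", "g5", "g6"))
})

test_that("gene model and hit table readers round-trip", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand\tcds_start\toperon_id\toperon_rank",
               "g1\tchrI\t1\t500\t+\t100\top1\t1",
               "g2\tchrI\t600\t900\t-\t850\tNA\tNA"), tsv)
  gm <- read_gene_models(tsv)
  expect_equal(gm$gene_id, c("g1", "g2"))
  expect_equal(gm$cds_start, c(100L, 850L))

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chrI", "src", "gene", "1", "500", ".", "+", ".",
                     "ID=g1;cds_start=100;operon=op1;operon_rank=1",
                     sep = "\t"),
               paste("chrI", "src", "gene", "600", "900", ".", "-", ".",
                     "ID=g2", sep = "\t")), gff)
  gg <- read_gene_models(gff)
  expect_equal(gg$gene_id, c("g1", "g2"))
  expect_equal(gg$cds_start, c(100L, 900L))  # minus strand defaults to end
  expect_equal(gg$operon_rank, c(1L, NA_integer_))

  ht <- tempfile(fileext = ".tsv")
  writeLines("a1\tb1\t1e-20\t0.8\t0.5", ht)
  expect_equal(read_hit_table(ht)$subject_id, "b1")
})
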