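test_that("nearest neighbour distance, direction and tie rule", {
  ref <- annotation_index(transcript_set(data.frame(
    chrom = "chr1", start = c(2001, 7001), end = c(3000, 9000),
    strand = "+", transcript_id = c("GA.1", "GB.1"),
    gene_id = c("GA", "GB")), source = "reference"))
  q <- function(s, e) transcript_set(data.frame(
    chrom = "chr1", start = s, end = e, strand = "+", transcript_id = "Q"))
  # gap of 1000 to the downstream gene
  nn <- nearest_neighbour(q(5001, 6000), ref)
  expect_equal(nn$distance_nt, 1000)
  expect_equal(nn$nearest_locus_id, "GB")
  expect_equal(nn$direction, "downstream")
  # equidistant (500 nt both sides): the upstream locus wins
  nn2 <- nearest_neighbour(q(3501, 6500), ref)
  expect_equal(nn2$distance_nt, 500)
  expect_equal(nn2$nearest_locus_id, "GA")
  expect_equal(nn2$direction, "upstream")
  # touching counts as zero
  expect_equal(nearest_neighbour(q(3001, 3200), ref)$distance_nt, 0)
  # no locus on the chromosome: infinite sentinel
  qx <- transcript_set(data.frame(chrom = "chrX", start = 10, end = 20,
                                  strand = "+", transcript_id = "Q"))
  expect_equal(nearest_neighbour(qx, ref)$distance_nt, Inf)
  expect_true(is.na(nearest_neighbour(qx, ref)$nearest_locus_id))
})

test_that("nearest neighbour equals the linear-scan oracle on random placements", {
  sim <- fixture_sim()
  idx <- annotation_index(sim$reference)
  spans <- idx$locus_spans
  loci <- data.frame(chrom = as.character(GenomicRanges::seqnames(spans)),
                     start = GenomicRanges::start(spans),
                     end = GenomicRanges::end(spans),
                     gene_id = spans$gene_id)
  set.seed(77)
  n <- 500
  chrom <- paste0("chr", sample(length(sim$genome), n, replace = TRUE))
  start <- sample(350000, n, replace = TRUE)
  width <- sample(100:3000, n, replace = TRUE)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + width - 1))
  q$transcript_id <- paste0("R", seq_len(n))
  nn <- nearest_neighbour(q, idx)
  for (i in seq_len(n)) {
    want <- oracle_nearest(chrom[i], start[i], start[i] + width[i] - 1, loci)
    expect_equal(nn$distance_nt[i], want$dist)
    if (is.finite(want$dist)) {
      expect_equal(nn$nearest_locus_id[i], want$gene)
      expect_equal(nn$direction[i], want$direction)
    }
  }
})

test_that("lncRNA, lincRNA and UTR-association flags follow the definitions", {
  f <- call_lnc(length = c(250, 250, 150, 201, 200),
                consensus = c("noncoding", "noncoding", "noncoding",
                              "noncoding", "noncoding"),
                distance = c(5000, 800, 5000, 1000, 5000))
  expect_equal(f$is_lncRNA, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(f$is_utr_associated, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(f$is_lincRNA, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # a coding transcript is never an lncRNA regardless of length
  expect_false(call_lnc(1000, "coding", 5000)$is_lncRNA)
  # lincRNA implies lncRNA by construction
  expect_true(all(!f$is_lincRNA | f$is_lncRNA))
})

test_that("raising the UTR window never increases the lincRNA count", {
  run <- fixture_run()
  tr <- run$transcripts
  prev <- Inf
  for (w in c(500, 1000, 2000, 5000)) {
    f <- call_lnc(tr$length, tr$consensus, tr$distance_nt, utr_dist = w)
    expect_lte(sum(f$is_lincRNA), prev)
    prev <- sum(f$is_lincRNA)
  }
})

test_that("evidence integration applies the precedence rules", {
  flags <- function(lnc, linc, utr) data.frame(
    is_lncRNA = lnc, is_utr_associated = utr, is_lincRNA = linc)
  # conserved similarity + noncoding consensus
  out <- integrate_evidence("noncoding", "lncRNA_conserved",
                            flags(TRUE, TRUE, FALSE))
  expect_equal(out$final, "lncRNA_conserved")
  # pseudogene inference overrides a coding consensus
  out <- integrate_evidence("coding", "potential_pseudogene",
                            flags(FALSE, FALSE, FALSE))
  expect_equal(out$final, "potential_pseudogene")
  expect_match(out$evidence, "homology_override")
  # plain coding consensus
  expect_equal(integrate_evidence("coding", "none",
                                  flags(FALSE, FALSE, FALSE))$final,
               "novel_coding")
  # inconsistent passes through untouched
  expect_equal(integrate_evidence("inconsistent", "none",
                                  flags(FALSE, FALSE, FALSE))$final,
               "inconsistent")
  # noncoding subdivision by position and length
  expect_equal(integrate_evidence("noncoding", "none",
                                  flags(TRUE, TRUE, FALSE))$final,
               "lincRNA_candidate")
  expect_equal(integrate_evidence("noncoding", "none",
                                  flags(TRUE, FALSE, TRUE))$final,
               "lncRNA_candidate")
  expect_equal(integrate_evidence("noncoding", "none",
                                  flags(FALSE, FALSE, FALSE))$final,
               "short_ncRNA_candidate")
})

test_that("summaries bin, count and filter as specified", {
  cl <- data.frame(transcript_id = c("A", "B", "C"),
                   chrom = c("chr1", "chr1", "chr2"),
                   length = c(100, 500, 3000),
                   distance_nt = c(500, 1500, 12000),
                   final_category = c("short_ncRNA_candidate",
                                      "lincRNA_candidate",
                                      "lincRNA_candidate"))
  s <- summarize_classification(cl, length_breaks = c(0, 1000, Inf))
  expect_equal(s$length_histogram$count, c(2L, 1L))
  expect_equal(sum(s$category_counts$count), 3L)
  expect_equal(s$distance_histogram$count[s$distance_histogram$from == 0], 1L)
  # the expression summary excludes transcripts at or under 105 nt
  expr <- toy_expression(c("A", "B", "C"))
  expr$fpkm_pig <- c(1000, 2, 4)
  s2 <- summarize_classification(cl, expr, length_breaks = c(0, Inf))
  ch1 <- s2$expression_by_chromosome
  expect_equal(ch1$fpkm_pig[ch1$chrom == "chr1"], 2)  # A (100 nt) excluded
})

test_that("query locus context lists flanking genes per side", {
  ref <- annotation_index(toy_reference())
  q <- transcript_set(data.frame(chrom = "chr1", start = 5001, end = 6000,
                                 strand = "+", transcript_id = "Q"))
  ctx <- locus_context(q, ref)
  expect_equal(ctx$upstream_gene, "G1")
  expect_equal(ctx$downstream_gene, "G2")
  # nothing upstream at the chromosome start
  q2 <- transcript_set(data.frame(chrom = "chr1", start = 10, end = 100,
                                  strand = "+", transcript_id = "Q"))
  ctx2 <- locus_context(q2, ref)
  expect_true(is.na(ctx2$upstream_gene))
  expect_equal(ctx2$downstream_gene, "G1,G2")
})
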