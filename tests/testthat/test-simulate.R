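test_that("generation is fully deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 5, n_reference_genes = 8,
                           n_predicted_genes = 3,
                           plants = c(known_isoform = 2, intronic = 2,
                                      intergenic_noncoding = 4,
                                      novel_coding = 2, utr_extension = 2,
                                      pseudogene_copy = 2,
                                      conserved_lncRNA = 2, short_ncRNA = 2,
                                      predicted_match = 2,
                                      low_expression = 2))
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$corpora, s2$corpora)
})

test_that("genome shape and composition follow the configuration", {
  cfg <- simulation_config(seed = 9, n_chromosomes = 2, chrom_length = 50000,
                           gc = 0.5)
  g <- generate_genome(cfg)
  expect_length(g, 2L)
  n <- nchar(g[[1]])
  gc_obs <- sum(strsplit(g[[1]], "")[[1]] %in% c("G", "C")) / n
  # binomial 3-sd bound around the configured GC
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / n))
  expect_error(generate_genome(simulation_config(chrom_length = 0)))
})

test_that("annotations respect spacing and predicted/reference disjointness", {
  sim <- fixture_sim()
  ref <- sim$reference
  expect_length(unique(ref$gene_id), 24L)
  pred <- sim$predicted
  ov <- GenomicRanges::findOverlaps(pred, ref, ignore.strand = TRUE)
  expect_length(ov, 0L)
  # adjacent reference genes keep a >= 1 kb gap
  spans <- annotation_index(ref)$locus_spans
  for (chr in unique(as.character(GenomicRanges::seqnames(spans)))) {
    on <- spans[as.character(GenomicRanges::seqnames(spans)) == chr]
    on <- on[order(GenomicRanges::start(on))]
    if (length(on) > 1) {
      gaps <- GenomicRanges::start(on)[-1] -
        GenomicRanges::end(on)[-length(on)]
      expect_true(all(gaps > 1000))
    }
  }
})

test_that("plants carry their designed properties", {
  sim <- fixture_sim()
  tr <- sim$truth; pl <- sim$plants
  # zero-CI plants are exactly the low-expression category and are filtered
  flt <- filter_low_expression(tx_ids(sim$assembly), sim$expression)
  expect_setequal(flt$removed,
                  tr$transcript_id[tr$category == "low_expression"])
  # UTR extensions sit within 1 kb of their neighbour gene
  nn <- nearest_neighbour(sim$assembly, annotation_index(sim$reference))
  utr_ids <- tr$transcript_id[tr$category == "utr_extension"]
  expect_true(all(nn$distance_nt[match(utr_ids, nn$transcript_id)] <= 1000))
  # intergenic noncoding plants lie beyond the 1 kb window
  linc_ids <- tr$transcript_id[tr$category == "intergenic_noncoding"]
  expect_true(all(nn$distance_nt[match(linc_ids, nn$transcript_id)] > 1000))
  # novel coding plants contain an ATG-anchored ORF of at least 300 nt
  seqs <- spliced_sequence(sim$assembly, sim$genome,
                           ids = tr$transcript_id[tr$category == "novel_coding"])
  for (s in as.character(seqs))
    expect_gte(longest_orf(s)$length_nt, 300L)
  # short ncRNA plants are at most 200 nt
  short_len <- pl$length[pl$category == "short_ncRNA"]
  expect_true(all(short_len <= 200))
  # single-exon bias near the configured fraction
  n_ex <- table(sim$assembly$transcript_id)
  expect_gt(mean(n_ex == 1), 0.8)
})

test_that("planted hits pass screening and curation; decoys straddle and fail", {
  sim <- fixture_sim_decoys()
  qlens <- setNames(sim$plants$length, sim$plants$transcript_id)
  p <- tempfile()
  write.table(sim$hits$inter, p, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  h <- read_hit_table(p, qlens, context = sim$hits$context)
  s <- screen_hits(h)
  spans <- GenomicRanges::GRanges(sim$plants$chrom,
    IRanges::IRanges(sim$plants$start, sim$plants$end))
  spans$transcript_id <- sim$plants$transcript_id
  qctx <- locus_context(spans, annotation_index(sim$reference))
  cu <- curate_hits(s, qctx)
  # every conserved plant retains a curated syntenic hit
  cons <- sim$truth$transcript_id[sim$truth$category == "conserved_lncRNA"]
  expect_true(all(cons %in% cu$qseqid[cu$syntenic %in% TRUE]))
  # every pseudogene copy retains a curated hit with discordant context
  ps <- sim$truth$transcript_id[sim$truth$category == "pseudogene_copy"]
  expect_true(all(ps %in% cu$qseqid[cu$syntenic %in% FALSE]))
  # decoys at 89.9 identity / covered < 100 never survive screening
  expect_false(any(grepl("DECOYA|DECOYB", s$sseqid)))
  # the curated decoy is never syntenic, the intraspecies decoy never curated
  expect_true(all(cu$syntenic[grepl("DECOYC", cu$sseqid)] %in% FALSE))
  pi <- tempfile()
  write.table(sim$hits$intra, pi, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  hi <- read_hit_table(pi, qlens, context = sim$hits$context)
  si <- screen_hits(hi)
  expect_gt(nrow(si), 0L)                     # decoys do pass screening
  cui <- curate_hits(si, qctx)
  expect_false(any(grepl("BTDECOY", cui$sseqid)))  # but never curation
})

test_that("file output round trips through the pipeline readers", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 13, n_reference_genes = 6,
                           n_predicted_genes = 2,
                           plants = c(known_isoform = 1, intronic = 1,
                                      intergenic_noncoding = 3,
                                      novel_coding = 2, utr_extension = 1,
                                      pseudogene_copy = 1,
                                      conserved_lncRNA = 1, short_ncRNA = 1,
                                      predicted_match = 1,
                                      low_expression = 1))
  sim <- simulate_dataset(cfg, dir = dir)
  back <- read_gtf(sim$files$assembly, "assembly")
  expect_setequal(tx_ids(back), tx_ids(sim$assembly))
  expect_equal(spliced_lengths(back)[tx_ids(sim$assembly)],
               spliced_lengths(sim$assembly))
  expr <- read_expression(sim$files$expression)
  expect_equal(nrow(expr), nrow(sim$expression))
  genome <- Biostrings::readDNAStringSet(sim$files$genome)
  expect_equal(as.character(genome[[1]]), as.character(sim$genome[[1]]))
})
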