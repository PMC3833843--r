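write_hits <- function(rows) {
  p <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), p)
  p
}

hit_line <- function(qid, sid, pident, qstart, qend, db = "refseq",
                     species = "human") {
  c(qid, sid, pident, qend - qstart + 1, 5, 0, qstart, qend, 1,
    qend - qstart + 1, "1e-20", 200, db, species)
}

test_that("hit tables parse, derive and validate", {
  p <- write_hits(list(hit_line("Q1", "S1", 92, 11, 260)))
  h <- read_hit_table(p, c(Q1 = 500))
  expect_equal(nrow(h), 1L)
  expect_equal(h$covered_region, 250)
  expect_equal(h$total_identity, 92 * 250 / 500)
  # column-count mismatch names the line
  p2 <- write_hits(list(hit_line("Q1", "S1", 92, 11, 260), c("too", "short")))
  expect_error(read_hit_table(p2, c(Q1 = 500)), "line 2")
  # covered region beyond the query length is invalid
  p3 <- write_hits(list(hit_line("Q1", "S1", 92, 1, 600)))
  expect_error(read_hit_table(p3, c(Q1 = 500)), "covered region")
  # empty file -> empty table
  p4 <- tempfile(); file.create(p4)
  expect_equal(nrow(read_hit_table(p4, c(Q1 = 500))), 0L)
  expect_error(read_hit_table(p, c(OTHER = 1)), "Q1")
})

test_that("screening applies the mode-specific cuts", {
  p <- write_hits(list(
    hit_line("Q1", "S1", 92, 6, 255),                      # total 90.2 pass
    hit_line("Q1", "S2", 80, 6, 95),                       # covered < 100
    hit_line("Q2", "S3", 85, 1, 200, species = "bovine"),  # intra, id < 90
    hit_line("Q2", "S4", 95, 1, 200, species = "bovine")))
  h <- read_hit_table(p, c(Q1 = 255, Q2 = 205))
  s <- screen_hits(h)
  expect_setequal(s$sseqid, c("S1", "S4"))
  expect_equal(s$screen_mode[s$sseqid == "S4"], "intraspecies")
  # under forced interspecies mode S3 still fails on total identity (82.9)
  s2 <- screen_hits(h, mode = "interspecies")
  expect_false("S3" %in% s2$sseqid)
})

test_that("screening is monotone in every threshold", {
  set.seed(71)
  rows <- lapply(1:80, function(i) {
    qe <- sample(80:300, 1)
    hit_line(paste0("Q", i), paste0("S", i), round(runif(1, 60, 100), 1),
             1, qe, species = sample(c("human", "bovine"), 1))
  })
  h <- read_hit_table(write_hits(rows),
                      setNames(rep(305, 80), paste0("Q", 1:80)))
  base <- screen_hits(h)
  for (args in list(list(min_covered = 150), list(min_total = 95),
                    list(min_mapping_inter = 90),
                    list(min_mapping_intra = 95))) {
    tighter <- do.call(screen_hits, c(list(h), args))
    expect_true(all(tighter$sseqid %in% base$sseqid))
  }
})

curated_input <- function() {
  # hand-assembled screened hits exercising each curation branch
  df <- data.frame(
    qseqid = c("Q1", "Q2", "Q3", "Q4", "Q5", "Q6"),
    sseqid = c("S1", "S2", "S3", "S4", "S5", "S6"),
    pident = c(78, 91, 80, 95, 94.9, 91),
    covered_region = c(200, 120, 120, 300, 300, 130),
    query_length = rep(320, 6),
    subject_db = c("refseq", "refseq", "refseq", "bovine-set-1",
                   "bovine-set-1", "refseq"),
    screen_mode = c("interspecies", "interspecies", "interspecies",
                    "intraspecies", "intraspecies", "interspecies"),
    subject_upstream = c("GA", "GA", "GA", "GU", "GU", NA),
    subject_downstream = c("GB", "GB", "GB", "GD", "GX", NA),
    stringsAsFactors = FALSE)
  df$total_identity <- df$pident * df$covered_region / df$query_length
  df
}

query_ctx6 <- data.frame(entity_id = paste0("Q", 1:6),
                         upstream_gene = "GU,GA",
                         downstream_gene = "GD",
                         stringsAsFactors = FALSE)

test_that("curation accepts the main branch, the rescue, and intra >= 95", {
  cu <- curate_hits(curated_input(), query_ctx6)
  expect_setequal(cu$qseqid, c("Q1", "Q2", "Q4", "Q6"))
  # Q1: covered 200 >= 150 with 78 >= 75, shared flank GA -> syntenic
  expect_false(cu$rescued[cu$qseqid == "Q1"])
  expect_true(cu$syntenic[cu$qseqid == "Q1"])
  # Q2: 91 >= 90 over a shorter region -> rescue
  expect_true(cu$rescued[cu$qseqid == "Q2"])
  # Q3: 80 < 90 and covered < 150 -> fails both branches
  expect_false("Q3" %in% cu$qseqid)
  # Q4 intra passes the 95 cut but flanking sets differ -> not syntenic
  expect_false(cu$syntenic[cu$qseqid == "Q4"])
  # Q5 intra at 94.9 misses the 95 sequence cut
  expect_false("Q5" %in% cu$qseqid)
  # Q6: rescue branch, but no subject context -> synteny verdict NA
  expect_true(is.na(cu$syntenic[cu$qseqid == "Q6"]))
})

test_that("intraspecies curation needs 95% identity and identical loci", {
  df <- curated_input()
  # identical adjacent loci pass
  df2 <- df[df$qseqid == "Q4", ]
  qc <- data.frame(entity_id = "Q4", upstream_gene = "GU",
                   downstream_gene = "GD")
  df2$subject_upstream <- "GU"; df2$subject_downstream <- "GD"
  cu2 <- curate_hits(df2, qc)
  expect_true(cu2$syntenic)
})

test_that("curation is monotone and nested within screening", {
  sim <- fixture_sim_decoys()
  run <- fixture_run_decoys()
  qlens <- setNames(run$transcripts$length, run$transcripts$transcript_id)
  p <- tempfile()
  write.table(sim$hits$inter, p, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  h <- read_hit_table(p, qlens, context = sim$hits$context)
  h <- h[h$qseqid %in% names(qlens), ]
  s <- screen_hits(h)
  qctx <- locus_context(
    GenomicRanges::GRanges(run$transcripts$chrom,
      IRanges::IRanges(run$transcripts$start, run$transcripts$end),
      transcript_id = run$transcripts$transcript_id),
    annotation_index(sim$reference))
  cu <- curate_hits(s, qctx)
  key <- function(d) paste(d$qseqid, d$sseqid)
  expect_true(all(key(s) %in% key(h)))
  expect_true(all(key(cu) %in% key(s)))
  cu_tight <- curate_hits(s, qctx, min_covered_curation = 300,
                          min_identity_inter = 90, min_identity_intra = 99)
  expect_true(all(key(cu_tight) %in% key(cu)))
})

test_that("category assignment follows the decision order", {
  base <- data.frame(
    qseqid = "Q", sseqid = "S", pident = 95, covered_region = 300,
    total_identity = 91, subject_db = "lncipedia",
    subject_locus_kind = "noncoding_gene", syntenic = TRUE,
    stringsAsFactors = FALSE)
  qc <- data.frame(entity_id = "Q", upstream_gene = "GU",
                   downstream_gene = "GD")
  expect_equal(assign_homology_category("Q", base, qc, 5000), "lncRNA_conserved")
  h <- base; h$subject_db <- "refseq"; h$subject_locus_kind <- "coding_gene"
  expect_equal(assign_homology_category("Q", h, qc, 800), "utr_of_known_gene")
  h$subject_gene <- "GU"
  expect_equal(assign_homology_category("Q", h, qc, 5000), "amended_gene")
  h$subject_gene <- "ELSEWHERE"
  expect_equal(assign_homology_category("Q", h, qc, 5000),
               "potential_novel_gene")
  h$syntenic <- FALSE
  expect_equal(assign_homology_category("Q", h, qc, 5000),
               "potential_pseudogene")
  h$subject_locus_kind <- "pseudogene"
  expect_equal(assign_homology_category("Q", h, qc, 5000), "pseudogene")
  # no curated hits: bovine-specific candidate
  expect_equal(assign_homology_category("Q", base[0, ], qc, 5000), "none")
  # non-syntenic noncoding subject is not conserved evidence
  h2 <- base; h2$syntenic <- FALSE
  expect_equal(assign_homology_category("Q", h2, qc, 5000), "none")
})

test_that("the best hit decides when curated hits disagree", {
  qc <- data.frame(entity_id = "Q", upstream_gene = "GU",
                   downstream_gene = "GD")
  two <- data.frame(
    qseqid = "Q", sseqid = c("A_lnc", "B_cod"),
    pident = c(95, 96), covered_region = c(300, 310),
    total_identity = c(90, 93),
    subject_db = c("lncipedia", "refseq"),
    subject_locus_kind = c("noncoding_gene", "coding_gene"),
    syntenic = c(TRUE, FALSE), stringsAsFactors = FALSE)
  # B_cod has the higher total identity -> pseudogene inference wins
  expect_equal(assign_homology_category("Q", two, qc, 5000),
               "potential_pseudogene")
  two$total_identity <- c(93, 90)
  expect_equal(assign_homology_category("Q", two, qc, 5000),
               "lncRNA_conserved")
})
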