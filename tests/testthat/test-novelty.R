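ref_idx <- function() annotation_index(toy_reference())

one_tx <- function(starts, ends, strand = "+", id = "Q") {
  transcript_set(data.frame(chrom = "chr1", start = starts, end = ends,
                            strand = strand, transcript_id = id))
}

test_that("class codes capture the five structural relationships", {
  idx <- ref_idx()
  # identical intron chain (coordinates of T1, shifted ends only)
  eq <- one_tx(c(950, 2001, 3001), c(1200, 2300, 3500))
  expect_equal(unname(assign_class_codes(eq, idx)["Q"]), "=")
  # 10 kb from any locus
  far <- one_tx(20000, 20500)
  expect_equal(unname(assign_class_codes(far, idx)["Q"]), "u")
  # wholly inside intron 1 of T1
  intr <- one_tx(1300, 1600)
  expect_equal(unname(assign_class_codes(intr, idx)["Q"]), "i")
  # exonic overlap, same strand, different chain
  iso <- one_tx(c(1100, 1500), c(1200, 1600))
  expect_equal(unname(assign_class_codes(iso, idx)["Q"]), "j")
  # exonic overlap on the opposite strand only
  opp <- one_tx(1100, 1250, strand = "-")
  expect_equal(unname(assign_class_codes(opp, idx)["Q"]), "o")
})

test_that("single-exon exact match needs reciprocal overlap", {
  idx <- ref_idx()
  # T3 on chr2 is 501..900 (width 400); 300/400 reciprocal overlap passes
  hit <- transcript_set(data.frame(chrom = "chr2", start = 550, end = 950,
                                   strand = "+", transcript_id = "Q"))
  expect_equal(unname(assign_class_codes(hit, idx)["Q"]), "=")
  # 100/400 reciprocal overlap fails the 0.5 cut -> j
  weak <- transcript_set(data.frame(chrom = "chr2", start = 801, end = 1200,
                                    strand = "+", transcript_id = "Q"))
  expect_equal(unname(assign_class_codes(weak, idx)["Q"]), "j")
  # raising the fraction parameter demotes the passing hit too
  expect_equal(unname(assign_class_codes(hit, idx,
                                         single_exon_frac = 0.95)["Q"]), "j")
})

test_that("class codes match the pairwise oracle on random structures", {
  set.seed(202)
  idx <- ref_idx()
  refs <- list(
    list(exons = data.frame(start = c(1001, 2001, 3001),
                            end = c(1200, 2300, 3400)), strand = "+"),
    list(exons = data.frame(start = c(8001, 9501), end = c(8400, 9900)),
         strand = "-"))
  n_match <- 0
  for (i in 1:200) {
    n_ex <- sample(1:3, 1)
    starts <- sort(sample(seq(500, 11000, by = 37), n_ex))
    widths <- sample(50:400, n_ex, replace = TRUE)
    ends <- starts + widths - 1
    if (n_ex > 1 && any(starts[-1] <= ends[-n_ex])) next
    strand <- sample(c("+", "-", "*"), 1)
    if (strand == "*" && n_ex > 1) strand <- "+"
    q <- transcript_set(data.frame(chrom = "chr1", start = starts, end = ends,
                                   strand = strand, transcript_id = "Q"))
    got <- unname(assign_class_codes(q, idx)["Q"])
    want <- oracle_class_code(data.frame(start = starts, end = ends),
                              strand, refs)
    expect_equal(got, want,
                 label = sprintf("starts=%s strand=%s",
                                 paste(starts, collapse = ","), strand))
    n_match <- n_match + 1
  }
  expect_gt(n_match, 100)
})

test_that("every planted transcript gets its designed class code", {
  sim <- fixture_sim()
  codes <- assign_class_codes(sim$assembly, annotation_index(sim$reference))
  expect_length(codes, nrow(sim$truth))  # partition: one code each
  m <- match(names(codes), sim$truth$transcript_id)
  expect_equal(unname(codes), sim$truth$expected_class_code[m])
})

test_that("expression filter drops zero-CI transcripts only", {
  expr <- data.frame(transcript_id = c("A", "B", "C"),
                     fpkm_pig = c(1, 2, 0.1), ci_low_pig = c(0, 0.3, 0),
                     ci_high_pig = c(2, 3, 0.5),
                     fpkm_nonpig = c(1, 0.5, 0.2), ci_low_nonpig = c(0, 0, 0),
                     ci_high_nonpig = c(2, 1, 0.6))
  out <- filter_low_expression(c("A", "B", "C"), expr)
  expect_equal(out$retained, "B")   # positive in one condition suffices
  expect_equal(out$removed, c("A", "C"))
  expect_equal(filter_low_expression(character(), expr)$retained, character())
  expect_error(filter_low_expression("Z", expr), "Z")
})

test_that("expression filter is monotone in its threshold", {
  sim <- fixture_sim()
  ids <- tx_ids(sim$assembly)
  prev <- filter_low_expression(ids, sim$expression, threshold = 0)$retained
  for (th in c(0.5, 1, 2, 5)) {
    cur <- filter_low_expression(ids, sim$expression, threshold = th)$retained
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("predicted-locus subtraction removes exon overlaps, conserves counts", {
  pred <- transcript_set(data.frame(chrom = "chr1", start = 5000, end = 5600,
                                    strand = "+", transcript_id = "P1"),
                         source = "predicted")
  pidx <- annotation_index(pred)
  overlapping <- one_tx(5551, 5800)       # 50 bp exonic overlap
  away <- one_tx(7601, 7800)              # 2 kb away
  both <- suppressWarnings(c(overlapping, away))
  both$transcript_id <- c("OV", "AW")
  out <- subtract_predicted(both, pidx)
  expect_equal(out$removed, "OV")
  expect_equal(out$retained, "AW")
  expect_setequal(c(out$retained, out$removed), tx_ids(both))
})
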