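# Shared synthetic fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fix$sim))
    .fix$sim <- simulate_dataset(simulation_config(seed = 42))
  .fix$sim
}

fixture_sim_decoys <- function() {
  if (is.null(.fix$simd))
    .fix$simd <- simulate_dataset(simulation_config(seed = 42, decoys = TRUE))
  .fix$simd
}

run_pipeline <- function(sim) {
  classify_transcripts(
    assembly = sim$assembly, reference = sim$reference,
    predicted = sim$predicted, genome = sim$genome,
    expression = sim$expression,
    hits_inter = sim$hits$inter, hits_intra = sim$hits$intra,
    subject_context = sim$hits$context,
    train_coding = sim$corpora$coding,
    train_noncoding = sim$corpora$noncoding)
}

fixture_run <- function() {
  if (is.null(.fix$run)) .fix$run <- run_pipeline(fixture_sim())
  .fix$run
}

fixture_run_decoys <- function() {
  if (is.null(.fix$rund)) .fix$rund <- run_pipeline(fixture_sim_decoys())
  .fix$rund
}

# small hand-built annotation: two genes on chr1 (one 3-exon + strand, one
# 2-exon - strand), one gene on chr2
toy_reference <- function() {
  transcript_set(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(1001, 2001, 3001, 8001, 9501, 501),
    end = c(1200, 2300, 3400, 8400, 9900, 900),
    strand = c("+", "+", "+", "-", "-", "+"),
    transcript_id = c("T1", "T1", "T1", "T2", "T2", "T3"),
    gene_id = c("G1", "G1", "G1", "G2", "G2", "G3")),
    source = "reference")
}

toy_expression <- function(ids, ci_low = 1) {
  n <- length(ids)
  data.frame(transcript_id = ids,
             fpkm_pig = rep(5, n), ci_low_pig = rep(ci_low, n),
             ci_high_pig = rep(9, n),
             fpkm_nonpig = rep(4, n), ci_low_nonpig = rep(ci_low, n),
             ci_high_nonpig = rep(8, n))
}
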