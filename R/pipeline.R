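#' Run the full unknown-transcript classification pipeline
#'
#' Stages, in order: expression-CI filter, class-code assignment against the
#' reference, restriction to class `u`, subtraction of transcripts matching
#' predicted loci, coding-potential assessment with two scorers, similarity
#' screening/curation with synteny, nearest-neighbour annotation, and
#' evidence integration into the final category.
#'
#' Inputs may be in-memory objects or file paths (GTF for transcript sets,
#' FASTA for the genome, TSV for expression and hit tables).
#'
#' @param assembly merged transcript assembly (transcript set or GTF path).
#' @param reference reference annotation (transcript set or GTF path).
#' @param predicted predicted-gene annotation (transcript set, GTF path, or
#'   `NULL` to skip subtraction).
#' @param genome genome sequence (`DNAStringSet`, named character vector, or
#'   FASTA path).
#' @param expression expression table (data.frame or TSV path).
#' @param hits_inter,hits_intra similarity hit tables (data.frame without
#'   derived columns, path, or `NULL`).
#' @param subject_context subject context table (data.frame or path).
#' @param cpat_scorer trained [train_coding_model()] scorer; alternatively
#'   give `train_coding`/`train_noncoding` corpora to train one here.
#' @param cpc_scorer trained [train_cpc_proxy()]; trained from the corpora
#'   when `NULL` and no `cpc_scores` given.
#' @param cpc_scores optional named numeric vector (or 2-column data.frame)
#'   of externally computed CPC scores.
#' @param train_coding,train_noncoding training corpora (character,
#'   `DNAStringSet`, or FASTA paths).
#' @param thresholds a [coding_thresholds()].
#' @param lnc_min_len,utr_dist lncRNA length cut and UTR window.
#' @param single_exon_frac single-exon `=`-call reciprocal overlap.
#' @param screen_args,curate_args named lists of extra arguments for
#'   [screen_hits()] / [curate_hits()].
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @param verbose print stage progress.
#' @return object of class `ut_classification`: list with `transcripts`
#'   (one row per UT with the full evidence trail), `class_codes` (all
#'   assembled transcripts), `removed` (per-stage id lists), `manifest`
#'   (stage counts + thresholds), `summaries` ([summarize_classification()]
#'   output), and the `expression` table.
#' @export
classify_transcripts <- function(assembly, reference, predicted = NULL,
                                 genome, expression,
                                 hits_inter = NULL, hits_intra = NULL,
                                 subject_context = NULL,
                                 cpat_scorer = NULL, cpc_scorer = NULL,
                                 cpc_scores = NULL,
                                 train_coding = NULL, train_noncoding = NULL,
                                 thresholds = coding_thresholds(),
                                 lnc_min_len = 200, utr_dist = 1000,
                                 single_exon_frac = 0.5,
                                 screen_args = list(), curate_args = list(),
                                 seed = 1, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  load_gtf <- function(x, label) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L) read_gtf(x, label) else x
  }
  assembly <- load_gtf(assembly, "assembly")
  reference <- load_gtf(reference, "reference")
  predicted <- load_gtf(predicted, "predicted")
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(subject_context))
    subject_context <- read_context_table(subject_context)
  ref_index <- annotation_index(reference)
  pred_index <- if (!is.null(predicted) && length(predicted))
    annotation_index(predicted) else NULL

  n_input <- length(tx_ids(assembly))
  say("expression filter on ", n_input, " transcripts")
  expr_split <- filter_low_expression(assembly, expression)
  expressed <- assembly[assembly$transcript_id %in% expr_split$retained]

  say("class codes vs reference")
  codes <- assign_class_codes(expressed, ref_index,
                              single_exon_frac = single_exon_frac)
  u_ids <- names(codes)[codes == "u"]
  u_set <- expressed[expressed$transcript_id %in% u_ids]

  if (!is.null(pred_index)) {
    sub <- subtract_predicted(u_set, pred_index)
  } else {
    sub <- list(retained = u_ids, removed = character())
  }
  uts <- u_set[u_set$transcript_id %in% sub$retained]
  ut_ids <- tx_ids(uts)
  say(length(ut_ids), " unknown transcripts after subtraction")

  # coding potential
  load_fasta <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      dss <- Biostrings::readDNAStringSet(x)
      setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
    } else as.character(x)
  }
  if (is.null(cpat_scorer)) {
    if (is.null(train_coding) || is.null(train_noncoding))
      stop("need a cpat_scorer or training corpora")
    tc <- load_fasta(train_coding); tn <- load_fasta(train_noncoding)
    say("training coding scorers on ", length(tc), "+", length(tn),
        " sequences")
    cpat_scorer <- train_coding_model(tc, tn, seed = seed)
    if (is.null(cpc_scorer) && is.null(cpc_scores))
      cpc_scorer <- train_cpc_proxy(tc, tn, seed = seed + 1)
  }
  if (is.data.frame(cpc_scores))
    cpc_scores <- setNames(cpc_scores[[2]], cpc_scores[[1]])

  seqs <- spliced_sequence(uts, genome)
  strand_unknown <- attr(seqs, "strand_unknown")
  strands <- ifelse(strand_unknown[ut_ids], "both", "sense")
  say("scoring coding potential")
  coding <- assess_coding(setNames(as.character(seqs), names(seqs)),
                          cpat_scorer, cpc_scorer = cpc_scorer,
                          cpc_scores = cpc_scores, thresholds = thresholds,
                          strands = strands)

  # positional context
  say("nearest neighbours and locus context")
  nn <- nearest_neighbour(uts, ref_index)
  qctx <- locus_context(uts, ref_index)

  # homology
  qlens <- spliced_lengths(uts)
  read_hits <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L)
      return(read_hit_table(x, qlens, context = subject_context))
    # in-memory raw hit frame: attach derived columns the same way
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp), add = TRUE)
    utils::write.table(x, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    read_hit_table(tmp, qlens, context = subject_context)
  }
  hits <- rbind(read_hits(hits_inter), read_hits(hits_intra))
  curated <- NULL
  if (!is.null(hits) && nrow(hits)) {
    hits <- hits[hits$qseqid %in% ut_ids, , drop = FALSE]
    screened <- do.call(screen_hits, c(list(hits), screen_args))
    curated <- do.call(curate_hits, c(list(screened, qctx), curate_args))
    say(nrow(hits), " hits, ", nrow(screened), " screened, ",
        nrow(curated), " curated")
  }
  hom_cat <- setNames(rep("none", length(ut_ids)), ut_ids)
  if (!is.null(curated) && nrow(curated)) {
    nn_dist <- setNames(nn$distance_nt, nn$transcript_id)
    for (id in unique(curated$qseqid))
      hom_cat[id] <- assign_homology_category(
        id, curated, qctx, neighbour_distance = nn_dist[[id]],
        utr_dist = utr_dist)
  }

  # integration
  m_nn <- match(ut_ids, nn$transcript_id)
  m_cd <- match(ut_ids, coding$transcript_id)
  flags <- call_lnc(coding$length[m_cd], coding$consensus[m_cd],
                    nn$distance_nt[m_nn], min_len = lnc_min_len,
                    utr_dist = utr_dist)
  integ <- integrate_evidence(coding$consensus[m_cd], hom_cat[ut_ids], flags)

  spans <- tx_spans(uts)
  m_sp <- match(ut_ids, spans$transcript_id)
  n_ex <- table(uts$transcript_id)
  m_ex <- match(ut_ids, expression$transcript_id)
  res <- data.frame(
    transcript_id = ut_ids,
    chrom = as.character(GenomicRanges::seqnames(spans))[m_sp],
    start = GenomicRanges::start(spans)[m_sp],
    end = GenomicRanges::end(spans)[m_sp],
    strand = as.character(GenomicRanges::strand(spans))[m_sp],
    n_exons = as.integer(n_ex[ut_ids]),
    length = coding$length[m_cd],
    strand_unknown = strand_unknown[ut_ids],
    fpkm_pig = expression$fpkm_pig[m_ex],
    fpkm_nonpig = expression$fpkm_nonpig[m_ex],
    orf_length = coding$orf_length[m_cd],
    orf_coverage = coding$orf_coverage[m_cd],
    fickett = coding$fickett[m_cd],
    hexamer = coding$hexamer[m_cd],
    cpc_s = coding$cpc_s[m_cd],
    cpat_p = coding$cpat_p[m_cd],
    cat_cpc = coding$cat_cpc[m_cd],
    cat_cpat = coding$cat_cpat[m_cd],
    consensus = coding$consensus[m_cd],
    homology_category = unname(hom_cat[ut_ids]),
    nearest_locus_id = nn$nearest_locus_id[m_nn],
    distance_nt = nn$distance_nt[m_nn],
    is_lncRNA = flags$is_lncRNA,
    is_utr_associated = flags$is_utr_associated,
    is_lincRNA = flags$is_lincRNA,
    final_category = integ$final,
    evidence = integ$evidence,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL

  manifest <- list(
    seed = seed,
    thresholds = unclass(thresholds),
    lnc_min_len = lnc_min_len, utr_dist = utr_dist,
    n_input = n_input,
    n_low_expression = length(expr_split$removed),
    n_expressed = length(expr_split$retained),
    class_code_counts = as.list(table(codes)),
    n_class_u = length(u_ids),
    n_predicted_removed = length(sub$removed),
    n_ut = length(ut_ids),
    consensus_counts = as.list(table(res$consensus)),
    homology_counts = as.list(table(res$homology_category)),
    final_counts = as.list(table(res$final_category)))

  structure(list(transcripts = res, class_codes = codes,
                 removed = list(low_expression = expr_split$removed,
                                predicted_match = sub$removed),
                 curated_hits = curated, manifest = manifest,
                 expression = expression,
                 summaries = summarize_classification(res, expression)),
            class = "ut_classification")
}

#' @export
print.ut_classification <- function(x, ...) {
  m <- x$manifest
  cat("Unknown-transcript classification\n")
  cat(sprintf("  assembled transcripts: %d\n", m$n_input))
  cat(sprintf("  expressed (CI > 0):    %d  (removed %d)\n",
              m$n_expressed, m$n_low_expression))
  cat(sprintf("  class code u:          %d\n", m$n_class_u))
  cat(sprintf("  matching predicted:    %d\n", m$n_predicted_removed))
  cat(sprintf("  unknown transcripts:   %d\n", m$n_ut))
  cat("  final categories:\n")
  fc <- sort(unlist(m$final_counts), decreasing = TRUE)
  for (nm in names(fc)) cat(sprintf("    %-24s %d\n", nm, fc[[nm]]))
  invisible(x)
}

#' @export
summary.ut_classification <- function(object, ...) {
  print(object)
  acc <- tabulate_accounting(object)
  cat("\nCoding-potential accounting:\n")
  print(acc$table, row.names = FALSE)
  cat(sprintf("\n  concordant: %d (%.1f%%), inconsistent: %d (%.1f%%)\n",
              acc$concordant, acc$concordant_pct,
              acc$inconsistent, acc$inconsistent_pct))
  invisible(acc)
}

#' Table-style accounting of coding-potential and similarity categories
#'
#' For a pipeline result: per-tool coding/noncoding/ambiguous counts, the
#' intersection row (plus its inconsistent cell), the homology category
#' counts, and the derived identities (unknown-transcript total, concordant
#' count and percentage, conserved percentage).  All marginals sum to the
#' number of unknown transcripts.
#'
#' The numeric method computes the same identities from externally supplied
#' counts (e.g. a published intersection row), so printed tables can be
#' checked without rerunning a pipeline.
#'
#' @param x a `ut_classification`, or a named numeric vector with elements
#'   `coding`, `noncoding`, `ambiguous`, `inconsistent` (the intersection
#'   row).
#' @param ... further arguments; for the numeric method: `conserved` (number
#'   of transcripts with curated interspecies similarity), `lnc_similar` and
#'   `lnc_similar_conserved` (intergenic-similarity transcripts and the
#'   subset conserved in lncRNA databases), `lnc_total` and `lnc_intergenic`
#'   (putative lncRNAs and the subset beyond the UTR window).
#' @return list with `table` (per-tool and intersection rows), `ut_total`,
#'   `concordant`, `concordant_pct`, `inconsistent`, `inconsistent_pct`, and
#'   when computable `conserved_pct`, `conserved_lncRNA_pct`,
#'   `lincRNA_retained_pct`.
#' @export
tabulate_accounting <- function(x, ...) UseMethod("tabulate_accounting")

#' @export
tabulate_accounting.ut_classification <- function(x, ...) {
  tr <- x$transcripts
  cats <- c("coding", "noncoding", "ambiguous")
  row_of <- function(v) vapply(cats, function(k) sum(v == k), numeric(1))
  cpc <- row_of(tr$cat_cpc); cpat <- row_of(tr$cat_cpat)
  inter <- row_of(tr$consensus)
  inconsistent <- sum(tr$consensus == "inconsistent")
  tab <- data.frame(
    tool = c("cpc", "cpat", "intersection"),
    coding = c(cpc[1], cpat[1], inter[1]),
    noncoding = c(cpc[2], cpat[2], inter[2]),
    ambiguous = c(cpc[3], cpat[3], inter[3]),
    inconsistent = c(NA, NA, inconsistent))
  conserved <- sum(tr$homology_category != "none")
  lnc_n <- sum(tr$is_lncRNA)
  linc_n <- sum(tr$is_lincRNA)
  out <- .accounting_identities(inter[1], inter[2], inter[3], inconsistent,
                                conserved = conserved,
                                lnc_total = lnc_n, lnc_intergenic = linc_n)
  out$table <- tab
  out$homology_counts <- as.list(table(tr$homology_category))
  out
}

#' @export
tabulate_accounting.numeric <- function(x, conserved = NULL,
                                        lnc_similar = NULL,
                                        lnc_similar_conserved = NULL,
                                        lnc_total = NULL,
                                        lnc_intergenic = NULL, ...) {
  needed <- c("coding", "noncoding", "ambiguous", "inconsistent")
  miss <- setdiff(needed, names(x))
  if (length(miss)) stop("missing count(s): ", paste(miss, collapse = ", "))
  .accounting_identities(x[["coding"]], x[["noncoding"]], x[["ambiguous"]],
                         x[["inconsistent"]], conserved = conserved,
                         lnc_similar = lnc_similar,
                         lnc_similar_conserved = lnc_similar_conserved,
                         lnc_total = lnc_total,
                         lnc_intergenic = lnc_intergenic)
}

.accounting_identities <- function(coding, noncoding, ambiguous, inconsistent,
                                   conserved = NULL, lnc_similar = NULL,
                                   lnc_similar_conserved = NULL,
                                   lnc_total = NULL, lnc_intergenic = NULL) {
  coding <- unname(coding); noncoding <- unname(noncoding)
  ambiguous <- unname(ambiguous); inconsistent <- unname(inconsistent)
  concordant <- coding + noncoding + ambiguous
  ut_total <- concordant + inconsistent
  out <- list(ut_total = ut_total, concordant = concordant,
              concordant_pct = 100 * concordant / ut_total,
              inconsistent = inconsistent,
              inconsistent_pct = 100 * inconsistent / ut_total)
  if (!is.null(conserved))
    out$conserved_pct <- 100 * conserved / ut_total
  if (!is.null(lnc_similar) && !is.null(lnc_similar_conserved))
    out$conserved_lncRNA_pct <- 100 * lnc_similar_conserved / lnc_similar
  if (!is.null(lnc_total) && !is.null(lnc_intergenic))
    out$lincRNA_retained_pct <- 100 * lnc_intergenic / lnc_total
  out
}

#' Write classification outputs to a directory
#'
#' Emits `classification.tsv` (one row per unknown transcript, full evidence
#' columns), `classified.gtf` (UT exons with `final_category`, `cpc_s` and
#' `cpat_p` attributes), `class_codes.tsv`, and `summary_*.tsv` tables.
#'
#' @param x a `ut_classification`.
#' @param dir output directory (created if needed).
#' @param uts the UT transcript set used in the run (for GTF output);
#'   omitted when `NULL`.
#' @return invisibly the vector of files written.
#' @export
write_classification <- function(x, dir, uts = NULL) {
  stopifnot(inherits(x, "ut_classification"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  wt(x$transcripts, "classification.tsv")
  wt(data.frame(transcript_id = names(x$class_codes),
                class_code = unname(x$class_codes)), "class_codes.tsv")
  for (nm in names(x$summaries))
    wt(x$summaries[[nm]], paste0("summary_", nm, ".tsv"))
  if (!is.null(uts)) {
    p <- file.path(dir, "classified.gtf")
    write_gtf(uts, p, extra_attributes = x$transcripts[
      c("transcript_id", "final_category", "cpc_s", "cpat_p")])
    files <- c(files, p)
  }
  invisible(files)
}
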