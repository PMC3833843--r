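#' Assign cuffcompare-style class codes against a reference annotation
#'
#' Each assembled transcript receives exactly one of five codes describing its
#' structural relationship to the reference:
#'
#' * `=` exact match: identical intron chain on the same strand (single-exon
#'   transcripts: a single-exon reference transcript on the same strand with
#'   reciprocal overlap at least `single_exon_frac` of each);
#' * `j` shares exonic sequence with a reference transcript on a compatible
#'   strand (potential novel isoform);
#' * `o` exonic overlap only on the opposite strand;
#' * `i` no exonic overlap but fully contained inside an intron of a
#'   reference transcript (any strand);
#' * `u` unknown, intergenic: no exonic overlap on either strand and not
#'   intronic.
#'
#' Strand `*` (unknown) is compatible with either strand.  The full cufflinks
#' 12-code taxonomy is deliberately collapsed: downstream only `u` and the
#' known/novel-isoform aggregates are consumed.
#'
#' @param assembly assembled transcript set (`GRanges` of exons).
#' @param reference an [annotation_index()] over the reference annotation.
#' @param single_exon_frac reciprocal-overlap fraction for a single-exon `=`
#'   call (default 0.5).
#' @return named character vector, one code per assembly transcript.
#' @export
assign_class_codes <- function(assembly, reference, single_exon_frac = 0.5) {
  stopifnot(inherits(reference, "annotation_index"))
  ids <- tx_ids(assembly)
  codes <- setNames(rep("u", length(ids)), ids)
  if (!length(ids)) return(codes)

  a_spans <- tx_spans(assembly)
  a_exons <- tx_exons(assembly)
  r_set <- reference$transcripts
  r_exons_by_tx <- tx_exons(r_set)
  r_spans <- reference$tx_spans
  a_strand <- setNames(as.character(GenomicRanges::strand(a_spans)),
                       a_spans$transcript_id)
  r_strand <- setNames(as.character(GenomicRanges::strand(r_spans)),
                       r_spans$transcript_id)

  # candidate reference transcripts per assembly transcript, by span overlap
  cand_hits <- GenomicRanges::findOverlaps(a_spans, r_spans, ignore.strand = TRUE)
  cand <- split(r_spans$transcript_id[S4Vectors::subjectHits(cand_hits)],
                factor(a_spans$transcript_id[S4Vectors::queryHits(cand_hits)],
                       levels = a_spans$transcript_id))

  intron_chain <- function(ex) {
    # ex: GRanges sorted by start; returns "" for single-exon
    if (length(ex) < 2L) return("")
    s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
    paste(e[-length(e)] + 1L, s[-1] - 1L, sep = "-", collapse = ",")
  }
  a_chain <- vapply(ids, function(id) intron_chain(a_exons[[id]]), character(1))

  for (id in ids) {
    rc <- cand[[id]]
    if (is.null(rc) || !length(rc)) next  # stays "u"
    aex <- a_exons[[id]]
    ast <- a_strand[[id]]
    code <- NULL
    exonic_same <- FALSE; exonic_opp <- FALSE; intronic <- FALSE
    for (rid in rc) {
      rex <- r_exons_by_tx[[rid]]
      rst <- r_strand[[rid]]
      strand_ok <- ast == "*" || rst == "*" || ast == rst
      n_ov <- sum(IRanges::overlapsAny(IRanges::ranges(aex), IRanges::ranges(rex)))
      has_exonic <- n_ov > 0L
      if (has_exonic) {
        if (strand_ok) exonic_same <- TRUE else exonic_opp <- TRUE
      }
      # exact intron-chain match
      if (strand_ok) {
        if (length(aex) > 1L) {
          if (length(rex) > 1L && a_chain[[id]] == intron_chain(rex)) {
            code <- "="
            break
          }
        } else if (length(rex) == 1L && has_exonic) {
          ov <- IRanges::width(IRanges::pintersect(
            IRanges::ranges(aex), IRanges::ranges(rex)))
          if (ov >= single_exon_frac * IRanges::width(IRanges::ranges(aex)) &&
              ov >= single_exon_frac * IRanges::width(IRanges::ranges(rex))) {
            code <- "="
            break
          }
        }
      }
      if (!has_exonic && length(rex) > 1L) {
        # fully inside one intron of this reference transcript?
        rs <- GenomicRanges::start(rex); re <- GenomicRanges::end(rex)
        int_s <- re[-length(re)] + 1L; int_e <- rs[-1] - 1L
        a_lo <- min(GenomicRanges::start(aex)); a_hi <- max(GenomicRanges::end(aex))
        if (any(int_s <= a_lo & a_hi <= int_e)) intronic <- TRUE
      }
    }
    if (is.null(code)) {
      code <- if (exonic_same) "j"
              else if (exonic_opp) "o"
              else if (intronic) "i"
              else "u"
    }
    codes[[id]] <- code
  }
  codes
}

#' Remove transcripts whose FPKM confidence interval touches zero
#'
#' A transcript is retained iff the lower bound of the 95% confidence
#' interval on its FPKM is strictly above `threshold` (default 0) in at least
#' one condition, i.e. transcripts whose expression cannot be distinguished
#' from zero in both pigmented and nonpigmented skin are dropped.
#'
#' @param ids character vector of transcript ids (or a transcript set, from
#'   which ids are taken).
#' @param expression data.frame as from [read_expression()]; every id must
#'   have a record.
#' @param threshold CI lower-bound cut (default 0: "lower bound of zero").
#' @return list with `retained` and `removed` character vectors.
#' @export
filter_low_expression <- function(ids, expression, threshold = 0) {
  if (inherits(ids, "GRanges")) ids <- tx_ids(ids)
  m <- match(ids, expression$transcript_id)
  if (anyNA(m))
    stop("no expression record for transcript: ", ids[which(is.na(m))[1]])
  keep <- expression$ci_low_pig[m] > threshold |
          expression$ci_low_nonpig[m] > threshold
  list(retained = ids[keep], removed = ids[!keep])
}

#' Subtract transcripts matching ab initio predicted loci
#'
#' An unknown transcript is attributed to a predicted (GNOMON-style) locus,
#' and removed, iff at least one of its exons overlaps an exon of any
#' predicted-track transcript by at least 1 bp, irrespective of strand - the
#' most conservative reading of "corresponded to the predicted loci".
#'
#' @param uts transcript set of class-`u` transcripts.
#' @param predicted an [annotation_index()] over the predicted annotation.
#' @return list with `retained` and `removed` transcript-id vectors
#'   (`retained` + `removed` partition the input ids).
#' @export
subtract_predicted <- function(uts, predicted) {
  stopifnot(inherits(predicted, "annotation_index"))
  ids <- tx_ids(uts)
  hit <- IRanges::overlapsAny(uts, predicted$exons, ignore.strand = TRUE)
  removed <- unique(uts$transcript_id[hit])
  list(retained = setdiff(ids, removed), removed = removed)
}
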