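#' Nearest annotated locus for each transcript
#'
#' Distance is the gap between locus-span boundaries (gene-level, not
#' exon-level), strand-agnostic; 0 when the spans touch or overlap.  Ties
#' are broken toward the upstream (lower-coordinate) locus.  Transcripts on
#' a chromosome with no annotated locus get distance `Inf` and locus `NA`.
#'
#' @param uts transcript set (or `GRanges` of spans) to annotate.
#' @param reference an [annotation_index()].
#' @return data.frame: `transcript_id`, `nearest_locus_id`, `distance_nt`,
#'   `direction` (`upstream` = neighbour at lower coordinates, `downstream`
#'   = higher, `overlapping` when spans intersect).
#' @export
nearest_neighbour <- function(uts, reference) {
  stopifnot(inherits(reference, "annotation_index"))
  spans <- if ("transcript_id" %in% names(S4Vectors::mcols(uts)) &&
               anyDuplicated(uts$transcript_id)) tx_spans(uts) else uts
  loci <- reference$locus_spans
  n <- length(spans)
  out <- data.frame(transcript_id = spans$transcript_id,
                    nearest_locus_id = NA_character_,
                    distance_nt = Inf, direction = NA_character_,
                    stringsAsFactors = FALSE)
  if (!n || !length(loci)) return(out)
  q_chr <- as.character(GenomicRanges::seqnames(spans))
  l_chr <- as.character(GenomicRanges::seqnames(loci))
  for (i in seq_len(n)) {
    on_chr <- which(l_chr == q_chr[i])
    if (!length(on_chr)) next
    qs <- GenomicRanges::start(spans)[i]; qe <- GenomicRanges::end(spans)[i]
    ls <- GenomicRanges::start(loci)[on_chr]; le <- GenomicRanges::end(loci)[on_chr]
    gap <- pmax(ls - qe - 1L, qs - le - 1L, 0L)
    best <- min(gap)
    cand <- on_chr[gap == best]
    # tie toward the upstream locus (lower coordinates)
    cand <- cand[order(GenomicRanges::start(loci)[cand])]
    pick <- cand[1]
    out$nearest_locus_id[i] <- loci$gene_id[pick]
    out$distance_nt[i] <- best
    ps <- GenomicRanges::start(loci)[pick]; pe <- GenomicRanges::end(loci)[pick]
    out$direction[i] <- if (pe < qs) "upstream"
                        else if (ps > qe) "downstream"
                        else "overlapping"
  }
  out
}

#' Long-noncoding / lincRNA / UTR-association flags
#'
#' * `is_lncRNA`: consensus noncoding and spliced length strictly greater
#'   than `min_len` (200 nt by the standard definition);
#' * `is_utr_associated`: nearest-locus distance at most `utr_dist` (1 kb),
#'   regardless of coding status;
#' * `is_lincRNA`: lncRNA located strictly farther than `utr_dist` from any
#'   annotated locus (intergenic position).
#'
#' @param length spliced transcript length(s), nt.
#' @param consensus consensus coding category vector.
#' @param distance nearest-neighbour distance vector (nt, `Inf` allowed).
#' @param min_len lncRNA length cut (default 200, strict `>`).
#' @param utr_dist UTR-association window (default 1000).
#' @return data.frame with logical columns `is_lncRNA`, `is_utr_associated`,
#'   `is_lincRNA`.
#' @export
call_lnc <- function(length, consensus, distance, min_len = 200,
                     utr_dist = 1000) {
  is_lnc <- consensus == "noncoding" & length > min_len
  is_utr <- distance <= utr_dist
  data.frame(is_lncRNA = is_lnc,
             is_utr_associated = is_utr,
             is_lincRNA = is_lnc & distance > utr_dist)
}

#' Integrate coding, homology and positional evidence into a final category
#'
#' Precedence: a curated similarity-based category (`amended_gene`,
#' `utr_of_known_gene`, `potential_novel_gene`, `pseudogene`,
#' `potential_pseudogene`) overrides the coding-potential consensus -
#' mirroring the manual curation step that reassigned coding-predicted
#' transcripts to pseudogenes.  Otherwise the consensus decides: coding
#' becomes `novel_coding`; noncoding is subdivided by homology and position
#' into `lncRNA_conserved` (curated lncRNA similarity), `lincRNA_candidate`
#' (intergenic), `lncRNA_candidate` (UTR-associated or short-distance), or
#' `short_ncRNA_candidate` (at most `min_len` nt); `ambiguous` and
#' `inconsistent` pass through.
#'
#' @param consensus consensus coding category vector.
#' @param homology_cat homology category vector (from
#'   [assign_homology_category()]).
#' @param flags data.frame from [call_lnc()].
#' @return list with `final` (character vector) and `evidence` (character
#'   vector; semicolon-separated rule firings per transcript).
#' @export
integrate_evidence <- function(consensus, homology_cat, flags) {
  n <- length(consensus)
  stopifnot(length(homology_cat) == n, nrow(flags) == n)
  override <- c("amended_gene", "utr_of_known_gene", "potential_novel_gene",
                "pseudogene", "potential_pseudogene")
  final <- character(n)
  evidence <- character(n)
  for (i in seq_len(n)) {
    ev <- c(paste0("consensus=", consensus[i]),
            paste0("homology=", homology_cat[i]))
    if (homology_cat[i] %in% override) {
      final[i] <- homology_cat[i]
      ev <- c(ev, "rule=homology_override")
    } else if (consensus[i] == "coding") {
      final[i] <- "novel_coding"
      ev <- c(ev, "rule=consensus_coding")
    } else if (consensus[i] == "noncoding") {
      if (homology_cat[i] == "lncRNA_conserved") {
        final[i] <- "lncRNA_conserved"
        ev <- c(ev, "rule=conserved_lncRNA_similarity")
      } else if (!flags$is_lncRNA[i]) {
        final[i] <- "short_ncRNA_candidate"
        ev <- c(ev, "rule=noncoding_short")
      } else if (flags$is_lincRNA[i]) {
        final[i] <- "lincRNA_candidate"
        ev <- c(ev, "rule=lncRNA_intergenic")
      } else {
        final[i] <- "lncRNA_candidate"
        ev <- c(ev, "rule=lncRNA_near_gene")
      }
    } else {
      final[i] <- consensus[i]  # ambiguous / inconsistent pass through
      ev <- c(ev, "rule=consensus_passthrough")
    }
    if (isTRUE(flags$is_utr_associated[i])) ev <- c(ev, "flag=utr_associated")
    evidence[i] <- paste(ev, collapse = ";")
  }
  list(final = final, evidence = evidence)
}

#' Summary tabulations of a classified transcript set
#'
#' Produces the descriptive bookkeeping: transcript-length histogram,
#' per-chromosome transcript counts, per-chromosome mean FPKM per condition
#' (restricted to transcripts longer than `min_expr_len`, default 105 nt),
#' nearest-neighbour distance histogram (default 1-kb bins), and the
#' final-category count table (whose counts always sum to the input size).
#'
#' @param classified data.frame with at least `transcript_id`, `chrom`,
#'   `length`, `distance_nt`, `final_category`.
#' @param expression optional expression table ([read_expression()]).
#' @param length_breaks numeric breaks for the length histogram (default
#'   `c(0, 200, 500, 1000, 2000, 5000, Inf)`).
#' @param dist_binwidth distance histogram bin width, nt (default 1000).
#' @param min_expr_len length floor for the expression summary (default 105,
#'   strict `>`).
#' @return list of data.frames: `length_histogram`, `per_chromosome`,
#'   `expression_by_chromosome` (when expression given), `distance_histogram`,
#'   `category_counts`.
#' @export
summarize_classification <- function(classified, expression = NULL,
                                     length_breaks = c(0, 200, 500, 1000,
                                                       2000, 5000, Inf),
                                     dist_binwidth = 1000,
                                     min_expr_len = 105) {
  stopifnot(nrow(classified) > 0)
  lh <- table(cut(classified$length, breaks = length_breaks, right = FALSE))
  length_histogram <- data.frame(bin = names(lh), count = as.integer(lh))
  pc <- table(classified$chrom)
  per_chromosome <- data.frame(chrom = names(pc), count = as.integer(pc))
  expression_by_chromosome <- NULL
  if (!is.null(expression)) {
    m <- match(classified$transcript_id, expression$transcript_id)
    keep <- classified$length > min_expr_len & !is.na(m)
    if (any(keep)) {
      agg <- stats::aggregate(
        cbind(fpkm_pig = expression$fpkm_pig[m][keep],
              fpkm_nonpig = expression$fpkm_nonpig[m][keep]),
        by = list(chrom = classified$chrom[keep]), FUN = mean)
      expression_by_chromosome <- agg
    }
  }
  d <- classified$distance_nt[is.finite(classified$distance_nt)]
  if (length(d)) {
    bin <- floor(d / dist_binwidth)
    db <- table(bin)
    distance_histogram <- data.frame(
      from = as.integer(names(db)) * dist_binwidth,
      to = (as.integer(names(db)) + 1L) * dist_binwidth,
      count = as.integer(db))
  } else {
    distance_histogram <- data.frame(from = integer(), to = integer(),
                                     count = integer())
  }
  cc <- table(classified$final_category)
  category_counts <- data.frame(category = names(cc), count = as.integer(cc))
  out <- list(length_histogram = length_histogram,
              per_chromosome = per_chromosome,
              distance_histogram = distance_histogram,
              category_counts = category_counts)
  if (!is.null(expression_by_chromosome))
    out$expression_by_chromosome <- expression_by_chromosome
  out
}

#' Query-side locus context (flanking annotated genes)
#'
#' For each transcript: the nearest annotated gene upstream (lower
#' coordinates) and downstream (higher coordinates) on its chromosome, as
#' comma-separated symbol lists of up to `window` genes per side.
#'
#' @param uts transcript set or span `GRanges`.
#' @param reference an [annotation_index()].
#' @param window flanking genes per side (default 5).
#' @return data.frame: `entity_id`, `chrom`, `upstream_gene`,
#'   `downstream_gene` (`NA` when no gene on that side).
#' @export
locus_context <- function(uts, reference, window = 5L) {
  stopifnot(inherits(reference, "annotation_index"))
  spans <- if ("transcript_id" %in% names(S4Vectors::mcols(uts)) &&
               anyDuplicated(uts$transcript_id)) tx_spans(uts) else uts
  loci <- reference$locus_spans
  l_chr <- as.character(GenomicRanges::seqnames(loci))
  q_chr <- as.character(GenomicRanges::seqnames(spans))
  out <- data.frame(entity_id = spans$transcript_id, chrom = q_chr,
                    upstream_gene = NA_character_,
                    downstream_gene = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(spans)) {
    on_chr <- which(l_chr == q_chr[i])
    if (!length(on_chr)) next
    qs <- GenomicRanges::start(spans)[i]; qe <- GenomicRanges::end(spans)[i]
    le <- GenomicRanges::end(loci)[on_chr]; ls <- GenomicRanges::start(loci)[on_chr]
    up <- on_chr[le < qs]
    dn <- on_chr[ls > qe]
    if (length(up)) {
      up <- up[order(GenomicRanges::end(loci)[up], decreasing = TRUE)]
      out$upstream_gene[i] <- paste(loci$gene_id[utils::head(up, window)],
                                    collapse = ",")
    }
    if (length(dn)) {
      dn <- dn[order(GenomicRanges::start(loci)[dn])]
      out$downstream_gene[i] <- paste(loci$gene_id[utils::head(dn, window)],
                                      collapse = ",")
    }
  }
  out
}
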