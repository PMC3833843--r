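#' Build a transcript set from an exon table
#'
#' The central container of the package: a set of (possibly multi-exon)
#' transcripts held as a `GRanges` of exons, one row per exon, with metadata
#' columns `transcript_id`, `gene_id` and `source`.  Coordinates follow the
#' Bioconductor convention (1-based, closed intervals), which is also the GTF
#' convention, so no coordinate shifting happens anywhere in the package.
#'
#' Within one transcript all exons must share chromosome and strand, must not
#' overlap each other, and are stored sorted by start.  Strand `"*"` is
#' permitted for single-exon transcripts only (the cufflinks convention for
#' unstranded single-exon transfrags); such transcripts are treated as
#' strand-unknown downstream.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`, and optionally `gene_id`.  `strand` uses `+`, `-` or
#'   `*`/`.` (both accepted for unstranded).
#' @param source one of `"assembly"`, `"reference"`, `"predicted"`; recycled.
#' @return a `GRanges` of exons with the metadata columns above, sorted by
#'   transcript id then start ("transcript set" throughout the docs).
#' @export
transcript_set <- function(exons, source = "assembly") {
  stopifnot(is.data.frame(exons))
  needed <- c("chrom", "start", "end", "strand", "transcript_id")
  miss <- setdiff(needed, names(exons))
  if (length(miss)) stop("exon table lacks column(s): ", paste(miss, collapse = ", "))
  source <- match.arg(source, c("assembly", "reference", "predicted"))
  if (!nrow(exons)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      transcript_id = character(), gene_id = character(), source = character())
    return(gr)
  }
  strand <- as.character(exons$strand)
  strand[strand == "."] <- "*"
  if (!all(strand %in% c("+", "-", "*"))) stop("strand must be one of '+', '-', '.', '*'")
  if (any(exons$end < exons$start)) stop("exon with end < start")
  gene_id <- if ("gene_id" %in% names(exons)) as.character(exons$gene_id)
             else as.character(exons$transcript_id)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(exons$chrom),
    ranges = IRanges::IRanges(start = as.integer(exons$start), end = as.integer(exons$end)),
    strand = strand,
    transcript_id = as.character(exons$transcript_id),
    gene_id = gene_id,
    source = source)
  gr <- gr[order(gr$transcript_id, GenomicRanges::start(gr))]
  validate_transcripts(gr)
  gr
}

#' Validate the transcript-set invariants
#'
#' Checks one chromosome/strand per transcript, no intra-transcript exon
#' overlap, and that `"*"` strand only occurs on single-exon transcripts.
#' Called by [transcript_set()]; exported for use on externally built objects.
#'
#' @param gr a `GRanges` of exons with a `transcript_id` metadata column.
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_transcripts <- function(gr) {
  tid <- gr$transcript_id
  chr <- as.character(GenomicRanges::seqnames(gr))
  std <- as.character(GenomicRanges::strand(gr))
  by_tx <- split(seq_along(gr), tid)
  for (ids in by_tx) {
    if (length(unique(chr[ids])) > 1L)
      stop("transcript ", tid[ids[1]], ": exons on multiple chromosomes")
    if (length(unique(std[ids])) > 1L)
      stop("transcript ", tid[ids[1]], ": exons on mixed strands")
    if (std[ids[1]] == "*" && length(ids) > 1L)
      stop("transcript ", tid[ids[1]], ": unstranded multi-exon transcript")
    if (length(ids) > 1L) {
      s <- GenomicRanges::start(gr)[ids]; e <- GenomicRanges::end(gr)[ids]
      o <- order(s)
      if (any(s[o][-1] <= e[o][-length(o)]))
        stop("transcript ", tid[ids[1]], ": overlapping exons")
    }
  }
  invisible(TRUE)
}

#' Transcript identifiers of a transcript set
#' @param x a transcript set (`GRanges` from [transcript_set()]).
#' @return character vector of unique transcript ids, in storage order.
#' @export
tx_ids <- function(x) unique(x$transcript_id)

#' Spliced lengths of every transcript
#' @param x a `transcript_set`.
#' @return named integer vector, sum of exon widths per transcript.
#' @export
spliced_lengths <- function(x) {
  w <- tapply(GenomicRanges::width(x), x$transcript_id, sum)
  out <- as.integer(w); names(out) <- names(w)
  out[tx_ids(x)]
}

#' Genomic span of every transcript
#'
#' One range per transcript covering first exon start to last exon end.
#'
#' @param x a `transcript_set`.
#' @return a `GRanges`, one row per transcript, with `transcript_id` and
#'   `gene_id` metadata columns.
#' @export
tx_spans <- function(x) {
  grl <- S4Vectors::split(GenomicRanges::granges(x), x$transcript_id)
  sp <- unlist(range(grl))
  meta <- x[!duplicated(x$transcript_id)]
  sp <- sp[meta$transcript_id]
  sp$transcript_id <- meta$transcript_id
  sp$gene_id <- meta$gene_id
  names(sp) <- NULL
  sp
}

#' Per-transcript exon lists
#' @param x a `transcript_set`.
#' @return a `GRangesList` of exons split by transcript id.
#' @export
tx_exons <- function(x) S4Vectors::split(GenomicRanges::granges(x), x$transcript_id)

#' Interval index over an annotation
#'
#' Groups transcripts by locus (`gene_id`) and precomputes locus spans and
#' the exon set, so that overlap and distance queries run through
#' `findOverlaps` rather than linear scans.
#'
#' @param x a `transcript_set` (typically reference or predicted annotation).
#' @return an object of class `annotation_index` with elements
#'   `transcripts` (the input), `exons` (`GRanges`), `locus_spans` (`GRanges`
#'   one row per locus, metadata `gene_id`), `tx_spans`.
#' @export
annotation_index <- function(x) {
  stopifnot(inherits(x, "GRanges"))
  ex <- GenomicRanges::granges(x)
  S4Vectors::mcols(ex) <- S4Vectors::mcols(x)[c("transcript_id", "gene_id")]
  spans <- tx_spans(x)
  by_gene <- S4Vectors::split(GenomicRanges::granges(spans), spans$gene_id)
  loci <- unlist(range(by_gene))
  gid <- names(loci)
  loci <- GenomicRanges::granges(loci)
  loci$gene_id <- gid
  names(loci) <- NULL
  structure(list(transcripts = x, exons = ex, locus_spans = loci, tx_spans = spans),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("annotation_index: %d loci, %d transcripts, %d exons\n",
              length(x$locus_spans), length(x$tx_spans), length(x$exons)))
  invisible(x)
}

#' Loci whose span intersects a query interval
#'
#' @param index an [annotation_index()].
#' @param query a `GRanges` of query intervals (strand ignored).
#' @return list of character vectors, one per query, of intersecting
#'   `gene_id`s (possibly empty).
#' @export
query_loci <- function(index, query) {
  stopifnot(inherits(index, "annotation_index"))
  hits <- GenomicRanges::findOverlaps(query, index$locus_spans, ignore.strand = TRUE)
  out <- rep(list(character()), length(query))
  if (length(hits)) {
    sp <- split(index$locus_spans$gene_id[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_along(query)))
    out <- lapply(sp, unique)
  }
  out
}

#' Spliced transcript sequence from a genome
#'
#' Concatenates exon sequences 5' to 3' in transcript orientation: exons in
#' genomic order, then reverse-complemented for minus-strand transcripts.
#' Strand-unknown (`*`) transcripts return the plus-strand sequence and are
#' flagged via the `strand_unknown` attribute so callers can record it in the
#' evidence trail and scan both strands downstream.
#'
#' @param x a `transcript_set`.
#' @param genome a named `DNAStringSet` (or file path to a FASTA readable by
#'   `Biostrings::readDNAStringSet`).
#' @param ids optional character vector restricting which transcripts to
#'   extract (default: all).
#' @return named `DNAStringSet` of uppercase spliced sequences, with a
#'   logical attribute `strand_unknown` (named, per transcript).
#' @export
spliced_sequence <- function(x, genome, ids = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.null(ids)) ids <- tx_ids(x)
  keep <- x$transcript_id %in% ids
  sub <- x[keep]
  out <- character(length(ids)); names(out) <- ids
  unk <- logical(length(ids)); names(unk) <- ids
  chr <- as.character(GenomicRanges::seqnames(sub))
  std <- as.character(GenomicRanges::strand(sub))
  st <- GenomicRanges::start(sub); en <- GenomicRanges::end(sub)
  by_tx <- split(seq_along(sub), sub$transcript_id)
  for (id in ids) {
    ix <- by_tx[[id]]
    if (is.null(ix)) stop("transcript not in set: ", id)
    ch <- chr[ix[1]]
    if (!ch %in% names(genome)) stop("chromosome missing from genome: ", ch)
    clen <- length(genome[[ch]])
    if (any(en[ix] > clen) || any(st[ix] < 1L))
      stop("exon out of chromosome bounds for transcript ", id)
    ix <- ix[order(st[ix])]
    parts <- vapply(ix, function(i)
      as.character(Biostrings::subseq(genome[[ch]], st[i], en[i])), character(1))
    s <- toupper(paste(parts, collapse = ""))
    if (std[ix[1]] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    out[id] <- s
    unk[id] <- std[ix[1]] == "*"
  }
  res <- Biostrings::DNAStringSet(out)
  attr(res, "strand_unknown") <- unk
  res
}
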