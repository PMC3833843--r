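#' Read a GTF file into a transcript set
#'
#' Exon lines (or all lines when no `type` field distinguishes exons) are
#' grouped by the mandatory `transcript_id` attribute.  Parsing itself is
#' delegated to `rtracklayer::import`; a light pre-scan reports structural
#' problems (wrong column count, non-numeric coordinates, missing
#' transcript_id) with their line number, which `import` would not.
#'
#' @param path GTF file path (9 columns, 1-based inclusive coordinates).
#' @param source_label provenance tag stored on every exon: `"assembly"`,
#'   `"reference"` or `"predicted"`.
#' @return a transcript set (`GRanges` of exons, see [transcript_set()]).
#' @export
read_gtf <- function(path, source_label = "assembly") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated columns, got ",
           length(f))
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5]))))
      stop("malformed GTF line ", i, ": non-numeric coordinates")
    if (!grepl("transcript_id", f[9], fixed = TRUE))
      stop("malformed GTF line ", i, ": no transcript_id attribute")
  }
  if (!length(body)) {
    return(transcript_set(data.frame(chrom = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     transcript_id = character()),
                          source = source_label))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(as.character(gr$type) == "exon"))
    gr <- gr[as.character(gr$type) == "exon"]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = as.character(gr$transcript_id),
    stringsAsFactors = FALSE)
  if ("gene_id" %in% names(S4Vectors::mcols(gr)) && !all(is.na(gr$gene_id)))
    df$gene_id <- as.character(gr$gene_id)
  transcript_set(df, source = source_label)
}

#' Write a transcript set as GTF
#'
#' Emits one `exon` line per exon, 1-based inclusive coordinates, with
#' `gene_id` and `transcript_id` attributes.  Extra per-transcript attributes
#' (e.g. the final classification category and scores) are repeated on every
#' exon line of the transcript, the convention downstream genome browsers
#' expect.
#'
#' @param x a transcript set (`GRanges` of exons).
#' @param path output file path.
#' @param extra_attributes optional data.frame with a `transcript_id` column;
#'   all other columns become GTF attributes on the matching exon lines.
#' @return invisibly `path`.
#' @export
write_gtf <- function(x, path, extra_attributes = NULL) {
  gr <- GenomicRanges::granges(x)
  gr$source <- x$source
  gr$type <- "exon"
  gr$gene_id <- x$gene_id
  gr$transcript_id <- x$transcript_id
  if (!is.null(extra_attributes)) {
    stopifnot(is.data.frame(extra_attributes),
              "transcript_id" %in% names(extra_attributes))
    m <- match(x$transcript_id, extra_attributes$transcript_id)
    for (col in setdiff(names(extra_attributes), "transcript_id"))
      S4Vectors::mcols(gr)[[col]] <- extra_attributes[[col]][m]
  }
  tryCatch(rtracklayer::export(gr, path, format = "gtf"),
           error = function(e) stop("cannot write GTF to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a per-transcript expression table
#'
#' Tab-separated with header: `transcript_id`, then per condition
#' (`pig` = pigmented, `nonpig` = nonpigmented skin) the FPKM point estimate
#' and the bounds of its 95% confidence interval:
#' `fpkm_pig, ci_low_pig, ci_high_pig, fpkm_nonpig, ci_low_nonpig,
#' ci_high_nonpig`.
#'
#' @param path TSV file path.
#' @return data.frame with the seven columns above, validated
#'   (`0 <= ci_low <= fpkm <= ci_high` per condition).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("transcript_id", "fpkm_pig", "ci_low_pig", "ci_high_pig",
              "fpkm_nonpig", "ci_low_nonpig", "ci_high_nonpig")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("expression table lacks column(s): ",
                         paste(miss, collapse = ", "))
  for (cond in c("pig", "nonpig")) {
    lo <- df[[paste0("ci_low_", cond)]]
    fp <- df[[paste0("fpkm_", cond)]]
    hi <- df[[paste0("ci_high_", cond)]]
    bad <- which(lo < 0 | fp < lo | hi < fp)
    if (length(bad))
      stop("invalid expression record for ", df$transcript_id[bad[1]],
           " (need 0 <= ci_low <= fpkm <= ci_high)")
  }
  df[needed]
}

#' Write an expression table (inverse of [read_expression()])
#' @param expr data.frame as returned by [read_expression()].
#' @param path output TSV path.
#' @return invisibly `path`.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
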