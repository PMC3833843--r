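#' Scan a nucleotide sequence for open reading frames
#'
#' Two scanning modes:
#' * `atg_anchored`: maximal ORFs running from an ATG to the next in-frame
#'   stop (stop codon included in the span).  Only the first ATG after the
#'   previous stop starts an ORF (maximal spans, no nested sub-ORFs).  An ORF
#'   reaching the end of the sequence without a stop is reported with
#'   `has_stop = FALSE`.
#' * `stop_to_stop`: maximal stop-free codon runs per frame; `has_start` is
#'   `TRUE` when the run contains an in-frame ATG.
#'
#' With `strands = "both"` the reverse complement is scanned too (used for
#' strand-unknown single-exon transfrags); offsets then refer to the
#' reverse-complemented sequence and `strand` is `"antisense"`.
#'
#' @param sequence character scalar over A,C,G,T,N (case-insensitive).
#' @param mode `"atg_anchored"` (default) or `"stop_to_stop"`.
#' @param strands `"sense"` (default) or `"both"`.
#' @return data.frame with columns `frame` (0..2), `strand`, `start`, `end`
#'   (1-based, inclusive, on the scanned strand), `length_nt` (multiple of
#'   3), `has_start`, `has_stop`; sorted by length descending, ties by
#'   leftmost start, sense strand first.  Zero rows when nothing is found or
#'   the sequence is shorter than 3.
#' @export
find_orfs <- function(sequence, mode = c("atg_anchored", "stop_to_stop"),
                      strands = c("sense", "both")) {
  mode <- match.arg(mode)
  strands <- match.arg(strands)
  sequence <- toupper(as.character(sequence))
  empty <- data.frame(frame = integer(), strand = character(),
                      start = integer(), end = integer(),
                      length_nt = integer(), has_start = logical(),
                      has_stop = logical(), stringsAsFactors = FALSE)
  if (nchar(sequence) < 3L) return(empty)

  scan_one <- function(seq, strand_label) {
    n <- nchar(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    rows <- list()
    for (frame in 0:2) {
      starts <- seq.int(frame + 1L, n - 2L, by = 3L)
      if (!length(starts)) next
      codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      if (mode == "atg_anchored") {
        open_at <- NA_integer_
        for (k in seq_along(codons)) {
          if (is.na(open_at) && is_atg[k]) open_at <- k
          if (!is.na(open_at) && is_stop[k]) {
            rows[[length(rows) + 1L]] <- data.frame(
              frame = frame, strand = strand_label,
              start = starts[open_at], end = starts[k] + 2L,
              length_nt = (k - open_at + 1L) * 3L,
              has_start = TRUE, has_stop = TRUE, stringsAsFactors = FALSE)
            open_at <- NA_integer_
          }
        }
        if (!is.na(open_at)) {
          k <- length(codons)
          rows[[length(rows) + 1L]] <- data.frame(
            frame = frame, strand = strand_label,
            start = starts[open_at], end = starts[k] + 2L,
            length_nt = (k - open_at + 1L) * 3L,
            has_start = TRUE, has_stop = FALSE, stringsAsFactors = FALSE)
        }
      } else {
        run_from <- 1L
        bounds <- c(which(is_stop), length(codons) + 1L)
        for (b in bounds) {
          if (b > run_from) {
            ks <- run_from:(b - 1L)
            rows[[length(rows) + 1L]] <- data.frame(
              frame = frame, strand = strand_label,
              start = starts[run_from], end = starts[b - 1L] + 2L,
              length_nt = length(ks) * 3L,
              has_start = is_atg[run_from], has_stop = b <= length(codons),
              stringsAsFactors = FALSE)
          }
          run_from <- b + 1L
        }
      }
    }
    if (!length(rows)) return(empty)
    do.call(rbind, rows)
  }

  out <- scan_one(sequence, "sense")
  if (strands == "both") {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    out <- rbind(out, scan_one(rc, "antisense"))
  }
  if (!nrow(out)) return(empty)
  out <- out[order(-out$length_nt, out$start, out$strand != "sense"), ]
  rownames(out) <- NULL
  out
}

#' Longest ORF of a sequence
#'
#' Convenience wrapper over [find_orfs()] returning the single top-ranked
#' ORF (longest; ties by leftmost start, sense strand first), or a length-0
#' row set when none exists.
#'
#' @inheritParams find_orfs
#' @return one-row data.frame (or zero rows).
#' @export
longest_orf <- function(sequence, mode = "atg_anchored", strands = "sense") {
  orfs <- find_orfs(sequence, mode = mode, strands = strands)
  utils::head(orfs, 1L)
}
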