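.all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  apply(g, 1, paste, collapse = "")
}

.count_hexamers <- function(seqs, step) {
  counts <- setNames(numeric(4096), .all_hexamers())
  for (s in seqs) {
    s <- toupper(as.character(s))
    n <- nchar(s)
    if (n < 6L) next
    starts <- seq.int(1L, n - 5L, by = step)
    hx <- substring(s, starts, starts + 5L)
    hx <- hx[!grepl("[^ACGT]", hx)]
    if (length(hx)) {
      tab <- table(hx)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  counts
}

#' Train a hexamer usage model
#'
#' Tabulates hexamer frequencies in a coding corpus (counted in frame, step
#' 3, so the hexamers are dicodons) and a noncoding corpus (step 1), with a
#' pseudocount so every hexamer has positive frequency in both tables.  The
#' log-ratio table `log(f_coding / f_noncoding)` is the feature source for
#' [hexamer_llr()].
#'
#' @param coding_seqs character vector / `DNAStringSet` of coding sequences
#'   (ideally ORF regions, so frame 0 is the reading frame).
#' @param noncoding_seqs noncoding corpus.
#' @param pseudocount added to every hexamer count (default 1).
#' @return object of class `hexamer_model`: list with `log_ratio` (named
#'   numeric, 4096 entries) and the two frequency tables.
#' @export
hexamer_model <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  if (!length(coding_seqs) || !length(noncoding_seqs))
    stop("both corpora must be non-empty")
  cc <- .count_hexamers(as.character(coding_seqs), step = 3L) + pseudocount
  nc <- .count_hexamers(as.character(noncoding_seqs), step = 1L) + pseudocount
  f_cod <- cc / sum(cc)
  f_non <- nc / sum(nc)
  structure(list(log_ratio = log(f_cod / f_non),
                 f_coding = f_cod, f_noncoding = f_non,
                 pseudocount = pseudocount),
            class = "hexamer_model")
}

#' @export
print.hexamer_model <- function(x, ...) {
  cat(sprintf("hexamer_model: 4096 hexamers, log-ratio range [%.2f, %.2f]\n",
              min(x$log_ratio), max(x$log_ratio)))
  invisible(x)
}

#' Hexamer log-likelihood ratio of a sequence
#'
#' Mean of `log(f_coding/f_noncoding)` over the scored hexamers.  When
#' `orf_start` is given, hexamers are read in frame from that position (step
#' 3); otherwise every position is scored (step 1).  Hexamers containing
#' ambiguous bases are skipped; if no hexamer is scorable the result is 0.
#'
#' @param sequence character scalar.
#' @param model a [hexamer_model()].
#' @param orf_start optional 1-based start of the ORF within `sequence`.
#' @return numeric scalar.
#' @export
hexamer_llr <- function(sequence, model, orf_start = NULL) {
  if (!inherits(model, "hexamer_model")) stop("untrained or invalid hexamer model")
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (is.null(orf_start)) {
    from <- 1L; step <- 1L
  } else {
    from <- as.integer(orf_start); step <- 3L
  }
  if (n - from + 1L < 6L) return(0)
  starts <- seq.int(from, n - 5L, by = step)
  hx <- substring(s, starts, starts + 5L)
  hx <- hx[!grepl("[^ACGT]", hx)]
  if (!length(hx)) return(0)
  mean(model$log_ratio[hx])
}
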