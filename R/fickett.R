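# Fickett (1982) TESTCODE lookup tables.  For each base: the probability that
# a window with the given position/content parameter is coding, and the
# weight of that parameter in the combined score.  Intervals run from high
# parameter values to low (position: >=1.9, [1.8,1.9), ..., [1.1,1.2), <1.1;
# content: >=0.33 down to <0.17 in steps of 0.02).

.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_position_cuts <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)

.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
.fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
.fickett_content_cuts <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)

.fickett_lookup <- function(value, cuts, probs) {
  idx <- which(value >= cuts)[1]
  probs[idx]
}

#' Fickett TESTCODE score of a nucleotide sequence
#'
#' The classic alignment-free coding statistic: for each base, the position
#' parameter measures the asymmetry of that base's occurrence across the
#' three codon positions (max count / (min count + 1)) and the content
#' parameter is its overall fraction; each of the 8 parameters is converted
#' to a coding probability via the published lookup tables and combined as a
#' weighted sum.  Ranges roughly within [0.16, 1.9]; higher = more
#' coding-like.  `N`s are ignored.
#'
#' @param sequence character scalar over A,C,G,T,N; must be non-empty.
#' @return numeric scalar.
#' @export
fickett_score <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (!nchar(sequence)) stop("empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  keep <- chars %in% c("A", "C", "G", "T")
  total <- sum(keep)
  if (!total) stop("sequence contains no unambiguous bases")
  score <- 0
  # codon-position counts use the original positions (frame of the given
  # sequence), skipping ambiguous bases from the tallies
  pos_of <- ((seq_along(chars) - 1L) %% 3L) + 1L
  for (base in c("A", "C", "G", "T")) {
    sel <- keep & chars == base
    counts <- vapply(1:3, function(p) sum(sel & pos_of == p), numeric(1))
    position_value <- max(counts) / (min(counts) + 1)
    content_value <- sum(counts) / total
    score <- score +
      .fickett_lookup(position_value, .fickett_position_cuts,
                      .fickett_position_prob[[base]]) *
        .fickett_position_weight[[base]] +
      .fickett_lookup(content_value, .fickett_content_cuts,
                      .fickett_content_prob[[base]]) *
        .fickett_content_weight[[base]]
  }
  unname(score)
}
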