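# Independent brute-force oracles.  Each re-derives its quantity from the
# definition with plain vectors and loops, sharing no code with the package
# internals.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# --- Fickett TESTCODE, literal second transcription of the published tables
oracle_fickett <- function(s) {
  pos_tab <- rbind(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  con_tab <- rbind(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  con_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  ch <- strsplit(toupper(s), "")[[1]]
  codon_pos <- rep_len(1:3, length(ch))
  valid <- ch %in% c("A", "C", "G", "T")
  total <- 0
  comp <- list()
  for (b in c("A", "C", "G", "T")) {
    n1 <- sum(ch == b & codon_pos == 1 & valid)
    n2 <- sum(ch == b & codon_pos == 2 & valid)
    n3 <- sum(ch == b & codon_pos == 3 & valid)
    pv <- max(n1, n2, n3) / (min(n1, n2, n3) + 1)
    cv <- (n1 + n2 + n3) / sum(valid)
    # interval index via findInterval on descending cuts
    pi <- 11L - findInterval(pv, c(0, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7,
                                   1.8, 1.9))
    ci <- 11L - findInterval(cv, c(0, 0.17, 0.19, 0.21, 0.23, 0.25, 0.27,
                                   0.29, 0.31, 0.33))
    comp[[b]] <- c(position = pv, content = cv)
    total <- total + pos_tab[b, pi] * pos_w[b] + con_tab[b, ci] * con_w[b]
  }
  attr(total, "components") <- comp
  unname(total)
}

# --- exhaustive frame-scan ORF oracle: returns the single best ORF
oracle_longest_orf <- function(s, mode = "atg_anchored", strands = "sense") {
  s <- toupper(s)
  scan <- function(seq, lab) {
    found <- list()
    ch <- strsplit(seq, "")[[1]]
    for (f in 0:2) {
      idx <- seq(f + 1, nchar(seq) - 2, by = 3)
      if (f + 3 > nchar(seq)) next
      cods <- sapply(idx, function(i) paste(ch[i:(i + 2)], collapse = ""))
      stops <- which(cods %in% c("TAA", "TAG", "TGA"))
      seg_start <- 1
      segments <- list()
      for (st in c(stops, length(cods) + 1)) {
        segments[[length(segments) + 1]] <- c(seg_start, st)
        seg_start <- st + 1
      }
      for (sg in segments) {
        lo <- sg[1]; stop_at <- sg[2]
        if (lo > length(cods)) next
        if (mode == "atg_anchored") {
          atg <- which(cods[lo:min(stop_at - 1, length(cods))] == "ATG")
          if (!length(atg)) next
          a <- lo + atg[1] - 1
          last <- min(stop_at, length(cods))
          found[[length(found) + 1]] <- data.frame(
            start = idx[a], end = idx[last] + 2,
            length_nt = (last - a + 1) * 3, strand = lab,
            has_stop = stop_at <= length(cods))
        } else {
          if (stop_at - 1 < lo) next
          last <- stop_at - 1
          found[[length(found) + 1]] <- data.frame(
            start = idx[lo], end = idx[last] + 2,
            length_nt = (last - lo + 1) * 3, strand = lab,
            has_stop = stop_at <= length(cods))
        }
      }
    }
    found
  }
  all <- scan(s, "sense")
  if (strands == "both") all <- c(all, scan(oracle_revcomp(s), "antisense"))
  if (!length(all)) return(NULL)
  df <- do.call(rbind, all)
  df <- df[order(-df$length_nt, df$start, df$strand != "sense"), ]
  df[1, ]
}

# --- per-hexamer summation oracle
oracle_hexamer_llr <- function(s, log_ratio, orf_start = NULL) {
  s <- toupper(s)
  step <- if (is.null(orf_start)) 1 else 3
  from <- if (is.null(orf_start)) 1 else orf_start
  vals <- c()
  i <- from
  while (i + 5 <= nchar(s)) {
    h <- substr(s, i, i + 5)
    if (!grepl("[^ACGT]", h)) vals <- c(vals, log_ratio[[h]])
    i <- i + step
  }
  if (!length(vals)) return(0)
  sum(vals) / length(vals)
}

# --- pairwise class-code oracle over plain exon tables
# query: data.frame(start, end, strand scalar); refs: list of the same
oracle_class_code <- function(q_exons, q_strand, refs, single_exon_frac = 0.5) {
  ov_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)
  any_exon_overlap <- function(a, b) {
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      if (ov_len(a$start[i], a$end[i], b$start[j], b$end[j]) > 0) return(TRUE)
    FALSE
  }
  chain <- function(ex) {
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) return(NULL)
    cbind(ex$end[-nrow(ex)] + 1, ex$start[-1] - 1)
  }
  q_exons <- q_exons[order(q_exons$start), ]
  exonic_same <- FALSE; exonic_opp <- FALSE; intronic <- FALSE
  for (r in refs) {
    rex <- r$exons[order(r$exons$start), ]
    compat <- q_strand == "*" || r$strand == "*" || q_strand == r$strand
    has_ov <- any_exon_overlap(q_exons, rex)
    if (compat) {
      if (nrow(q_exons) > 1 && nrow(rex) > 1 &&
          identical(unname(chain(q_exons)), unname(chain(rex))))
        return("=")
      if (nrow(q_exons) == 1 && nrow(rex) == 1) {
        ov <- ov_len(q_exons$start, q_exons$end, rex$start, rex$end)
        wq <- q_exons$end - q_exons$start + 1
        wr <- rex$end - rex$start + 1
        if (ov >= single_exon_frac * wq && ov >= single_exon_frac * wr)
          return("=")
      }
    }
    if (has_ov) {
      if (compat) exonic_same <- TRUE else exonic_opp <- TRUE
    } else if (nrow(rex) > 1) {
      ch <- chain(rex)
      qlo <- min(q_exons$start); qhi <- max(q_exons$end)
      for (k in seq_len(nrow(ch)))
        if (ch[k, 1] <= qlo && qhi <= ch[k, 2]) intronic <- TRUE
    }
  }
  if (exonic_same) "j" else if (exonic_opp) "o" else if (intronic) "i" else "u"
}

# --- linear-scan nearest-locus oracle
oracle_nearest <- function(chrom, start, end, loci) {
  loci <- loci[loci$chrom == chrom, ]
  if (!nrow(loci)) return(list(dist = Inf, gene = NA, direction = NA))
  gap <- pmax(loci$start - end - 1, start - loci$end - 1, 0)
  best <- min(gap)
  cand <- loci[gap == best, ]
  cand <- cand[order(cand$start), ]
  direction <- if (cand$end[1] < start) "upstream"
               else if (cand$start[1] > end) "downstream" else "overlapping"
  list(dist = best, gene = cand$gene_id[1], direction = direction)
}

random_dna_str <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
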