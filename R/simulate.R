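#' Configuration for the synthetic transcriptome generator
#'
#' Defaults emulate the statistical structure the classifier assumes: mostly
#' single-exon unknown transcripts (0.91 single-exon fraction), lengths
#' spanning both sides of the 200-nt lncRNA cut, dedicated plants within the
#' 1-kb UTR window and far outside it, a conserved subset with near-full-
#' length high-identity similarity hits, and pseudogene copies placed with a
#' discordant adjacent-gene context.
#'
#' @param seed integer master seed; every generated byte derives from it.
#' @param n_chromosomes,chrom_length toy genome shape.
#' @param gc genomic GC fraction.
#' @param n_reference_genes,n_predicted_genes annotated / ab-initio loci.
#' @param plants named integer vector of planted transcript counts per
#'   category (`known_isoform`, `intronic`, `intergenic_noncoding`,
#'   `novel_coding`, `utr_extension`, `pseudogene_copy`, `conserved_lncRNA`,
#'   `short_ncRNA`, `predicted_match`, `low_expression`).
#' @param coding_bias codon/hexamer skew of coding plants in [0,1]; 1 =
#'   strongly biased (noiseless separability), 0 = uniform.
#' @param conservation_identity percent identity of planted interspecies
#'   hits.
#' @param decoys logical: also emit near-threshold decoy hits that straddle
#'   every screening/curation cut (they must all be rejected).
#' @param single_exon_fraction fraction of plants built as single-exon.
#' @param fpkm_meanlog,fpkm_sdlog log-normal FPKM parameters.
#' @param ci_low_frac,ci_high_frac CI bounds as fractions of the FPKM.
#' @param n_train training-corpus size per class for the coding scorers.
#' @return named list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_chromosomes = 3,
                              chrom_length = 400000, gc = 0.42,
                              n_reference_genes = 24, n_predicted_genes = 9,
                              plants = c(known_isoform = 15, intronic = 15,
                                         intergenic_noncoding = 40,
                                         novel_coding = 25,
                                         utr_extension = 20,
                                         pseudogene_copy = 15,
                                         conserved_lncRNA = 25,
                                         short_ncRNA = 20,
                                         predicted_match = 10,
                                         low_expression = 15),
                              coding_bias = 1, conservation_identity = 94,
                              decoys = FALSE, single_exon_fraction = 0.91,
                              fpkm_meanlog = 2, fpkm_sdlog = 1,
                              ci_low_frac = 0.4, ci_high_frac = 1.8,
                              n_train = 100) {
  stopifnot(chrom_length > 0, n_chromosomes >= 1, all(plants >= 0),
            gc > 0, gc < 1, coding_bias >= 0, coding_bias <= 1,
            single_exon_fraction >= 0, single_exon_fraction <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

.random_dna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(b, b, b)[, 3:1], 1, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# a fixed preferred-codon set gives coding plants a reproducible hexamer skew
.preferred_codons <- c("GCC", "GAG", "AAG", "CTG", "GAC", "TTC", "ATC", "AAC",
                       "CAG", "GTG", "TAC", "TGC", "CGC", "AGC", "ACC", "GGC")

.codon_weights <- function(bias) {
  codons <- .sense_codons()
  w <- rep(1, length(codons))
  w[codons %in% .preferred_codons] <- 1 + 9 * bias
  names(w) <- codons
  w
}

.coding_dna <- function(len, bias, gc = 0.42, min_orf = NULL,
                        max_tries = 50L) {
  # UTR / ATG-ORF-stop / UTR layout; ORF takes ~80% of the length.  Redrawn
  # until the planted ORF is also the longest one found, so that in-frame
  # feature extraction reads the designed codon stream, not a chance
  # out-of-frame open stretch.
  orf_codons <- max(4L, floor(0.8 * len / 3))
  if (!is.null(min_orf)) orf_codons <- max(orf_codons, ceiling(min_orf / 3))
  orf_len <- orf_codons * 3L
  if (orf_len > len - 6L) orf_len <- (len - 6L) %/% 3L * 3L
  codons <- .sense_codons()
  w <- .codon_weights(bias)
  for (i in seq_len(max_tries)) {
    body <- paste(sample(codons, orf_len / 3 - 2L, replace = TRUE, prob = w),
                  collapse = "")
    orf <- paste0("ATG", body, "TAA")
    rest <- len - nchar(orf)
    utr5 <- rest %/% 2
    s <- paste0(.random_dna(utr5, gc), orf, .random_dna(rest - utr5, gc))
    top <- longest_orf(s)
    if (nrow(top) && top$start == utr5 + 1L && top$length_nt == nchar(orf))
      return(s)
  }
  s
}

# noncoding plant sequence, composition-controlled: redraw until the
# sequence is free of coding-like signal (chance ORFs capped at half the
# length, Fickett TESTCODE below the coding-typical range), so that at the
# noiseless settings planted noncoding transcripts are unambiguously
# noncoding by composition
.noncoding_dna <- function(len, gc = 0.42, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    s <- .random_dna(len, gc)
    orf <- longest_orf(s, strands = "both")
    orf_len <- if (nrow(orf)) orf$length_nt else 0L
    if (orf_len <= max(45L, 0.5 * len) && fickett_score(s) <= 0.95)
      return(s)
  }
  s
}

#' Generate the toy genome
#'
#' I.i.d. background sequence per chromosome at the configured GC, fully
#' determined by the seed.
#'
#' @param config a [simulation_config()].
#' @return named character vector of chromosome sequences (chr1..chrN).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$chrom_length <= 0) stop("zero-length chromosome")
  set.seed(config$seed)
  chroms <- vapply(seq_len(config$n_chromosomes),
                   function(i) .random_dna(config$chrom_length, config$gc),
                   character(1))
  names(chroms) <- paste0("chr", seq_len(config$n_chromosomes))
  chroms
}

# deterministic layout: genes every (gene span + 11 kb), tail zone for
# free-standing plants; returns per-chromosome tables
.layout_genes <- function(config) {
  set.seed(config$seed + 1L)
  n_chr <- config$n_chromosomes
  per_chr <- rep(config$n_reference_genes %/% n_chr, n_chr)
  extra <- config$n_reference_genes %% n_chr
  if (extra) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  genes <- list()
  g <- 0L
  tail_start <- integer(n_chr)
  for (c_i in seq_len(n_chr)) {
    cursor <- 3000L
    for (k in seq_len(per_chr[c_i])) {
      g <- g + 1L
      n_ex <- sample(3:4, 1)
      ex_w <- sample(150:400, n_ex, replace = TRUE)
      in_w <- sample(500:900, n_ex - 1, replace = TRUE)
      starts <- cursor + cumsum(c(0L, ex_w[-n_ex] + in_w))
      ends <- starts + ex_w - 1L
      genes[[g]] <- data.frame(
        gene_id = sprintf("GENE%04d", g),
        transcript_id = sprintf("GENE%04d.1", g),
        chrom = paste0("chr", c_i),
        exon_start = starts, exon_end = ends,
        strand = if (g %% 2L) "+" else "-",
        stringsAsFactors = FALSE)
      cursor <- max(ends) + 11000L
    }
    tail_start[c_i] <- cursor + 6000L
  }
  list(genes = do.call(rbind, genes), tail_start = tail_start,
       per_chr = per_chr)
}

#' Generate reference and predicted annotations
#'
#' Reference genes are multi-exon (3-4 exons), non-overlapping, spaced 11 kb
#' apart; ab-initio predicted genes are placed in the gene-free tail of each
#' chromosome, exon-disjoint from every reference gene.
#'
#' @param config a [simulation_config()].
#' @param genome output of [generate_genome()] (used for bounds checking).
#' @return list with `reference` and `predicted` transcript sets and the
#'   internal `layout` (gene table, tail-zone starts, predicted table).
#' @export
generate_annotations <- function(config, genome) {
  lay <- .layout_genes(config)
  chrom_len <- nchar(genome[1])
  # predicted genes at the start of each tail zone
  set.seed(config$seed + 2L)
  n_chr <- config$n_chromosomes
  preds <- list()
  pred_cursor <- lay$tail_start
  for (p in seq_len(config$n_predicted_genes)) {
    c_i <- ((p - 1L) %% n_chr) + 1L
    w <- sample(300:700, 1)
    s <- pred_cursor[c_i]
    preds[[p]] <- data.frame(
      gene_id = sprintf("gene.%06d", 470000 + p),
      transcript_id = sprintf("PRED%04d", p),
      chrom = paste0("chr", c_i),
      exon_start = s, exon_end = s + w - 1L,
      strand = if (p %% 2L) "+" else "-", stringsAsFactors = FALSE)
    pred_cursor[c_i] <- s + w + 3000L
  }
  pred_df <- if (length(preds)) do.call(rbind, preds) else NULL
  lay$plant_start <- pred_cursor + 3000L
  gmax <- tapply(c(lay$genes$exon_end, pred_cursor),
                 c(lay$genes$chrom, paste0("chr", seq_len(n_chr))), max)
  if (any(gmax > chrom_len))
    stop("insufficient chromosome length for requested gene count")
  reference <- transcript_set(data.frame(
    chrom = lay$genes$chrom, start = lay$genes$exon_start,
    end = lay$genes$exon_end, strand = lay$genes$strand,
    transcript_id = lay$genes$transcript_id, gene_id = lay$genes$gene_id),
    source = "reference")
  predicted <- if (!is.null(pred_df)) transcript_set(data.frame(
    chrom = pred_df$chrom, start = pred_df$exon_start, end = pred_df$exon_end,
    strand = pred_df$strand, transcript_id = pred_df$transcript_id,
    gene_id = pred_df$gene_id), source = "predicted")
  else transcript_set(data.frame(chrom = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 transcript_id = character()),
                      source = "predicted")
  lay$predicted <- pred_df
  list(reference = reference, predicted = predicted, layout = lay)
}

#' Plant unknown transcripts of every category into the genome
#'
#' Builds the assembled-transcript set: for each configured category the
#' planted transcripts get a genomic placement, exon structure, designed
#' sequence (codon-biased ORFs for coding plants, background composition for
#' noncoding ones; pseudogene copies duplicate a source gene's spliced
#' sequence at a position with different adjacent genes) and an expression
#' record.  `low_expression` plants get a CI lower bound of exactly 0 in
#' both conditions, to exercise the expression filter.  The genome is
#' patched so that extracting each plant's spliced sequence returns the
#' designed sequence.
#'
#' @param config a [simulation_config()].
#' @param genome character genome from [generate_genome()].
#' @param annotations output of [generate_annotations()].
#' @return list: `assembly` (transcript set), `genome` (patched), `expression`
#'   (data.frame), `truth` (data.frame: `transcript_id`, `category`,
#'   `expected_class_code`, `expected_final`, `expressed`, `conserved`),
#'   `plants` (detail table used by [generate_hit_tables()]).
#' @export
plant_transcripts <- function(config, genome, annotations) {
  set.seed(config$seed + 3L)
  lay <- annotations$layout
  genes <- lay$genes
  n_chr <- config$n_chromosomes
  cursor <- lay$plant_start
  counts <- config$plants
  exp_final <- c(intergenic_noncoding = "lincRNA_candidate",
                 novel_coding = "novel_coding",
                 utr_extension = "utr_of_known_gene",
                 pseudogene_copy = "potential_pseudogene",
                 conserved_lncRNA = "lncRNA_conserved",
                 short_ncRNA = "short_ncRNA_candidate")
  exon_rows <- list(); plant_rows <- list(); t_i <- 0L

  add_plant <- function(category, chrom, exons, strand, seq = NULL,
                        extra = list()) {
    t_i <<- t_i + 1L
    id <- sprintf("TCONS%05d", t_i)
    if (max(exons$end) > nchar(genome[[chrom]]))
      stop("insufficient chromosome length for requested plant counts")
    exon_rows[[t_i]] <<- data.frame(chrom = chrom, start = exons$start,
                                    end = exons$end, strand = strand,
                                    transcript_id = id, gene_id = id,
                                    stringsAsFactors = FALSE)
    if (!is.null(seq)) {
      g <- if (strand == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      else seq
      off <- 0L
      for (e in seq_len(nrow(exons))) {
        w <- exons$end[e] - exons$start[e] + 1L
        substr(genome[[chrom]], exons$start[e], exons$end[e]) <<-
          substr(g, off + 1L, off + w)
        off <- off + w
      }
    }
    plant_rows[[t_i]] <<- c(list(transcript_id = id, category = category,
                                 chrom = chrom,
                                 start = min(exons$start),
                                 end = max(exons$end), strand = strand,
                                 length = sum(exons$end - exons$start + 1L)),
                            extra)
    id
  }

  split_exons <- function(start, len, single_frac) {
    if (stats::runif(1) < single_frac || len < 500L) {
      return(data.frame(start = start, end = start + len - 1L))
    }
    n_ex <- sample(2:3, 1)
    w <- as.integer(round(len * stats::runif(n_ex, 0.8, 1.2) / n_ex))
    w[n_ex] <- len - sum(w[-n_ex])
    if (any(w < 50L)) return(data.frame(start = start, end = start + len - 1L))
    introns <- sample(300:600, n_ex - 1, replace = TRUE)
    st <- start + cumsum(c(0L, w[-n_ex] + introns))
    data.frame(start = st, end = st + w - 1L)
  }

  place_tail <- function(chrom_i, span) {
    s <- cursor[chrom_i]
    cursor[chrom_i] <<- s + span + 2600L
    s
  }

  gene_exons <- split(genes, genes$gene_id)
  # round-robin chromosome assignment keeps layouts balanced
  rr <- function(i) ((i - 1L) %% n_chr) + 1L

  for (k in seq_len(counts[["intergenic_noncoding"]])) {
    len <- as.integer(round(exp(stats::runif(1, log(250), log(4000)))))
    c_i <- rr(k)
    st <- place_tail(c_i, len + 1500L)
    ex <- split_exons(st, len, config$single_exon_fraction)
    strand <- sample(c("+", "-", "*"), 1, prob = c(0.35, 0.35, 0.3))
    if (nrow(ex) > 1L && strand == "*") strand <- "+"
    add_plant("intergenic_noncoding", paste0("chr", c_i), ex, strand,
              seq = .noncoding_dna(len, config$gc))
  }
  for (k in seq_len(counts[["novel_coding"]])) {
    len <- sample(600:1800, 1)
    c_i <- rr(k)
    st <- place_tail(c_i, len + 1500L)
    ex <- split_exons(st, len, config$single_exon_fraction)
    strand <- sample(c("+", "-"), 1)
    add_plant("novel_coding", paste0("chr", c_i), ex, strand,
              seq = .coding_dna(len, config$coding_bias, config$gc,
                                min_orf = 300L))
  }
  for (k in seq_len(counts[["conserved_lncRNA"]])) {
    len <- sample(500:2500, 1)
    c_i <- rr(k)
    st <- place_tail(c_i, len + 1500L)
    ex <- data.frame(start = st, end = st + len - 1L)
    strand <- sample(c("+", "-"), 1)
    add_plant("conserved_lncRNA", paste0("chr", c_i), ex, strand,
              seq = .noncoding_dna(len, config$gc),
              extra = list(conserved = TRUE))
  }
  for (k in seq_len(counts[["short_ncRNA"]])) {
    len <- sample(80:195, 1)
    c_i <- rr(k)
    st <- place_tail(c_i, len + 1000L)
    add_plant("short_ncRNA", paste0("chr", c_i),
              data.frame(start = st, end = st + len - 1L),
              sample(c("+", "*"), 1), seq = .noncoding_dna(len, config$gc))
  }
  for (k in seq_len(counts[["low_expression"]])) {
    len <- sample(300:1500, 1)
    c_i <- rr(k)
    st <- place_tail(c_i, len + 1000L)
    add_plant("low_expression", paste0("chr", c_i),
              data.frame(start = st, end = st + len - 1L),
              sample(c("+", "-"), 1), seq = .noncoding_dna(len, config$gc))
  }
  # pseudogene copies: spliced copy of a source gene from ANOTHER chromosome,
  # so the adjacent gene context cannot match
  gene_ids <- unique(genes$gene_id)
  for (k in seq_len(counts[["pseudogene_copy"]])) {
    c_i <- rr(k)
    src_pool <- gene_ids[genes$chrom[match(gene_ids, genes$gene_id)] !=
                         paste0("chr", c_i)]
    src <- sample(src_pool, 1)
    gx <- gene_exons[[src]]
    src_seq <- paste(vapply(seq_len(nrow(gx)), function(e)
      substr(genome[[gx$chrom[1]]], gx$exon_start[e], gx$exon_end[e]),
      character(1)), collapse = "")
    if (gx$strand[1] == "-")
      src_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(src_seq)))
    len <- nchar(src_seq)
    st <- place_tail(c_i, len + 1500L)
    add_plant("pseudogene_copy", paste0("chr", c_i),
              data.frame(start = st, end = st + len - 1L), "+",
              seq = src_seq, extra = list(source_gene = src))
  }
  # predicted-locus matches: single exon overlapping a predicted exon
  if (counts[["predicted_match"]] > 0L && is.null(lay$predicted))
    stop("predicted_match plants requested but no predicted genes configured")
  for (k in seq_len(counts[["predicted_match"]])) {
    p <- lay$predicted[((k - 1L) %% nrow(lay$predicted)) + 1L, ]
    len <- sample(200:400, 1)
    st <- p$exon_start + 50L
    add_plant("predicted_match", p$chrom,
              data.frame(start = st, end = st + len - 1L), "+")
  }
  # UTR extensions: just downstream/upstream of a reference gene, within 1 kb
  for (k in seq_len(counts[["utr_extension"]])) {
    gid <- gene_ids[((k - 1L) %% length(gene_ids)) + 1L]
    gx <- gene_exons[[gid]]
    d <- sample(200:900, 1)
    len <- sample(250:800, 1)
    st <- max(gx$exon_end) + d + 1L
    add_plant("utr_extension", gx$chrom[1],
              data.frame(start = st, end = st + len - 1L), gx$strand[1],
              seq = .noncoding_dna(len, config$gc),
              extra = list(neighbour_gene = gid, planted_distance = d))
  }
  # known isoforms: first two exons of a (>=3-exon) gene
  for (k in seq_len(counts[["known_isoform"]])) {
    gid <- gene_ids[((k - 1L) %% length(gene_ids)) + 1L]
    gx <- gene_exons[[gid]]
    add_plant("known_isoform", gx$chrom[1],
              data.frame(start = gx$exon_start[1:2], end = gx$exon_end[1:2]),
              gx$strand[1])
  }
  # intronic plants: inside the first intron of a gene
  for (k in seq_len(counts[["intronic"]])) {
    gid <- gene_ids[((k - 1L) %% length(gene_ids)) + 1L]
    gx <- gene_exons[[gid]]
    i_s <- gx$exon_end[1] + 50L
    i_e <- gx$exon_start[2] - 50L
    len <- min(sample(100:300, 1), i_e - i_s - 10L)
    add_plant("intronic", gx$chrom[1],
              data.frame(start = i_s, end = i_s + len - 1L),
              sample(c("+", "-"), 1))
  }

  chrom_len <- nchar(genome[1])
  if (any(cursor > chrom_len))
    stop("insufficient chromosome length for requested plant counts")

  exons <- do.call(rbind, exon_rows)
  plants <- do.call(rbind, lapply(plant_rows, function(r) {
    base <- list(source_gene = NA_character_, neighbour_gene = NA_character_,
                 planted_distance = NA_real_, conserved = FALSE)
    base[names(r)] <- r
    as.data.frame(base, stringsAsFactors = FALSE)
  }))
  assembly <- transcript_set(exons, source = "assembly")

  # expression records
  n <- nrow(plants)
  fpkm_p <- stats::rlnorm(n, config$fpkm_meanlog, config$fpkm_sdlog)
  fpkm_n <- stats::rlnorm(n, config$fpkm_meanlog, config$fpkm_sdlog)
  lowx <- plants$category == "low_expression"
  expression <- data.frame(
    transcript_id = plants$transcript_id,
    fpkm_pig = round(fpkm_p, 3),
    ci_low_pig = round(ifelse(lowx, 0, fpkm_p * config$ci_low_frac), 3),
    ci_high_pig = round(fpkm_p * config$ci_high_frac, 3),
    fpkm_nonpig = round(fpkm_n, 3),
    ci_low_nonpig = round(ifelse(lowx, 0, fpkm_n * config$ci_low_frac), 3),
    ci_high_nonpig = round(fpkm_n * config$ci_high_frac, 3),
    stringsAsFactors = FALSE)

  code_of <- c(known_isoform = "j", intronic = "i")
  truth <- data.frame(
    transcript_id = plants$transcript_id,
    category = plants$category,
    expected_class_code = ifelse(plants$category %in% names(code_of),
                                 code_of[plants$category], "u"),
    expected_final = ifelse(plants$category %in% names(exp_final),
                            exp_final[plants$category], NA_character_),
    expressed = !lowx,
    conserved = plants$conserved,
    stringsAsFactors = FALSE)

  list(assembly = assembly, genome = genome, expression = expression,
       truth = truth, plants = plants)
}

#' Generate inter- and intraspecies hit tables with subject contexts
#'
#' Conserved lncRNA plants get near-full-length, high-identity hits to mock
#' human lncRNA database entries whose flanking-gene context matches the
#' plant's; pseudogene copies get coding-gene hits whose context is that of
#' the source gene (discordant by construction); UTR-extension plants get
#' hits to the human ortholog of their adjacent gene.  With `config$decoys`,
#' near-threshold decoy hits straddling each screening/curation cut are
#' added to intergenic noncoding plants; every decoy must be rejected by the
#' rules.
#'
#' @param config a [simulation_config()].
#' @param plants detail table from [plant_transcripts()].
#' @param annotations output of [generate_annotations()].
#' @param reference_index optional precomputed [annotation_index()] of the
#'   reference (built internally otherwise).
#' @return list: `inter` (data.frame, outfmt-6 + annotation columns),
#'   `intra` (same), `context` (subject context table).
#' @export
generate_hit_tables <- function(config, plants, annotations,
                                reference_index = NULL) {
  set.seed(config$seed + 4L)
  if (is.null(reference_index))
    reference_index <- annotation_index(annotations$reference)
  spans <- GenomicRanges::GRanges(plants$chrom,
                                  IRanges::IRanges(plants$start, plants$end))
  spans$transcript_id <- plants$transcript_id
  qctx <- locus_context(spans, reference_index)
  genes <- annotations$layout$genes

  gene_ctx <- function(gid) {
    gx <- genes[genes$gene_id == gid, ]
    g_span <- GenomicRanges::GRanges(gx$chrom[1],
      IRanges::IRanges(min(gx$exon_start), max(gx$exon_end)))
    g_span$transcript_id <- gid
    locus_context(g_span, reference_index)
  }

  hit_row <- function(qid, sid, pident, qlen, covered, db, species) {
    qstart <- max(1L, as.integer(floor((qlen - covered) / 2)) + 1L)
    data.frame(qseqid = qid, sseqid = sid, pident = pident,
               length = covered, mismatch = round(covered * (100 - pident) / 100),
               gapopen = 0L, qstart = qstart, qend = qstart + covered - 1L,
               sstart = 1L, send = covered, evalue = 1e-30,
               bitscore = round(covered * 1.8), subject_db = db,
               subject_species = species, stringsAsFactors = FALSE)
  }

  inter <- list(); intra <- list(); ctx <- list()
  pid <- config$conservation_identity
  for (i in seq_len(nrow(plants))) {
    p <- plants[i, ]
    qc <- qctx[qctx$entity_id == p$transcript_id, ]
    if (p$category == "conserved_lncRNA") {
      sid <- sprintf("HSLNC%04d", i)
      covered <- max(150L, as.integer(floor(0.97 * p$length)))
      inter[[length(inter) + 1L]] <-
        hit_row(p$transcript_id, sid, pid, p$length, covered,
                "lncipedia", "human")
      ctx[[length(ctx) + 1L]] <- data.frame(
        entity_id = sid, chrom = "HSA1",
        upstream_gene = qc$upstream_gene, downstream_gene = qc$downstream_gene,
        locus_kind = "noncoding_gene", ortholog = NA_character_,
        stringsAsFactors = FALSE)
    } else if (p$category == "pseudogene_copy") {
      sid <- paste0("HS_", p$source_gene)
      covered <- max(150L, as.integer(floor(0.95 * p$length)))
      inter[[length(inter) + 1L]] <-
        hit_row(p$transcript_id, sid, max(pid, 95), p$length, covered,
                "refseq", "human")
      sc <- gene_ctx(p$source_gene)
      ctx[[length(ctx) + 1L]] <- data.frame(
        entity_id = sid, chrom = "HSA2",
        upstream_gene = sc$upstream_gene, downstream_gene = sc$downstream_gene,
        locus_kind = "coding_gene", ortholog = p$source_gene,
        stringsAsFactors = FALSE)
    } else if (p$category == "utr_extension") {
      sid <- paste0("HS_", p$neighbour_gene)
      covered <- max(150L, as.integer(floor(0.96 * p$length)))
      inter[[length(inter) + 1L]] <-
        hit_row(p$transcript_id, sid, max(pid, 95), p$length, covered,
                "refseq", "human")
      nc <- gene_ctx(p$neighbour_gene)
      # the human ortholog's neighbours are the same symbols as the bovine
      # gene's neighbours, plus the gene itself
      up <- if (is.na(nc$upstream_gene)) p$neighbour_gene
            else paste(p$neighbour_gene, nc$upstream_gene, sep = ",")
      ctx[[length(ctx) + 1L]] <- data.frame(
        entity_id = sid, chrom = "HSA3",
        upstream_gene = up, downstream_gene = nc$downstream_gene,
        locus_kind = "coding_gene", ortholog = p$neighbour_gene,
        stringsAsFactors = FALSE)
    }
  }

  if (isTRUE(config$decoys)) {
    targets <- plants[plants$category == "intergenic_noncoding" &
                      plants$length >= 250, ]
    targets <- utils::head(targets, 8L)
    for (i in seq_len(nrow(targets))) {
      p <- targets[i, ]
      qid <- p$transcript_id
      # (a) fails screening: total identity just under 90
      inter[[length(inter) + 1L]] <-
        hit_row(qid, sprintf("DECOYA%03d", i), 89.9, p$length, p$length,
                "noncode", "human")
      # (b) fails screening: covered region just under 100
      inter[[length(inter) + 1L]] <-
        hit_row(qid, sprintf("DECOYB%03d", i), 95, p$length,
                min(99L, p$length), "noncode", "human")
      # (c) passes screening and curation but non-syntenic noncoding subject
      sidc <- sprintf("DECOYC%03d", i)
      inter[[length(inter) + 1L]] <-
        hit_row(qid, sidc, 91, p$length, p$length, "noncode", "human")
      ctx[[length(ctx) + 1L]] <- data.frame(
        entity_id = sidc, chrom = "HSA9",
        upstream_gene = "DECOYUP", downstream_gene = "DECOYDN",
        locus_kind = "noncoding_gene", ortholog = NA_character_,
        stringsAsFactors = FALSE)
      # (d) intraspecies: screens at >=90 but fails curation (<95)
      intra[[length(intra) + 1L]] <-
        hit_row(qid, sprintf("BTDECOY%03d", i), 94.9, p$length, p$length,
                "bovine-set-1", "bovine")
    }
  }

  empty_hits <- data.frame(qseqid = character(), sseqid = character(),
                           pident = numeric(), length = numeric(),
                           mismatch = numeric(), gapopen = numeric(),
                           qstart = numeric(), qend = numeric(),
                           sstart = numeric(), send = numeric(),
                           evalue = numeric(), bitscore = numeric(),
                           subject_db = character(),
                           subject_species = character(),
                           stringsAsFactors = FALSE)
  list(inter = if (length(inter)) do.call(rbind, inter) else empty_hits,
       intra = if (length(intra)) do.call(rbind, intra) else empty_hits,
       context = if (length(ctx)) do.call(rbind, ctx) else
         data.frame(entity_id = character(), chrom = character(),
                    upstream_gene = character(), downstream_gene = character(),
                    locus_kind = character(), ortholog = character(),
                    stringsAsFactors = FALSE))
}

#' Generate training corpora for the coding scorers
#'
#' Coding sequences follow the same UTR/ORF/UTR construction (and codon
#' bias) as the coding plants; noncoding sequences are background
#' composition.  Drawn with an offset seed so corpora and plants are
#' disjoint samples from the same distributions.
#'
#' @param config a [simulation_config()].
#' @return list of character vectors `coding` and `noncoding`, named.
#' @export
generate_training_corpora <- function(config) {
  set.seed(config$seed + 5L)
  n <- config$n_train
  lens_c <- sample(600:2000, n, replace = TRUE)
  # log-uniform noncoding lengths: the short-length regime, where chance ORF
  # coverage runs high, must be well represented for a calibrated scorer
  lens_n <- as.integer(round(exp(stats::runif(n, log(80), log(2500)))))
  coding <- vapply(lens_c, function(l)
    .coding_dna(l, config$coding_bias, config$gc, min_orf = 300L), character(1))
  noncoding <- vapply(lens_n, function(l) .random_dna(l, config$gc),
                      character(1))
  names(coding) <- sprintf("TRAINC%04d", seq_len(n))
  names(noncoding) <- sprintf("TRAINN%04d", seq_len(n))
  list(coding = coding, noncoding = noncoding)
}

#' Generate a complete synthetic fixture
#'
#' Runs genome, annotation, plant, hit-table and training-corpus generation
#' under one seed and (optionally) writes every file the pipeline consumes.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; when given, writes `genome.fa`,
#'   `reference.gtf`, `predicted.gtf`, `assembly.gtf`, `expression.tsv`,
#'   `hits_interspecies.tsv`, `hits_intraspecies.tsv`, `subject_context.tsv`,
#'   `truth.tsv`, `train_coding.fa`, `train_noncoding.fa`.
#' @return list with all in-memory pieces (`genome` as `DNAStringSet`,
#'   `reference`, `predicted`, `assembly`, `expression`, `truth`, `plants`,
#'   `hits`, `corpora`, `config`, and `files` when `dir` was given).
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL) {
  genome <- generate_genome(config)
  ann <- generate_annotations(config, genome)
  planted <- plant_transcripts(config, genome, ann)
  hits <- generate_hit_tables(config, planted$plants, ann)
  corpora <- generate_training_corpora(config)
  genome_dss <- Biostrings::DNAStringSet(planted$genome)
  out <- list(genome = genome_dss, reference = ann$reference,
              predicted = ann$predicted, assembly = planted$assembly,
              expression = planted$expression, truth = planted$truth,
              plants = planted$plants, hits = hits, corpora = corpora,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(dir, x)
    Biostrings::writeXStringSet(genome_dss, f("genome.fa"))
    write_gtf(ann$reference, f("reference.gtf"))
    write_gtf(ann$predicted, f("predicted.gtf"))
    write_gtf(planted$assembly, f("assembly.gtf"))
    write_expression(planted$expression, f("expression.tsv"))
    wt <- function(df, path, header = TRUE)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = header)
    wt(hits$inter, f("hits_interspecies.tsv"), header = FALSE)
    wt(hits$intra, f("hits_intraspecies.tsv"), header = FALSE)
    wt(hits$context, f("subject_context.tsv"))
    wt(planted$truth, f("truth.tsv"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(corpora$coding),
                                f("train_coding.fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(corpora$noncoding),
                                f("train_noncoding.fa"))
    out$files <- list(
      genome = f("genome.fa"), reference = f("reference.gtf"),
      predicted = f("predicted.gtf"), assembly = f("assembly.gtf"),
      expression = f("expression.tsv"),
      hits_inter = f("hits_interspecies.tsv"),
      hits_intra = f("hits_intraspecies.tsv"),
      context = f("subject_context.tsv"), truth = f("truth.tsv"),
      train_coding = f("train_coding.fa"),
      train_noncoding = f("train_noncoding.fa"))
  }
  out
}
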