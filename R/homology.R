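#' Read a tabular pairwise-alignment hit file
#'
#' Tab-separated, BLAST outfmt-6-compatible: `qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`, followed by two
#' annotation columns `subject_db` (database label, e.g. refseq, gencode,
#' noncode, lncipedia, lincRNA-set, rnadb, lncrnadb, bovine-set-1,
#' bovine-set-2) and `subject_species` (bovine, human, mouse, sheep, other).
#' No header line.
#'
#' Derived per hit: `covered_region` = aligned span on the query
#' (`qend - qstart + 1`) and `total_identity` = `pident * covered_region /
#' query_length` - identity weighted by query coverage, so it can only reach
#' the screening cut for near-full-length alignments.  `pident` itself is the
#' "mapping identity".
#'
#' @param path hit table path.
#' @param query_lengths named numeric vector of query transcript lengths
#'   (spliced), used to derive `total_identity`; every `qseqid` must be
#'   present.
#' @param context optional subject context table (see [read_context_table()]);
#'   joined by `sseqid` into columns `subject_chrom`, `subject_upstream`,
#'   `subject_downstream`, `subject_locus_kind`.
#' @return data.frame of hits with derived columns; zero rows for an empty
#'   file.
#' @export
read_hit_table <- function(path, query_lengths, context = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "subject_db", "subject_species")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
    out$query_length <- numeric(); out$covered_region <- numeric()
    out$total_identity <- numeric()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(cols)))
    stop("hit table line ", which(nf != length(cols))[1], ": expected ",
         length(cols), " columns, got ", nf[nf != length(cols)][1])
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- cols
  for (numcol in c("pident", "length", "mismatch", "gapopen", "qstart",
                   "qend", "sstart", "send", "evalue", "bitscore"))
    df[[numcol]] <- as.numeric(df[[numcol]])
  m <- match(df$qseqid, names(query_lengths))
  if (anyNA(m)) stop("no query length for: ", df$qseqid[which(is.na(m))[1]])
  df$query_length <- as.numeric(query_lengths[m])
  df$covered_region <- df$qend - df$qstart + 1
  bad <- which(df$covered_region > df$query_length | df$pident <= 0 |
               df$pident > 100)
  if (length(bad))
    stop("invalid hit on line ", bad[1],
         " (covered region exceeds query length or identity out of (0,100])")
  df$total_identity <- df$pident * df$covered_region / df$query_length
  if (!is.null(context)) {
    cm <- match(df$sseqid, context$entity_id)
    df$subject_chrom <- context$chrom[cm]
    df$subject_upstream <- context$upstream_gene[cm]
    df$subject_downstream <- context$downstream_gene[cm]
    if ("locus_kind" %in% names(context))
      df$subject_locus_kind <- context$locus_kind[cm]
    if ("ortholog" %in% names(context))
      df$subject_gene <- context$ortholog[cm]
  }
  if (!"subject_locus_kind" %in% names(df))
    df$subject_locus_kind <- "unknown"
  df$subject_locus_kind[is.na(df$subject_locus_kind)] <- "unknown"
  df
}

#' Read a locus-context table
#'
#' TSV with header: `entity_id`, `chrom`, `upstream_gene`, `downstream_gene`
#' and optionally `locus_kind` (coding_gene, noncoding_gene, pseudogene,
#' intergenic, unknown) and `ortholog` (the query-species gene symbol the
#' subject corresponds to, when known).  Flanking-gene cells may hold
#' comma-separated symbol lists (a window of neighbours); empty or `.` means
#' explicitly none.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_context_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("entity_id", "chrom", "upstream_gene", "downstream_gene")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("context table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}

.context_symbols <- function(up, down) {
  syms <- c(strsplit(ifelse(is.na(up), "", up), ",")[[1]],
            strsplit(ifelse(is.na(down), "", down), ",")[[1]])
  syms <- trimws(syms)
  syms[nzchar(syms) & syms != "."]
}

#' Screen similarity hits at the discovery thresholds
#'
#' Interspecies: mapping identity >= 75, total identity >= 90, covered
#' region >= 100 nt.  Intraspecies (bovine subjects): mapping identity >= 90,
#' total identity >= 90, covered region >= 100 nt.  With `mode = "auto"` the
#' per-hit mode follows `subject_species`.
#'
#' @param hits data.frame from [read_hit_table()].
#' @param mode `"auto"`, `"interspecies"` or `"intraspecies"`.
#' @param min_covered covered-region floor (default 100).
#' @param min_total total-identity floor (default 90).
#' @param min_mapping_inter,min_mapping_intra mapping-identity floors
#'   (defaults 75 and 90).
#' @return the passing subset of `hits`, with a `screen_mode` column.
#' @export
screen_hits <- function(hits, mode = c("auto", "interspecies", "intraspecies"),
                        min_covered = 100, min_total = 90,
                        min_mapping_inter = 75, min_mapping_intra = 90) {
  mode <- match.arg(mode)
  if (!nrow(hits)) { hits$screen_mode <- character(); return(hits) }
  hit_mode <- switch(mode,
    auto = ifelse(hits$subject_species == "bovine", "intraspecies", "interspecies"),
    rep(mode, nrow(hits)))
  min_map <- ifelse(hit_mode == "intraspecies", min_mapping_intra, min_mapping_inter)
  pass <- hits$pident >= min_map &
          hits$total_identity >= min_total &
          hits$covered_region >= min_covered
  out <- hits[pass, , drop = FALSE]
  out$screen_mode <- hit_mode[pass]
  rownames(out) <- NULL
  out
}

#' Curate screened hits and attach the synteny verdict
#'
#' Sequence-level curation: interspecies hits pass at covered region >= 150
#' nt with identity >= 75%, or via the rescue rule (identity >= 90% over a
#' shorter region, i.e. covered < 150 but still above the screening floor).
#' Intraspecies hits pass at identity >= 95%.  The rescue rule's identity is
#' the mapping identity by default (`rescue_on = "mapping"`); the printed
#' rule does not say which identity it refers to, so `"total"` is available.
#'
#' Synteny is assessed separately and recorded, not used to drop hits: an
#' interspecies hit is syntenic when query and subject share at least one
#' flanking gene symbol; an intraspecies hit requires identical flanking
#' symbol sets ("identical adjacent loci").  Hits without subject context
#' get `syntenic = NA` (uncurated context, never silently treated as
#' syntenic).  Downstream category assignment consumes both columns: the
#' conserved categories require `curated & syntenic`, the pseudogene
#' inference requires a curated hit whose context is discordant.
#'
#' @param hits screened hits (from [screen_hits()]).
#' @param query_ctx data.frame of query contexts (`entity_id`,
#'   `upstream_gene`, `downstream_gene`), e.g. from [locus_context()].
#' @param min_covered_curation,min_identity_inter,rescue_identity,min_identity_intra
#'   curation cuts (defaults 150, 75, 90, 95).
#' @param rescue_on `"mapping"` or `"total"`: which identity the rescue rule
#'   tests.
#' @return `hits` restricted to curation passes, with logical `rescued` and
#'   `syntenic` columns.
#' @export
curate_hits <- function(hits, query_ctx,
                        min_covered_curation = 150, min_identity_inter = 75,
                        rescue_identity = 90, min_identity_intra = 95,
                        rescue_on = c("mapping", "total")) {
  rescue_on <- match.arg(rescue_on)
  if (!nrow(hits)) {
    hits$rescued <- logical(); hits$syntenic <- logical()
    return(hits)
  }
  if (!"screen_mode" %in% names(hits))
    stop("hits must be screened first (no screen_mode column)")
  rescue_id <- if (rescue_on == "mapping") hits$pident else hits$total_identity
  inter <- hits$screen_mode == "interspecies"
  main_pass <- inter & hits$covered_region >= min_covered_curation &
               hits$pident >= min_identity_inter
  rescue_pass <- inter & !main_pass & rescue_id >= rescue_identity &
                 hits$covered_region < min_covered_curation
  intra_pass <- !inter & hits$pident >= min_identity_intra
  pass <- main_pass | rescue_pass | intra_pass

  qm <- match(hits$qseqid, query_ctx$entity_id)
  syntenic <- rep(NA, nrow(hits))
  for (i in which(pass)) {
    if (is.na(qm[i]) || is.null(hits$subject_upstream)) next
    qs <- .context_symbols(query_ctx$upstream_gene[qm[i]],
                           query_ctx$downstream_gene[qm[i]])
    ss <- .context_symbols(hits$subject_upstream[i], hits$subject_downstream[i])
    if (!length(ss) && is.na(hits$subject_upstream[i]) &&
        is.na(hits$subject_downstream[i])) next  # no context: NA
    syntenic[i] <- if (inter[i]) length(intersect(qs, ss)) >= 1L
                   else setequal(qs, ss)
  }
  out <- hits[pass, , drop = FALSE]
  out$rescued <- rescue_pass[pass]
  out$syntenic <- as.logical(syntenic[pass])
  rownames(out) <- NULL
  out
}

#' Assign the similarity-based category of one unknown transcript
#'
#' Decision order, applied to the best curated hit (highest total identity;
#' ties by longer covered region, then lexicographic subject id):
#'
#' 1. subject is a known lncRNA entry (noncoding database / noncoding gene)
#'    or an intergenic subject region, syntenic: `lncRNA_conserved`;
#' 2. subject is a coding gene, syntenic, transcript lies within `utr_dist`
#'    of its nearest annotated bovine neighbour: `utr_of_known_gene`;
#' 3. subject is a coding gene, syntenic, and that gene is already annotated
#'    near the transcript (subject matches a flanking symbol): `amended_gene`
#'    (the transcript extends the known exon structure);
#' 4. subject is a coding gene, syntenic, with no bovine annotation at the
#'    position: `potential_novel_gene`;
#' 5. subject is an annotated pseudogene: `pseudogene`;
#' 6. subject is a coding gene but the context is NOT syntenic (different
#'    adjacent gene context): `potential_pseudogene`;
#' 7. otherwise `none` (a bovine-specific candidate).
#'
#' @param ut_id transcript id (for error messages only).
#' @param curated_hits curated hits of this transcript ([curate_hits()] rows
#'   with `qseqid == ut_id`).
#' @param query_ctx one-row query context for the transcript (or the full
#'   table; matched by `entity_id`).
#' @param neighbour_distance distance to the nearest annotated locus (nt).
#' @param utr_dist the UTR-association window (default 1000).
#' @return character scalar category.
#' @export
assign_homology_category <- function(ut_id, curated_hits, query_ctx,
                                     neighbour_distance = Inf,
                                     utr_dist = 1000) {
  h <- curated_hits[curated_hits$qseqid == ut_id, , drop = FALSE]
  if (!nrow(h)) return("none")
  h <- h[order(-h$total_identity, -h$covered_region, h$sseqid), , drop = FALSE]
  qrow <- query_ctx[query_ctx$entity_id == ut_id, , drop = FALSE]
  q_syms <- if (nrow(qrow))
    .context_symbols(qrow$upstream_gene[1], qrow$downstream_gene[1])
  else character()
  best <- h[1, ]
  kind <- best$subject_locus_kind
  noncoding_dbs <- c("noncode", "lncipedia", "lincRNA-set", "rnadb",
                     "lncrnadb", "bovine-set-1", "bovine-set-2", "rfam")
  is_lnc_subject <- kind %in% c("noncoding_gene", "intergenic") ||
                    best$subject_db %in% noncoding_dbs
  syntenic <- isTRUE(best$syntenic)
  if (is_lnc_subject && kind != "pseudogene") {
    if (syntenic) return("lncRNA_conserved")
    return("none")
  }
  if (kind == "pseudogene") return("pseudogene")
  if (kind == "coding_gene") {
    if (syntenic) {
      if (neighbour_distance <= utr_dist) return("utr_of_known_gene")
      subj_gene <- if (!is.null(best$subject_gene)) best$subject_gene
                   else NA_character_
      if (!is.na(subj_gene) && subj_gene %in% q_syms) return("amended_gene")
      return("potential_novel_gene")
    }
    if (identical(best$syntenic, FALSE)) return("potential_pseudogene")
    return("none")  # context unavailable: never inferred as pseudogene
  }
  "none"
}
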