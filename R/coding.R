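#' Threshold set for the two coding-potential scorers
#'
#' Defaults are the published operating points: a CPC-style score is called
#' coding at `>= 1` and noncoding at `<= -0.5`; the CPAT-style coding
#' probability is called coding at `>= 0.5` and noncoding at `< 0.02`.
#' Scores between the cuts are ambiguous.  Note the inequality directions
#' differ between the two tools and are applied verbatim.
#'
#' @param cpc_coding,cpc_noncoding,cpat_coding,cpat_noncoding numeric cuts.
#' @return named list of class `coding_thresholds`.
#' @export
coding_thresholds <- function(cpc_coding = 1, cpc_noncoding = -0.5,
                              cpat_coding = 0.5, cpat_noncoding = 0.02) {
  stopifnot(cpc_noncoding < cpc_coding, cpat_noncoding < cpat_coding)
  structure(list(cpc_coding = cpc_coding, cpc_noncoding = cpc_noncoding,
                 cpat_coding = cpat_coding, cpat_noncoding = cpat_noncoding),
            class = "coding_thresholds")
}

#' Categorise a tool score as coding / noncoding / ambiguous
#'
#' @param score numeric vector of scores.
#' @param tool `"cpc"` (unbounded score) or `"cpat"` (probability in [0,1]).
#' @param thresholds a [coding_thresholds()].
#' @return character vector in `{coding, noncoding, ambiguous}`.
#' @export
classify_tool_score <- function(score, tool = c("cpc", "cpat"),
                                thresholds = coding_thresholds()) {
  tool <- match.arg(tool)
  if (tool == "cpc") {
    ifelse(score >= thresholds$cpc_coding, "coding",
           ifelse(score <= thresholds$cpc_noncoding, "noncoding", "ambiguous"))
  } else {
    ifelse(score >= thresholds$cpat_coding, "coding",
           ifelse(score < thresholds$cpat_noncoding, "noncoding", "ambiguous"))
  }
}

#' Intersection of the two per-tool categories
#'
#' Equal categories pass through; unequal categories yield `inconsistent`.
#' Symmetric in its arguments.
#'
#' @param cat_cpc,cat_cpat character vectors in `{coding, noncoding,
#'   ambiguous}`.
#' @return character vector in `{coding, noncoding, ambiguous, inconsistent}`.
#' @export
consensus_category <- function(cat_cpc, cat_cpat) {
  ifelse(cat_cpc == cat_cpat, cat_cpc, "inconsistent")
}

#' Compute the four coding-potential features of a sequence set
#'
#' Per transcript: length of the longest ATG-anchored ORF (`orf_length`, 0
#' when none), its fraction of the transcript (`orf_coverage`), the Fickett
#' TESTCODE score, and the in-frame hexamer log-likelihood ratio (scored over
#' the whole sequence, step 1, when there is no ORF).
#'
#' The in-frame hexamer estimate needs enough dicodons to be stable: when
#' the longest ORF is shorter than 60 nt the whole-sequence (step 1) scan is
#' used instead, exactly as for ORF-free sequences.
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param hex_model a [hexamer_model()].
#' @param strands per-sequence ORF scanning mode: `"sense"` or `"both"`;
#'   recycled (use `"both"` for strand-unknown transcripts).
#' @return data.frame with columns `transcript_id`, `length`, `orf_length`,
#'   `orf_coverage`, `fickett`, `hexamer`, `orf_has_start`, `orf_strand`.
#' @export
coding_features <- function(seqs, hex_model, strands = "sense") {
  ids <- names(seqs)
  sq <- as.character(seqs)  # drops names, hence captured first
  if (is.null(ids)) ids <- paste0("seq", seq_along(sq))
  strands <- rep_len(strands, length(sq))
  out <- data.frame(transcript_id = ids, length = nchar(sq),
                    orf_length = 0L, orf_coverage = 0,
                    fickett = NA_real_, hexamer = NA_real_,
                    orf_has_start = FALSE, orf_strand = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sq)) {
    orf <- longest_orf(sq[i], mode = "atg_anchored", strands = strands[i])
    s_for_hex <- sq[i]
    orf_start <- NULL
    if (nrow(orf)) {
      out$orf_length[i] <- orf$length_nt
      out$orf_coverage[i] <- orf$length_nt / nchar(sq[i])
      out$orf_has_start[i] <- orf$has_start
      out$orf_strand[i] <- orf$strand
      if (orf$strand == "antisense")
        s_for_hex <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(sq[i])))
      # frame-specific hexamer statistics are meaningless on tiny ORFs
      if (orf$length_nt >= 60L) orf_start <- orf$start
    }
    out$fickett[i] <- fickett_score(sq[i])
    out$hexamer[i] <- hexamer_llr(s_for_hex, hex_model, orf_start = orf_start)
  }
  out
}

#' Train the alignment-free logistic coding scorer
#'
#' A CPAT-style scorer: logistic regression of coding status on the four
#' sequence features (ORF length, ORF coverage, Fickett score, hexamer LLR),
#' with the hexamer model trained on the same corpora (ORF regions of the
#' coding corpus vs whole noncoding sequences).  Training is deterministic
#' given the corpora; `seed` only fixes any downstream stochastic use.
#'
#' @param coding_seqs,noncoding_seqs training corpora (character or
#'   `DNAStringSet`); at least 2 sequences per class, >= 50 recommended.
#' @param seed integer stored with the model.
#' @param features which of the four features to use (default all); the
#'   CPC-style proxy uses a reweighted subset, see [train_cpc_proxy()].
#' @return object of class `coding_scorer` with elements `fit` (glm),
#'   `hex_model`, `features`, `seed`.
#' @export
train_coding_model <- function(coding_seqs, noncoding_seqs, seed = 1,
                               features = c("orf_length", "orf_coverage",
                                            "fickett", "hexamer")) {
  coding_seqs <- as.character(coding_seqs)
  noncoding_seqs <- as.character(noncoding_seqs)
  if (length(coding_seqs) < 2L || length(noncoding_seqs) < 2L)
    stop("need at least two sequences in each class")
  orf_regions <- vapply(coding_seqs, function(s) {
    orf <- longest_orf(s)
    if (nrow(orf)) substring(s, orf$start, orf$end) else s
  }, character(1))
  hm <- hexamer_model(orf_regions, noncoding_seqs)
  fx <- rbind(coding_features(coding_seqs, hm),
              coding_features(noncoding_seqs, hm))
  fx$label <- rep(c(1L, 0L), c(length(coding_seqs), length(noncoding_seqs)))
  fml <- stats::as.formula(paste("label ~", paste(features, collapse = " + ")))
  # perfectly separable training data is expected on designed corpora; the
  # diverging-coefficient warning is benign (fitted probabilities saturate)
  fit <- suppressWarnings(stats::glm(fml, data = fx, family = stats::binomial()))
  structure(list(fit = fit, hex_model = hm, features = features, seed = seed),
            class = "coding_scorer")
}

#' @export
print.coding_scorer <- function(x, ...) {
  cat("coding_scorer: logistic regression on",
      paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Score sequences with a trained coding scorer
#'
#' @param object a `coding_scorer`.
#' @param seqs sequences to score (or a precomputed feature data.frame from
#'   [coding_features()]).
#' @param type `"prob"` for the coding probability in [0,1] (CPAT-style),
#'   `"score"` for the scaled linear predictor (unbounded, CPC-style).
#' @param strands passed to [coding_features()].
#' @param ... unused.
#' @return named numeric vector.
#' @export
predict.coding_scorer <- function(object, seqs, type = c("prob", "score"),
                                  strands = "sense", ...) {
  type <- match.arg(type)
  fx <- if (is.data.frame(seqs)) seqs
        else coding_features(seqs, object$hex_model, strands = strands)
  eta <- suppressWarnings(
    stats::predict(object$fit, newdata = fx, type = "link"))
  out <- if (type == "prob") stats::plogis(eta) else eta / 4
  setNames(as.numeric(out), fx$transcript_id)
}

#' Train the internal CPC-style proxy scorer
#'
#' The pipeline's second, independent scorer for offline runs when no
#' external CPC score table is supplied.  Same feature family as the
#' CPAT-style scorer but a different weighting: log-transformed ORF length,
#' no ORF-coverage term, and its output is the scaled logistic linear
#' predictor (unbounded, sign-coded like a CPC score) rather than a
#' probability.
#'
#' @inheritParams train_coding_model
#' @return a `coding_scorer` whose natural output type is `"score"`.
#' @export
train_cpc_proxy <- function(coding_seqs, noncoding_seqs, seed = 2) {
  coding_seqs <- as.character(coding_seqs)
  noncoding_seqs <- as.character(noncoding_seqs)
  if (length(coding_seqs) < 2L || length(noncoding_seqs) < 2L)
    stop("need at least two sequences in each class")
  orf_regions <- vapply(coding_seqs, function(s) {
    orf <- longest_orf(s)
    if (nrow(orf)) substring(s, orf$start, orf$end) else s
  }, character(1))
  hm <- hexamer_model(orf_regions, noncoding_seqs)
  fx <- rbind(coding_features(coding_seqs, hm),
              coding_features(noncoding_seqs, hm))
  fx$log_orf <- log1p(fx$orf_length)
  fx$label <- rep(c(1L, 0L), c(length(coding_seqs), length(noncoding_seqs)))
  fit <- suppressWarnings(stats::glm(label ~ log_orf + fickett + hexamer,
                                     data = fx, family = stats::binomial()))
  structure(list(fit = fit, hex_model = hm,
                 features = c("log_orf", "fickett", "hexamer"), seed = seed),
            class = c("cpc_proxy", "coding_scorer"))
}

#' @export
predict.cpc_proxy <- function(object, seqs, type = c("score", "prob"),
                              strands = "sense", ...) {
  type <- match.arg(type)
  fx <- if (is.data.frame(seqs)) seqs
        else coding_features(seqs, object$hex_model, strands = strands)
  fx$log_orf <- log1p(fx$orf_length)
  eta <- suppressWarnings(
    stats::predict(object$fit, newdata = fx, type = "link"))
  out <- if (type == "prob") stats::plogis(eta) else eta / 4
  setNames(as.numeric(out), fx$transcript_id)
}

#' Assess coding potential of a transcript sequence set
#'
#' Runs both scorers, applies the thresholds, and intersects the per-tool
#' categories into the consensus.  An externally computed CPC score column
#' can replace the internal proxy (`cpc_scores`), keeping the published
#' two-tool design when real CPC output is available.
#'
#' @param seqs named sequences (character or `DNAStringSet`).
#' @param cpat_scorer a `coding_scorer` from [train_coding_model()].
#' @param cpc_scorer a `cpc_proxy` from [train_cpc_proxy()]; ignored when
#'   `cpc_scores` is given.
#' @param cpc_scores optional named numeric vector of external CPC scores.
#' @param thresholds a [coding_thresholds()].
#' @param strands per-sequence strand mode, recycled.
#' @return data.frame: the four features plus `cpc_s`, `cpat_p`, `cat_cpc`,
#'   `cat_cpat`, `consensus`.
#' @export
assess_coding <- function(seqs, cpat_scorer, cpc_scorer = NULL,
                          cpc_scores = NULL, thresholds = coding_thresholds(),
                          strands = "sense") {
  fx <- coding_features(seqs, cpat_scorer$hex_model, strands = strands)
  cpat_p <- predict(cpat_scorer, fx, type = "prob")
  if (is.null(cpc_scores)) {
    if (is.null(cpc_scorer)) stop("need cpc_scorer or cpc_scores")
    cpc_s <- predict(cpc_scorer, fx, type = "score")
  } else {
    m <- match(fx$transcript_id, names(cpc_scores))
    if (anyNA(m)) stop("missing external CPC score for: ",
                       fx$transcript_id[which(is.na(m))[1]])
    cpc_s <- as.numeric(cpc_scores[m])
  }
  fx$cpc_s <- as.numeric(cpc_s)
  fx$cpat_p <- as.numeric(cpat_p)
  fx$cat_cpc <- classify_tool_score(fx$cpc_s, "cpc", thresholds)
  fx$cat_cpat <- classify_tool_score(fx$cpat_p, "cpat", thresholds)
  fx$consensus <- consensus_category(fx$cat_cpc, fx$cat_cpat)
  fx
}
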