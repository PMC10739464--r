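# Template selection: rank candidate templates by MHC chain sequence
# identity, then break ties with the core-anchored PAM30 peptide alignment
# score. Because MHC structures are highly conserved, the best-identity
# template is usable even when no template shares either allele (pan-allele
# fallback).

#' Core-anchored peptide alignment
#'
#' Aligns a target peptide to a template peptide by pairing their 9-mer
#' binding cores column-to-column (ungapped) and extending the pairing
#' outward position-by-position into the flanks; the shorter flank is padded
#' with terminal gaps. The score is the sum of substitution-matrix scores
#' over non-gap columns (gap columns score 0, keeping flank-length
#' differences neutral).
#'
#' @param target_pep,template_pep Peptide sequences.
#' @param target_core,template_core `binding_core` objects for the two
#'   peptides.
#' @param matrix Substitution matrix; default PAM30.
#' @return A `pmhc_core_alignment`: `offset_map` (integer vector, one entry
#'   per target position giving the paired template position or `NA`),
#'   `score`.
#' @export
align_peptide_to_template <- function(target_pep, target_core,
                                      template_pep, template_core,
                                      matrix = substitution_matrix("PAM30")) {
  check_aa_string(target_pep, "target peptide")
  check_aa_string(template_pep, "template peptide")
  if (!inherits(target_core, "binding_core") ||
      !inherits(template_core, "binding_core")) {
    abort_pmhc("cores must be binding_core objects", "pmhc_core_error")
  }
  if (target_core$peptide_length != nchar(target_pep) ||
      template_core$peptide_length != nchar(template_pep)) {
    abort_pmhc("binding core does not match its peptide length", "pmhc_core_error")
  }
  lt <- nchar(target_pep)
  lp <- nchar(template_pep)
  # relative position of each target residue to its core start (0-based)
  rel <- seq_len(lt) - (target_core$start + 1L)
  tmpl_pos <- template_core$start + 1L + rel
  offset_map <- ifelse(tmpl_pos >= 1L & tmpl_pos <= lp, tmpl_pos, NA_integer_)
  ta <- seq_to_chars(target_pep)
  tb <- seq_to_chars(template_pep)
  paired <- !is.na(offset_map)
  score <- sum(substitution_score(matrix, ta[paired], tb[offset_map[paired]]))
  structure(list(offset_map = as.integer(offset_map), score = as.integer(score)),
            class = "pmhc_core_alignment")
}

#' @export
print.pmhc_core_alignment <- function(x, ...) {
  cat(sprintf("<core_alignment> score %d, %d/%d target positions paired\n",
              x$score, sum(!is.na(x$offset_map)), length(x$offset_map)))
  invisible(x)
}

#' Rank templates for a modelling target
#'
#' Primary key: combined MHC identity (mean -- or min -- of the alpha- and
#' beta-chain global-alignment identities against the target sequences),
#' best first. Templates tied on the primary key within `identity_tol` are
#' ordered by core-anchored peptide alignment score (descending); remaining
#' ties break deterministically by resolution (ascending, missing last) and
#' then template id.
#'
#' @param alpha_seq,beta_seq Target MHC chain sequences.
#' @param target_pep Target peptide sequence.
#' @param target_core `binding_core` of the target peptide.
#' @param templates List of `template_record`.
#' @param matrix Peptide-scoring substitution matrix (PAM30).
#' @param identity_agg `"mean"` (default) or `"min"` aggregation of the two
#'   chain identities.
#' @param identity_tol Identity tie tolerance in percentage points.
#' @param exclude_ids Template ids to leave out (e.g. the target itself in a
#'   leave-one-out benchmark).
#' @return A tibble of class `pmhc_ranking`: `template_id`,
#'   `alpha_identity_pct`, `beta_identity_pct`, `combined_identity`,
#'   `peptide_score`, `resolution`, sorted best first.
#' @export
rank_templates <- function(alpha_seq, beta_seq, target_pep, target_core,
                           templates,
                           matrix = substitution_matrix("PAM30"),
                           identity_agg = c("mean", "min"),
                           identity_tol = 0, exclude_ids = NULL) {
  identity_agg <- match.arg(identity_agg)
  if (!is.null(exclude_ids)) {
    templates <- purrr::keep(templates, ~ !(.x$id %in% exclude_ids))
  }
  # templates without a structural core (peptides < 9 residues) cannot be
  # core-aligned and are never selected
  templates <- purrr::keep(templates, ~ !is.null(.x$core))
  if (length(templates) == 0L) {
    abort_pmhc("template set is empty (after exclusions)", "pmhc_selection_error")
  }
  rows <- purrr::map(templates, function(tr) {
    cx <- tr$complex
    ai <- sequence_identity(alpha_seq, chain_sequence(cx, "M"))
    bi <- sequence_identity(beta_seq, chain_sequence(cx, "N"))
    comb <- if (identity_agg == "mean") (ai + bi) / 2 else min(ai, bi)
    pal <- align_peptide_to_template(target_pep, target_core,
                                     cx$peptide_seq, tr$core, matrix)
    tibble(template_id = tr$id,
           alpha_identity_pct = ai, beta_identity_pct = bi,
           combined_identity = comb, peptide_score = pal$score,
           resolution = cx$resolution)
  })
  tb <- bind_rows(rows)
  tb <- tb[order(-tb$combined_identity), ]
  # group rows whose combined identity ties the group leader within tolerance
  grp <- integer(nrow(tb))
  g <- 0L
  lead <- -Inf
  for (i in seq_len(nrow(tb))) {
    if (tb$combined_identity[i] < lead - identity_tol) {
      g <- g + 1L
      lead <- tb$combined_identity[i]
    } else if (i == 1L) {
      lead <- tb$combined_identity[i]
    }
    grp[i] <- g
  }
  res_key <- ifelse(is.na(tb$resolution), Inf, tb$resolution)
  tb <- tb[order(grp, -tb$peptide_score, res_key, tb$template_id), ]
  class(tb) <- c("pmhc_ranking", class(tb))
  tb
}

#' Select the modelling template
#'
#' Returns the highest-ranking template under [rank_templates()]; the full
#' ranking is attached as attribute `"ranking"`.
#'
#' @inheritParams rank_templates
#' @return The selected `template_record` with attribute `ranking`.
#' @export
select_template <- function(alpha_seq, beta_seq, target_pep, target_core,
                            templates,
                            matrix = substitution_matrix("PAM30"),
                            identity_agg = c("mean", "min"),
                            identity_tol = 0, exclude_ids = NULL) {
  ranking <- rank_templates(alpha_seq, beta_seq, target_pep, target_core,
                            templates, matrix, identity_agg, identity_tol,
                            exclude_ids)
  best_id <- ranking$template_id[1]
  tr <- purrr::detect(templates, ~ .x$id == best_id)
  attr(tr, "ranking") <- ranking
  tr
}

#' Export a template ranking as TSV
#'
#' @param ranking A `pmhc_ranking`.
#' @param path Output file.
#' @param selected_id Id flagged as selected (default: the top entry).
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path,
                              selected_id = ranking$template_id[1]) {
  df <- as.data.frame(ranking)
  df$selected <- df$template_id == selected_id
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
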