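# High-level modelling pipeline: resolve target sequences, pick the binding
# core, select a template, derive anchor restraints, and generate the ranked
# conformer ensemble.

resolve_chain_seq <- function(seq, allele, templates, reference, which) {
  if (!is.null(seq)) {
    check_aa_string(seq, sprintf("%s sequence", which))
    return(seq)
  }
  if (is.null(allele)) {
    abort_pmhc(sprintf("provide either a sequence or an allele name for the %s chain",
                       which),
               "pmhc_config_error")
  }
  if (!is.null(reference)) {
    ref <- as_sequence_records(reference)
    hit <- ref$seq[ref$id == allele]
    if (length(hit) == 1L) return(hit)
  }
  slot <- if (which == "alpha") "alpha_allele" else "beta_allele"
  chain <- if (which == "alpha") "M" else "N"
  for (tr in templates) {
    if (identical(tr$complex[[slot]], allele)) {
      return(chain_sequence(tr$complex, chain))
    }
  }
  abort_pmhc(sprintf("allele '%s' not found in the reference set or template database",
                     allele),
             "pmhc_config_error")
}

#' Model a peptide-MHC class II complex
#'
#' End-to-end pipeline: resolves the target MHC chain sequences (from raw
#' sequences, or from allele names looked up in a reference set or the
#' template database), determines the 9-mer binding core (user anchors, a
#' pluggable predictor, or the built-in fallback), selects the best template
#' by MHC identity and core-anchored PAM30 peptide score, derives anchor
#' distance restraints from the template contacts, and generates a ranked
#' conformer ensemble.
#'
#' @param templates Template set: a list of `template_record` or a database
#'   directory (read with [read_template_db()]).
#' @param peptide Target peptide sequence (7-25 residues).
#' @param alpha_seq,beta_seq Target chain sequences (optional if alleles
#'   given).
#' @param alpha_allele,beta_allele Allele names used for sequence lookup.
#' @param anchors Optional four 1-based anchor positions (P1/P4/P6/P9).
#' @param core_predictor Optional `(peptide, alpha_allele, beta_allele) ->
#'   binding_core` function (see [core_predictor_external()]).
#' @param reference Optional reference allele set (tibble `id`, `seq`).
#' @param mode,sd,n_models,seed Modelling-job parameters (see
#'   [modelling_job()]).
#' @param exclude_ids Template ids excluded from selection.
#' @param contact_cutoff Anchor contact cutoff for restraint derivation, A.
#' @param max_steps Refinement budget per model.
#' @return A `pmhc_ensemble`; attributes `"template"`, `"ranking"`,
#'   `"restraints"` and `"core"` record the pipeline stages.
#' @export
model_pmhc2 <- function(templates, peptide,
                        alpha_seq = NULL, beta_seq = NULL,
                        alpha_allele = NULL, beta_allele = NULL,
                        anchors = NULL, core_predictor = NULL,
                        reference = NULL,
                        mode = c("fixed_core", "flex_core"), sd = 0,
                        n_models = 20, seed = 1, exclude_ids = NULL,
                        contact_cutoff = 5.0, max_steps = 200) {
  mode <- match.arg(mode)
  if (is.character(templates) && length(templates) == 1L) {
    templates <- read_template_db(templates)
  }
  check_aa_string(peptide, "peptide")
  a_seq <- resolve_chain_seq(alpha_seq, alpha_allele, templates, reference, "alpha")
  b_seq <- resolve_chain_seq(beta_seq, beta_allele, templates, reference, "beta")
  core <- if (!is.null(anchors)) {
    core_from_user_anchors(peptide, anchors)
  } else if (!is.null(core_predictor)) {
    core_predictor(peptide, alpha_allele %||% "", beta_allele %||% "")
  } else {
    predict_core_fallback(peptide)
  }
  sel <- select_template(a_seq, b_seq, peptide, core, templates,
                         exclude_ids = exclude_ids)
  job <- modelling_job(a_seq, b_seq, peptide, core, sel, mode = mode,
                       sd = sd, n_models = n_models, seed = seed)
  restraints <- derive_restraints(sel, job$correspondence,
                                  contact_cutoff = contact_cutoff, sd = sd)
  ens <- generate_ensemble(job, restraints, max_steps = max_steps)
  attr(ens, "template") <- sel$id
  attr(ens, "ranking") <- attr(sel, "ranking")
  attr(ens, "restraints") <- restraints
  attr(ens, "core") <- core
  ens
}
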