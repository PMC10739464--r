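# Backbone ligand-RMSD (L-RMSD) metrics and the leave-one-out benchmark
# harness. Model and reference are first superposed on the receptor backbone
# (chains M + N); the peptide is then compared without re-fitting, following
# CAPRI-style ligand-RMSD practice. All RMSDs use the backbone atoms
# N, CA, C and O only.

#' Superpose a model onto a reference using the receptor frame
#'
#' Least-squares fit computed on the receptor (chains M and N) backbone
#' atoms only; the resulting rigid transform is applied to the whole model.
#' The reference is untouched.
#'
#' @param model,reference `pmhc_complex` objects sharing chain naming and
#'   receptor residue numbering.
#' @param on_mismatch `"error"` (default) raises a correspondence error
#'   listing the missing residues; `"intersect"` fits on the shared residues.
#' @param groove_only Restrict the fit to the first 80 residues of each
#'   receptor chain (an alpha1/beta1 groove-domain proxy) instead of the full
#'   receptor backbone.
#' @return The transformed model; attribute `"receptor_rmsd"` carries the
#'   post-fit receptor backbone RMSD.
#' @export
receptor_superpose <- function(model, reference,
                               on_mismatch = c("error", "intersect"),
                               groove_only = FALSE) {
  on_mismatch <- match.arg(on_mismatch)
  key <- function(cx) {
    a <- cx$atoms
    a <- a[a$chain %in% c("M", "N") & a$atom %in% BACKBONE_ATOMS, ]
    if (groove_only) a <- a[a$resno <= 80, ]
    a$k <- paste(a$chain, a$resno, a$atom)
    a
  }
  am <- key(model)
  ar <- key(reference)
  shared <- intersect(am$k, ar$k)
  missing <- union(setdiff(am$k, ar$k), setdiff(ar$k, am$k))
  if (length(missing) > 0L && on_mismatch == "error") {
    abort_pmhc(
      sprintf("receptor residue/atom mismatch between model and reference (%d unpaired, e.g. %s)",
              length(missing), paste(head(missing, 5), collapse = "; ")),
      "pmhc_correspondence_error")
  }
  if (length(shared) < 12L) {
    abort_pmhc("fewer than 12 shared receptor backbone atoms; cannot superpose",
               "pmhc_correspondence_error")
  }
  P <- as.matrix(am[match(shared, am$k), c("x", "y", "z")])
  Q <- as.matrix(ar[match(shared, ar$k), c("x", "y", "z")])
  fit <- kabsch_fit(P, Q)
  out <- model
  xyz <- as.matrix(out$atoms[, c("x", "y", "z")])
  xyz <- apply_rigid(xyz, fit)
  out$atoms$x <- xyz[, 1]
  out$atoms$y <- xyz[, 2]
  out$atoms$z <- xyz[, 3]
  attr(out, "receptor_rmsd") <- fit$rmsd
  out
}

#' Backbone L-RMSD report (core / flanking / whole)
#'
#' RMSD over the peptide backbone atoms (N, CA, C, O), with no re-fitting on
#' the peptide: apply [receptor_superpose()] first. The core metric covers
#' the 9 core residues; the flanking metric covers the residues N-terminal
#' of the first anchor and C-terminal of the fourth anchor (the anchors
#' themselves belong to the core); the whole metric covers all peptide
#' residues. With no flank residues the flanking value is `NA`, not 0.
#'
#' @param model,reference `pmhc_complex` objects with equal-length peptides,
#'   already in a common receptor frame.
#' @param core The `binding_core` (valid for both peptides).
#' @return One-row tibble of class `rmsd_report`: `core`, `flanking`,
#'   `whole` (Angstrom), `n_core_atoms`, `n_flank_atoms`.
#' @export
lrmsd <- function(model, reference, core) {
  Lm <- nchar(model$peptide_seq)
  Lr <- nchar(reference$peptide_seq)
  if (Lm != Lr) {
    abort_pmhc(sprintf("peptide length mismatch: model %d vs reference %d", Lm, Lr),
               "pmhc_evaluation_error")
  }
  stopifnot(inherits(core, "binding_core"))
  pick <- function(cx) {
    a <- cx$atoms
    a <- a[a$chain == "P" & a$atom %in% BACKBONE_ATOMS, ]
    a$k <- paste(a$resno, a$atom)
    a
  }
  am <- pick(model)
  ar <- pick(reference)
  shared <- intersect(am$k, ar$k)
  missing <- union(setdiff(am$k, ar$k), setdiff(ar$k, am$k))
  if (length(missing) > 0L) {
    abort_pmhc(sprintf("unpaired peptide backbone atom(s): %s",
                       paste(head(missing, 8), collapse = "; ")),
               "pmhc_evaluation_error")
  }
  M <- as.matrix(am[match(shared, am$k), c("x", "y", "z")])
  Rf <- as.matrix(ar[match(shared, ar$k), c("x", "y", "z")])
  resno <- am$resno[match(shared, am$k)]
  d2 <- rowSums((M - Rf)^2)
  core_res <- core_residues(core)
  in_core <- resno %in% core_res
  rms <- function(v) if (length(v)) sqrt(mean(v)) else NA_real_
  structure(
    tibble(core = rms(d2[in_core]),
           flanking = rms(d2[!in_core]),
           whole = rms(d2),
           n_core_atoms = sum(in_core),
           n_flank_atoms = sum(!in_core)),
    class = c("rmsd_report", class(tibble())))
}

#' Evaluate every model of an ensemble against a reference structure
#'
#' Superposes each model on the reference receptor and reports core /
#' flanking / whole backbone L-RMSD alongside the ensemble ranking.
#'
#' @param ensemble A `pmhc_ensemble`.
#' @param reference The experimental `pmhc_complex`.
#' @param core `binding_core` used for the region split (defaults to the
#'   modelling core of the ensemble's job).
#' @param on_mismatch Passed to [receptor_superpose()].
#' @return Tibble: ensemble table columns plus `core`, `flanking`, `whole`.
#' @export
evaluate_ensemble <- function(ensemble, reference, core = ensemble$job$core,
                              on_mismatch = "error") {
  stopifnot(inherits(ensemble, "pmhc_ensemble"))
  rows <- purrr::imap(ensemble$models, function(m, i) {
    base <- ensemble$table[i, ]
    if (is.null(m)) return(base)
    fitted <- receptor_superpose(m, reference, on_mismatch = on_mismatch)
    rep <- lrmsd(fitted, reference, core)
    dplyr::bind_cols(base, rep[, c("core", "flanking", "whole")])
  })
  bind_rows(rows)
}

#' Top-k success rate
#'
#' Fraction of benchmark cases whose best (minimum) whole-peptide L-RMSD
#' among the top `k` ranked models is below `threshold`.
#'
#' @param per_case Per-case tibble from [run_benchmark()] (uses the
#'   `topk_whole` column, which already encodes the minimum over the top-k
#'   ranked models) or any tibble with a `topk_whole` column.
#' @param threshold L-RMSD threshold in Angstrom (default 2).
#' @return A fraction in `[0, 1]`; failed cases count as misses.
#' @export
success_rate <- function(per_case, threshold = 2) {
  ok <- !is.na(per_case$topk_whole) & per_case$topk_whole < threshold
  mean(ok)
}

#' Leave-one-out modelling benchmark
#'
#' For each template-set entry: remove it from the set (when `leave_one_out`),
#' select a template for its sequences, model an ensemble, and evaluate every
#' model against the experimental structure. Records, per case, the
#' best-sampled metrics (minimum over the whole ensemble) and the top-k
#' ranked metrics (minimum over the `top_k` best-ranked models), plus
#' aggregate median / mean / sd per metric. With `oracle_anchors` the target
#' binding core is taken from the target structure itself, isolating
#' modelling quality from core-prediction quality.
#'
#' @param templates List of `template_record` (the template set).
#' @param leave_one_out Exclude each case's own entry during template
#'   selection (default TRUE).
#' @param top_k Ranked-model depth for the success metrics (default 5).
#' @param threshold Success threshold in Angstrom (default 2).
#' @param mode,sd,n_models,seed Passed to the modelling job.
#' @param oracle_anchors Use each target's structural core (default TRUE);
#'   otherwise `predictor` (or the built-in fallback) predicts the core.
#' @param predictor Optional core predictor `(peptide, alpha_allele,
#'   beta_allele) -> binding_core`.
#' @param max_steps Refinement budget per model.
#' @param on_mismatch Receptor-correspondence policy during evaluation
#'   (default `"intersect"`: a cross-length template contributes a receptor
#'   whose groove-floor segment is shorter or longer than the reference's,
#'   so the fit uses the shared receptor residues).
#' @return A `pmhc_benchmark`: list with `per_case`, `aggregates`, `options`.
#' @export
run_benchmark <- function(templates, leave_one_out = TRUE, top_k = 5,
                          threshold = 2, mode = "fixed_core", sd = 0,
                          n_models = 20, seed = 1, oracle_anchors = TRUE,
                          predictor = NULL, max_steps = 200,
                          on_mismatch = "intersect") {
  if (leave_one_out && length(templates) < 2L) {
    abort_pmhc("leave-one-out benchmarking needs at least 2 templates",
               "pmhc_precondition_error")
  }
  rows <- purrr::map(templates, function(tr) {
    target <- tr$complex
    case_id <- tr$id
    res <- tryCatch({
      core <- if (oracle_anchors) {
        tr$core
      } else if (!is.null(predictor)) {
        predictor(target$peptide_seq, target$alpha_allele, target$beta_allele)
      } else {
        predict_core_fallback(target$peptide_seq)
      }
      sel <- select_template(
        chain_sequence(target, "M"), chain_sequence(target, "N"),
        target$peptide_seq, core, templates,
        exclude_ids = if (leave_one_out) case_id else NULL)
      job <- modelling_job(chain_sequence(target, "M"),
                           chain_sequence(target, "N"),
                           target$peptide_seq, core, sel,
                           mode = mode, sd = sd, n_models = n_models,
                           seed = seed)
      restraints <- derive_restraints(sel, job$correspondence, sd = sd)
      ens <- generate_ensemble(job, restraints, max_steps = max_steps)
      ev <- evaluate_ensemble(ens, target, core = core,
                              on_mismatch = on_mismatch)
      okv <- ev[!ev$failed, ]
      topk <- okv[okv$rank <= top_k, ]
      tibble(
        case_id = case_id, peptide_length = nchar(target$peptide_seq),
        template_id = sel$id,
        best_core = min(okv$core), best_flanking = suppressWarnings(min(okv$flanking)),
        best_whole = min(okv$whole),
        topk_core = min(topk$core), topk_flanking = suppressWarnings(min(topk$flanking)),
        topk_whole = min(topk$whole),
        n_models_ok = nrow(okv), failed = FALSE, error = NA_character_)
    }, error = function(e) {
      tibble(case_id = case_id, peptide_length = nchar(target$peptide_seq),
             template_id = NA_character_,
             best_core = NA_real_, best_flanking = NA_real_, best_whole = NA_real_,
             topk_core = NA_real_, topk_flanking = NA_real_, topk_whole = NA_real_,
             n_models_ok = 0L, failed = TRUE, error = conditionMessage(e))
    })
    res
  })
  per_case <- bind_rows(rows)
  okc <- per_case[!per_case$failed, ]
  agg <- purrr::map(c("best_core", "best_flanking", "best_whole",
                      "topk_core", "topk_flanking", "topk_whole"),
                    function(m) {
    v <- okc[[m]]
    v <- v[is.finite(v)]
    tibble(metric = m, median = median(v), mean = mean(v), sd = sd(v),
           n = length(v))
  })
  structure(
    list(per_case = per_case, aggregates = bind_rows(agg),
         options = list(leave_one_out = leave_one_out, top_k = top_k,
                        threshold = threshold, mode = mode, sd = sd,
                        n_models = n_models, seed = seed,
                        oracle_anchors = oracle_anchors),
         n_failed = sum(per_case$failed)),
    class = "pmhc_benchmark")
}

#' @export
print.pmhc_benchmark <- function(x, ...) {
  cat(sprintf("<pmhc_benchmark> %d cases (%d failed), %s, top-%d success (< %.1f A): %.1f%%\n",
              nrow(x$per_case), x$n_failed, x$options$mode, x$options$top_k,
              x$options$threshold,
              100 * success_rate(x$per_case, x$options$threshold)))
  agg <- x$aggregates
  best <- agg[agg$metric %in% c("best_core", "best_whole"), ]
  cat(sprintf("  best-sampled median: core %.2f A, whole %.2f A\n",
              best$median[best$metric == "best_core"],
              best$median[best$metric == "best_whole"]))
  invisible(x)
}

#' Write benchmark outputs
#'
#' Per-case TSV, a summary JSON (aggregates + success rate), and a
#' per-length long-format CSV for plotting.
#'
#' @param benchmark A `pmhc_benchmark`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(as.data.frame(benchmark$per_case), file.path(dir, "per_case.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(
    n_cases = nrow(benchmark$per_case),
    n_failed = benchmark$n_failed,
    success_rate = success_rate(benchmark$per_case,
                                benchmark$options$threshold),
    threshold = benchmark$options$threshold,
    top_k = benchmark$options$top_k,
    aggregates = benchmark$aggregates)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  long <- tidyr::pivot_longer(
    benchmark$per_case[!benchmark$per_case$failed,
                       c("case_id", "peptide_length", "best_core", "best_whole")],
    cols = c("best_core", "best_whole"),
    names_to = "metric", values_to = "lrmsd")
  utils::write.csv(as.data.frame(long), file.path(dir, "per_length.csv"),
                   row.names = FALSE)
  invisible(dir)
}
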