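# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a conformer ensemble
#'
#' @param x A `pmhc_ensemble`.
#' @param ... Unused.
#' @return The per-model tibble (rank, seed, pseudo-energy and its terms).
#' @method tidy pmhc_ensemble
#' @export
tidy.pmhc_ensemble <- function(x, ...) {
  x$table[order(x$table$rank, na.last = TRUE), ]
}

#' One-row ensemble summary
#'
#' @param x A `pmhc_ensemble`.
#' @param ... Unused.
#' @return Tibble: models, failures, best/median pseudo-energy, template id.
#' @method glance pmhc_ensemble
#' @export
glance.pmhc_ensemble <- function(x, ...) {
  ok <- x$table[!x$table$failed, ]
  tibble(n_models = nrow(x$table), n_failed = sum(x$table$failed),
         best_pseudo_energy = if (nrow(ok)) min(ok$pseudo_energy) else NA_real_,
         median_pseudo_energy = if (nrow(ok)) median(ok$pseudo_energy) else NA_real_,
         template_id = attr(x, "template") %||% x$job$template$id,
         mode = x$job$mode, peptide = x$job$peptide)
}

#' Tidy a benchmark
#'
#' @param x A `pmhc_benchmark`.
#' @param ... Unused.
#' @return The per-case tibble.
#' @method tidy pmhc_benchmark
#' @export
tidy.pmhc_benchmark <- function(x, ...) x$per_case

#' One-row benchmark summary
#'
#' @param x A `pmhc_benchmark`.
#' @param ... Unused.
#' @return Tibble with case counts, per-metric medians/means and the top-k
#'   success rate at the benchmark threshold.
#' @method glance pmhc_benchmark
#' @export
glance.pmhc_benchmark <- function(x, ...) {
  g <- function(metric, stat) {
    row <- x$aggregates[x$aggregates$metric == metric, ]
    if (nrow(row)) row[[stat]] else NA_real_
  }
  tibble(n_cases = nrow(x$per_case), n_failed = x$n_failed,
         median_best_core = g("best_core", "median"),
         median_best_whole = g("best_whole", "median"),
         mean_best_whole = g("best_whole", "mean"),
         sd_best_whole = g("best_whole", "sd"),
         success_rate = success_rate(x$per_case, x$options$threshold),
         threshold = x$options$threshold, top_k = x$options$top_k)
}

#' Plot an ensemble's pseudo-energy ranking
#'
#' @param object A `pmhc_ensemble`.
#' @param ... Unused.
#' @return A ggplot: pseudo-energy (and its terms) versus rank.
#' @method autoplot pmhc_ensemble
#' @export
autoplot.pmhc_ensemble <- function(object, ...) {
  tb <- object$table[!object$table$failed, ]
  long <- tidyr::pivot_longer(
    tb[, c("rank", "pseudo_energy", "bonded", "clash", "restraint")],
    cols = c("pseudo_energy", "bonded", "clash", "restraint"),
    names_to = "term", values_to = "energy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$energy,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "rank", y = "pseudo-energy",
                  title = "Conformer ensemble ranking") +
    ggplot2::theme_minimal()
}

#' Plot benchmark L-RMSD per case, grouped by peptide length
#'
#' @param object A `pmhc_benchmark`.
#' @param metric `"best"` (best-sampled) or `"topk"` (top-ranked).
#' @param ... Unused.
#' @return A ggplot: core and whole backbone L-RMSD bars per case.
#' @method autoplot pmhc_benchmark
#' @export
autoplot.pmhc_benchmark <- function(object, metric = c("best", "topk"), ...) {
  metric <- match.arg(metric)
  pc <- object$per_case[!object$per_case$failed, ]
  cols <- paste0(metric, c("_core", "_whole"))
  long <- tidyr::pivot_longer(
    pc[, c("case_id", "peptide_length", cols)],
    cols = dplyr::all_of(cols), names_to = "region", values_to = "lrmsd")
  long$region <- sub(paste0(metric, "_"), "", long$region)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$case_id,
                                                  .data$peptide_length),
                               y = .data$lrmsd, fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$options$threshold,
                        linetype = "dashed") +
    ggplot2::facet_grid(~ .data$peptide_length, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "case (grouped by peptide length)",
                  y = "backbone L-RMSD (Å)",
                  title = sprintf("%s-model backbone L-RMSD",
                                  if (metric == "best") "Best-sampled"
                                  else "Top-ranked")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
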