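#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-candidate GRNIC table
#'
#' @param x a `grnic_result` from [grnic_scores()].
#' @param ... unused.
#' @return tibble with one row per candidate: `index`, `link_count`,
#'   `sparsity`, `k_raw`, `k_norm`, `fit_error_raw`, `l_norm`, `grnic`,
#'   `degenerate`, `selected`.
#' @export
tidy.grnic_result <- function(x, ...) {
  dplyr::mutate(x$table, selected = .data$index == x$selected_index)
}

#' One-row summary of a GRNIC selection
#'
#' @inheritParams tidy.grnic_result
#' @return one-row tibble: candidate count and the selected candidate's
#'   index, link count, sparsity and GRNIC value.
#' @export
glance.grnic_result <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$table),
    n_genes = x$n_genes,
    method = x$method,
    selected_index = x$selected_index,
    selected_link_count = x$selected_link_count,
    selected_sparsity = x$selected_sparsity,
    selected_grnic = x$table$grnic[x$selected_index])
}

#' Tidy the per-candidate evaluation table
#'
#' @param x a `grn_eval` from [evaluate_sweep()].
#' @param ... unused.
#' @return tibble with one row per candidate: confusion counts, precision,
#'   recall and F1.
#' @export
tidy.grn_eval <- function(x, ...) {
  x$table
}

#' One-row summary of a sweep evaluation
#'
#' @inheritParams tidy.grn_eval
#' @return one-row tibble with max/selected F1 and the three sparsities
#'   (true, selected, max-F1), in links per gene.
#' @export
glance.grn_eval <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$table),
    n_genes = x$n_genes,
    method = x$method,
    max_f1 = x$max_f1,
    selected_f1 = x$selected_f1,
    sparsity_true = x$sparsity_true,
    sparsity_selected = x$sparsity_selected,
    sparsity_max_f1 = x$sparsity_max_f1)
}

#' Plot GRNIC and its two terms across a sparsity sweep
#'
#' Draws `k_norm`, `l_norm` and their sum `grnic` against sparsity
#' (links per gene), with a vertical line at the selected candidate.
#'
#' @param object a `grnic_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.grnic_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$table[, c("sparsity", "k_norm", "l_norm", "grnic")],
    cols = c("k_norm", "l_norm", "grnic"),
    names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$sparsity, .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_sparsity,
                        linetype = "dashed") +
    ggplot2::labs(x = "sparsity (links per gene)", y = NULL,
                  colour = NULL,
                  title = "GRN information criterion across the sweep",
                  subtitle = sprintf("selected: %.2f links/gene",
                                     object$selected_sparsity)) +
    ggplot2::theme_minimal()
}

#' Plot F1 across a sparsity sweep
#'
#' F1-score against sparsity with the true sparsity (dotted), the
#' maximum-F1 candidate (solid) and, when present, the GRNIC-selected
#' candidate (dashed) marked by vertical lines.
#'
#' @param object a `grn_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.grn_eval <- function(object, ...) {
  p <- ggplot2::ggplot(object$table,
                       ggplot2::aes(.data$sparsity, .data$f1)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$sparsity_true,
                        linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$sparsity_max_f1) +
    ggplot2::labs(x = "sparsity (links per gene)", y = "F1-score",
                  title = "Edge-recovery accuracy across the sweep") +
    ggplot2::theme_minimal()
  if (!is.na(object$sparsity_selected)) {
    p <- p + ggplot2::geom_vline(xintercept = object$sparsity_selected,
                                 linetype = "dashed")
  }
  p
}

#' @importFrom rlang .data
NULL
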