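#' Confusion counts between an estimated and a true network
#'
#' Edges are compared as directed (regulator, target) pairs on the
#' off-diagonal support of the weight matrices; weight sign and magnitude
#' are ignored, and self-loops never enter any count (accuracy is determined
#' solely by non-self-loops).
#'
#' @param estimate,truth square weight matrices on the same gene set.
#' @return named integer vector `c(tp, fp, fn)`.
#' @export
confusion <- function(estimate, truth) {
  estimate <- as_network_matrix(estimate, "estimate")
  truth <- as_network_matrix(truth, "truth")
  check_same_genes(estimate, truth, "estimate", "truth")
  e <- estimate != 0; diag(e) <- FALSE
  t <- truth != 0; diag(t) <- FALSE
  c(tp = sum(e & t), fp = sum(e & !t), fn = sum(!e & t))
}

#' F1-score from confusion counts
#'
#' `2 tp / (2 tp + fp + fn)`; defined as 0 when `tp = 0` (where precision
#' would otherwise be undefined).
#'
#' @param tp,fp,fn nonnegative counts.
#' @return value in `[0, 1]`.
#' @export
f1_score <- function(tp, fp, fn) {
  ifelse(tp == 0, 0, 2 * tp / (2 * tp + fp + fn))
}

#' Evaluate a sparsity sweep against a gold-standard network
#'
#' Scores every candidate with directed, sign-blind edge confusion counts
#' and the F1-score, locates the maximum-F1 candidate, and reports the
#' sparsities (links per gene) of the truth, the maximum-F1 candidate and,
#' when a [grnic_scores()] result is supplied, the selected candidate.
#'
#' @param sweep a [grn_sweep()].
#' @param truth gold-standard weight matrix on the same gene set.
#' @param result optional `grnic_result` for the same sweep.
#' @return an object of class `grn_eval` with a per-candidate tibble and
#'   summary fields (`max_f1`, `selected_f1`, `sparsity_true`, ...).
#' @export
evaluate_sweep <- function(sweep, truth, result = NULL) {
  if (!inherits(sweep, "grn_sweep")) sweep <- grn_sweep(sweep)
  truth <- as_network_matrix(truth, "truth")
  if (nrow(truth) != length(sweep$genes)) {
    abort("truth and sweep are on different gene sets")
  }
  cm <- t(vapply(sweep$candidates, confusion, integer(3), truth = truth))
  tp <- cm[, "tp"]; fp <- cm[, "fp"]; fn <- cm[, "fn"]
  tab <- tibble::tibble(
    index = seq_len(nrow(cm)),
    link_count = sweep$link_counts,
    sparsity = sweep$link_counts / nrow(truth),
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    precision = ifelse(tp + fp == 0, 0, tp / (tp + fp)),
    recall = ifelse(tp + fn == 0, 0, tp / (tp + fn)),
    f1 = f1_score(tp, fp, fn))
  max_i <- which.max(tab$f1)
  sel_i <- if (is.null(result)) NA_integer_ else result$selected_index
  structure(
    list(
      table = tab,
      max_f1_index = max_i,
      max_f1 = tab$f1[max_i],
      selected_index = sel_i,
      selected_f1 = if (is.na(sel_i)) NA_real_ else tab$f1[sel_i],
      sparsity_true = network_sparsity(truth),
      sparsity_max_f1 = tab$sparsity[max_i],
      sparsity_selected = if (is.na(sel_i)) NA_real_ else tab$sparsity[sel_i],
      n_genes = nrow(truth),
      method = sweep$method),
    class = "grn_eval")
}

#' @export
#' @method print grn_eval
print.grn_eval <- function(x, ...) {
  cat(sprintf("<grn_eval> %d candidates over %d genes (%s)\n",
              nrow(x$table), x$n_genes,
              if (is.na(x$method)) "unlabeled" else x$method))
  cat(sprintf("  truth: %.2f links/gene | max F1 = %.3f at %.2f links/gene\n",
              x$sparsity_true, x$max_f1, x$sparsity_max_f1))
  if (!is.na(x$selected_index)) {
    cat(sprintf("  selected: F1 = %.3f at %.2f links/gene\n",
                x$selected_f1, x$sparsity_selected))
  }
  invisible(x)
}
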