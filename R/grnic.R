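#' Predict expression from a candidate network via a safeguarded pseudoinverse
#'
#' Reconstructs the steady-state log2 fold-change response of a candidate
#' network `A` to the perturbation design `P` as `Yhat = -A^dagger P`, where
#' `A^dagger` is the Moore-Penrose pseudoinverse computed by singular value
#' decomposition. Because candidate networks from a sparsity sweep are often
#' rank-deficient, singular values below a safeguard threshold `1 / max(Y)`
#' (taken from the measured expression matrix) are zeroed before inversion.
#'
#' "max(Y)" admits several readings. The default (`threshold_mode =
#' "sigma_max"`) takes the largest singular value of the measured matrix,
#' so the cutoff is `1 / sigma_max(Y)`. Because any candidate fitted to the
#' steady-state relation `A Y = -P` has singular values of order
#' `1 / sigma(Y)` and above, this cutoff sits just below the candidate's
#' spectrum and triggers only on genuinely unstable inversions — the guard
#' is almost never active, which is its stated purpose. The entrywise
#' readings are available as `"max_abs"` (maximum absolute entry; for
#' steady-state fold-change data this lands in the middle of the candidate
#' spectrum and distorts predictions badly) and `"max"` (plain maximum
#' entry, undefined for all-negative matrices).
#'
#' @param candidate square weight matrix of the candidate network.
#' @param design perturbation design matrix.
#' @param measured measured expression matrix supplying the safeguard scale;
#'   may be omitted when `sv_threshold` is given explicitly.
#' @param sv_threshold explicit singular-value cutoff overriding the
#'   `1 / max(Y)` rule (0 disables the safeguard).
#' @param threshold_mode `"sigma_max"` (default), `"max_abs"` or `"max"`.
#' @return predicted expression matrix, genes x experiments. If every
#'   singular value falls below the threshold the prediction is all zeros
#'   and carries attribute `degenerate = TRUE`.
#' @export
predict_expression <- function(candidate, design, measured = NULL,
                               sv_threshold = NULL,
                               threshold_mode = c("sigma_max", "max_abs", "max")) {
  candidate <- as_network_matrix(candidate, "candidate")
  check_same_genes(candidate, design, "candidate", "design")
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(sv_threshold)) {
    if (is.null(measured)) {
      abort("supply `measured` (for the 1/max(Y) safeguard) or an explicit `sv_threshold`")
    }
    scale <- switch(threshold_mode,
                    sigma_max = svd(measured, nu = 0, nv = 0)$d[1],
                    max_abs = max(abs(measured)),
                    max = max(measured))
    if (!is.finite(scale) || scale <= 0) {
      abort("measured expression gives a non-positive safeguard scale; pass `sv_threshold`")
    }
    sv_threshold <- 1 / scale
  }

  s <- svd(candidate)
  # the relative slack keeps singular values sitting exactly at the cutoff
  # (round-off from the svd) on the retained side
  keep <- s$d >= sv_threshold * (1 - 1e-8)
  if (!any(keep)) {
    yhat <- matrix(0, nrow(candidate), ncol(design),
                   dimnames = list(rownames(candidate), colnames(design)))
    return(structure(yhat, degenerate = TRUE))
  }
  pinv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  yhat <- -pinv %*% design
  dimnames(yhat) <- list(rownames(candidate), colnames(design))
  yhat
}

#' Regulator-count penalty K
#'
#' The number of genes that regulate at least one other gene: columns of the
#' weight matrix with at least one nonzero off-diagonal entry. A gene whose
#' only outgoing edge is its own self-loop does not count.
#'
#' @param candidate square weight matrix.
#' @return nonnegative integer.
#' @export
penalty_K <- function(candidate) {
  candidate <- as_network_matrix(candidate, "candidate")
  m <- candidate != 0
  diag(m) <- FALSE
  sum(colSums(m) > 0)
}

#' Badness of fit between predicted and measured expression
#'
#' Predicted expression from a pseudoinverse can differ from the measured
#' matrix by orders of magnitude, so both matrices are first brought to the
#' same range by dividing each by its own maximum absolute entry (an
#' all-zero matrix is left as is); the badness of fit is then the
#' root-mean-square of the elementwise differences. Across a sweep this raw
#' value is transformed and normalized by [grnic_scores()].
#'
#' @param predicted,measured equal-shaped expression matrices.
#' @return nonnegative scalar; 0 iff the scaled matrices are identical.
#' @export
badness_of_fit <- function(predicted, measured) {
  if (!identical(dim(predicted), dim(measured))) {
    abort(sprintf("shape mismatch: predicted is %s, measured is %s",
                  paste(dim(predicted), collapse = "x"),
                  paste(dim(measured), collapse = "x")))
  }
  scale1 <- function(x) {
    m <- max(abs(x))
    if (m == 0) x else x / m
  }
  sqrt(mean((scale1(predicted) - scale1(measured))^2))
}

#' Score a sparsity sweep with the GRN Information Criterion
#'
#' For every candidate network the criterion `GRNIC = K + L` balances a
#' penalty `K` against a badness of fit `L`:
#' * `k_raw`: the number of regulator genes ([penalty_K()]);
#' * `fit_error_raw`: the badness of fit of the candidate's reconstructed
#'   expression `-A^dagger P` against the measured matrix
#'   ([predict_expression()], [badness_of_fit()]).
#'
#' The two terms are made commensurate across the sweep: the raw fit errors
#' are min-max scaled to `[0, 1]`, exponentiated (`e` to the badness of fit,
#' mirroring the log-likelihood term of AIC with opposite sign), and min-max
#' normalized again, giving `l_norm`; the raw penalties are min-max
#' normalized to `k_norm`. Then `grnic = k_norm + l_norm` and the candidate
#' minimizing it is selected, ties going to the smaller link count. A term
#' that is constant across the sweep (including the single-candidate case)
#' normalizes to all zeros.
#'
#' @param sweep a [grn_sweep()].
#' @param design perturbation design matrix.
#' @param measured measured expression matrix.
#' @param sv_threshold,threshold_mode passed to [predict_expression()].
#' @return an object of class `grnic_result`: per-candidate table plus the
#'   selected index and sparsity. See [tidy.grnic_result()],
#'   [glance.grnic_result()], [autoplot.grnic_result()].
#' @export
grnic_scores <- function(sweep, design, measured,
                         sv_threshold = NULL,
                         threshold_mode = c("sigma_max", "max_abs", "max")) {
  if (!inherits(sweep, "grn_sweep")) {
    sweep <- grn_sweep(sweep)
  }
  threshold_mode <- match.arg(threshold_mode)
  check_same_genes(measured, design, "expression", "design")
  if (!identical(dim(measured), dim(design))) {
    abort("measured expression and design must have the same shape")
  }
  if (nrow(measured) != length(sweep$genes)) {
    abort("sweep candidates and expression data are on different gene sets")
  }

  k_raw <- vapply(sweep$candidates, penalty_K, numeric(1))
  preds <- lapply(sweep$candidates, predict_expression,
                  design = design, measured = measured,
                  sv_threshold = sv_threshold, threshold_mode = threshold_mode)
  degenerate <- vapply(preds, function(p) isTRUE(attr(p, "degenerate")), logical(1))
  e_raw <- vapply(preds, badness_of_fit, numeric(1), measured = measured)

  l_norm <- minmax(exp(minmax(e_raw)))
  k_norm <- minmax(k_raw)
  grnic <- k_norm + l_norm
  sel <- which.min(grnic) # sweep is ordered sparse -> dense, first min wins

  n <- length(sweep$genes)
  structure(
    list(
      table = tibble::tibble(
        index = seq_along(grnic),
        link_count = sweep$link_counts,
        sparsity = sweep$link_counts / n,
        k_raw = k_raw, k_norm = k_norm,
        fit_error_raw = e_raw, l_norm = l_norm,
        grnic = grnic, degenerate = degenerate),
      selected_index = sel,
      selected_link_count = sweep$link_counts[sel],
      selected_sparsity = sweep$link_counts[sel] / n,
      n_genes = n,
      method = sweep$method),
    class = "grnic_result")
}

#' @export
#' @method print grnic_result
print.grnic_result <- function(x, ...) {
  cat(sprintf("<grnic_result> %d candidates over %d genes (%s)\n",
              nrow(x$table), x$n_genes,
              if (is.na(x$method)) "unlabeled" else x$method))
  cat(sprintf("  selected: candidate %d, %d links (%.2f links/gene), GRNIC = %.4f\n",
              x$selected_index, x$selected_link_count, x$selected_sparsity,
              x$table$grnic[x$selected_index]))
  invisible(x)
}

#' Experiment-wise shuffle control for badness-of-fit curves
#'
#' Randomly permutes the gene values within each experiment (column)
#' independently, preserving each column's value multiset while destroying
#' the gene-to-gene structure. Used as a null control: badness-of-fit
#' curves computed from shuffled reconstructions lose the decreasing trend
#' with density that real reconstructions show.
#'
#' @param predicted expression matrix to shuffle.
#' @param seed optional integer seed.
#' @return matrix of the same shape with each column permuted.
#' @export
shuffle_control <- function(predicted, seed = NULL) {
  with_seed_opt(seed, {
    out <- apply(predicted, 2, function(col) col[sample.int(length(col))])
    out <- matrix(out, nrow(predicted), ncol(predicted),
                  dimnames = dimnames(predicted))
    out
  })
}
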