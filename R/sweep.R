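#' Sparsity sweep of candidate networks
#'
#' A sweep is an ordered family of candidate networks on one shared gene set
#' with strictly increasing non-self-loop link counts, typically spanning
#' 1-5 links per gene in single-link steps (401 candidates for 100 genes).
#'
#' @param candidates list of square weight matrices on the same gene set.
#' @param method optional backend label ("lasso", "ridge", "tree", ...).
#' @return an object of class `grn_sweep`: a list with elements
#'   `candidates`, `link_counts`, `genes`, `method`.
#' @export
grn_sweep <- function(candidates, method = NA_character_) {
  if (length(candidates) == 0) {
    abort("a sweep needs at least one candidate network")
  }
  candidates <- lapply(candidates, as_network_matrix, arg = "candidate")
  genes <- rownames(candidates[[1]])
  for (c in candidates) {
    if (!identical(rownames(c), genes)) {
      abort("all sweep candidates must share one gene set and order")
    }
  }
  lc <- vapply(candidates, link_count, integer(1))
  if (any(diff(lc) <= 0)) {
    abort("sweep link counts must be strictly increasing")
  }
  structure(
    list(candidates = candidates, link_counts = lc,
         genes = genes, method = method),
    class = "grn_sweep")
}

#' @export
length.grn_sweep <- function(x) length(x$candidates)

#' @export
#' @method print grn_sweep
print.grn_sweep <- function(x, ...) {
  n <- length(x$genes)
  cat(sprintf("<grn_sweep> %d candidates over %d genes (%s)\n",
              length(x), n,
              if (is.na(x$method)) "unlabeled" else x$method))
  cat(sprintf("  links: %d..%d (%.2f..%.2f links/gene)\n",
              min(x$link_counts), max(x$link_counts),
              min(x$link_counts) / n, max(x$link_counts) / n))
  invisible(x)
}

# Deterministic ranking of off-diagonal entries of `full`:
# |weight| descending, then regulator (column) index, then target (row)
# index ascending. Returns a data frame of candidate edges, strongest first.
rank_offdiag <- function(full) {
  n <- nrow(full)
  i <- rep(seq_len(n), n)        # target (row)
  j <- rep(seq_len(n), each = n) # regulator (column)
  keep <- i != j & full != 0
  w <- full[cbind(i[keep], j[keep])]
  ord <- order(-abs(w), j[keep], i[keep])
  data.frame(i = i[keep][ord], j = j[keep][ord], w = w[ord])
}

# Build the candidate with exactly the k strongest off-diagonal entries of
# `full` (deterministic tie-break), keeping full's diagonal.
keep_k <- function(full, k, ranked = rank_offdiag(full)) {
  out <- matrix(0, nrow(full), ncol(full), dimnames = dimnames(full))
  diag(out) <- diag(full)
  if (k > 0) {
    sel <- ranked[seq_len(k), , drop = FALSE]
    out[cbind(sel$i, sel$j)] <- sel$w
  }
  out
}

#' Extract a nested sparsity sweep from a full network by weight cutoffs
#'
#' Produces one candidate per integer link count from
#' `round(min_lpg * N)` to `round(max_lpg * N)`; the candidate with `k`
#' links contains exactly the `k` largest-|weight| off-diagonal entries of
#' `full` (ties broken deterministically by regulator then target index),
#' so consecutive candidates are nested. Diagonal entries of `full` are
#' carried into every candidate and never counted as links.
#'
#' @param full square weight matrix with at least `max_lpg * N` nonzero
#'   off-diagonal entries (fewer triggers a truncated sweep and a warning).
#' @param min_lpg,max_lpg sweep bounds in links per gene.
#' @param method backend label stored on the sweep.
#' @return a [grn_sweep()].
#' @export
extract_sweep <- function(full, min_lpg = 1, max_lpg = 5,
                          method = NA_character_) {
  full <- as_network_matrix(full)
  stopifnot(min_lpg <= max_lpg, min_lpg >= 0)
  n <- nrow(full)
  ks <- seq.int(round(min_lpg * n), round(max_lpg * n))
  ranked <- rank_offdiag(full)
  if (nrow(ranked) < max(ks)) {
    warn(sprintf(
      "network has only %d nonzero off-diagonal weights; sweep truncated at %d links",
      nrow(ranked), nrow(ranked)))
    ks <- ks[ks <= nrow(ranked)]
    if (length(ks) == 0) {
      abort("no sweep candidates possible: too few nonzero weights")
    }
  }
  grn_sweep(lapply(ks, keep_k, full = full, ranked = ranked), method = method)
}
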