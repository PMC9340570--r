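#' @importFrom rlang %||% abort warn inform
#' @importFrom stats rnorm runif var cor.test
#' @importFrom utils head
NULL

# Run `code` under a temporary RNG seed when one is given, otherwise use the
# session RNG as-is. All user-facing randomness funnels through here.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Min-max rescale to [0, 1]; a constant (or length-1) vector maps to all
# zeros, the degenerate rule used when a sweep term carries no contrast.
minmax <- function(x) {
  r <- range(x)
  if (!all(is.finite(r))) {
    abort("cannot normalize non-finite values")
  }
  if (r[1] == r[2]) {
    return(rep(0, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

default_genes <- function(n) {
  sprintf("G%0*d", max(3L, nchar(n)), seq_len(n))
}

as_network_matrix <- function(x, arg = "network") {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    abort(sprintf("%s must be a square matrix, got %d x %d", arg, nrow(x), ncol(x)))
  }
  if (!is.numeric(x)) {
    abort(sprintf("%s must be numeric", arg))
  }
  if (is.null(rownames(x))) {
    rownames(x) <- colnames(x) <- default_genes(nrow(x))
  }
  x
}

#' Count regulatory links in a network
#'
#' Links are nonzero off-diagonal entries of the weight matrix; self-loops
#' (diagonal entries) are never counted.
#'
#' @param net square numeric weight matrix, rows = targets, columns =
#'   regulators.
#' @return integer link count.
#' @export
link_count <- function(net) {
  net <- as_network_matrix(net)
  m <- net != 0
  diag(m) <- FALSE
  sum(m)
}

#' Network sparsity in links per gene
#'
#' @inheritParams link_count
#' @return non-self-loop links divided by the number of genes.
#' @export
network_sparsity <- function(net) {
  link_count(net) / nrow(as_network_matrix(net))
}

check_same_genes <- function(a, b, what_a = "first", what_b = "second") {
  if (!identical(dim(a), dim(b)) && nrow(a) != nrow(b)) {
    abort(sprintf("%s and %s have different gene counts (%d vs %d)",
                  what_a, what_b, nrow(a), nrow(b)))
  }
  ga <- rownames(a)
  gb <- rownames(b)
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb)) {
    abort(sprintf("%s and %s have mismatched gene labels", what_a, what_b))
  }
  invisible(TRUE)
}
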