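#' Generate a stable random gene regulatory network
#'
#' Draws a signed, weighted, directed network that mimics the topology
#' statistics of curated E. coli subnetworks used in steady-state GRN
#' benchmarks: only a fraction of genes (`tf_fraction`) act as regulators,
#' regulators are hub-heavy (preferential attachment on out-degree), and
#' every gene carries a negative self-loop so the linear system
#' dx/dt = A x + p has a stable steady state.
#'
#' The returned matrix `A` follows the convention `A[i, j] != 0` means gene
#' `j` regulates gene `i` (rows = targets, columns = regulators). Off-diagonal
#' weight magnitudes are uniform on `weight_range` with random sign; the
#' diagonal is -1. If the raw draw is not stable, off-diagonal weights are
#' shrunk by a constant factor until all eigenvalues have real part below
#' `-spectral_margin`.
#'
#' @param n_genes number of genes (N).
#' @param sparsity target non-self-loop links per gene; the network gets
#'   `round(sparsity * n_genes)` links.
#' @param tf_fraction fraction of genes allowed to have outgoing edges
#'   (transcription factors), in (0, 1].
#' @param seed optional integer seed; same arguments + seed reproduce the
#'   network exactly.
#' @param weight_range magnitude bounds for off-diagonal weights.
#' @param spectral_margin required distance of the spectral abscissa below 0.
#' @param condition_max upper bound on the condition number of the final
#'   matrix; interaction weights are damped until both stability and this
#'   bound hold. Ill-conditioned (high "interampatteness") systems produce
#'   perturbation responses from which no method can recover the network,
#'   so benchmark networks are kept well conditioned by default.
#' @return square numeric matrix with gene dimnames and attributes
#'   `tf_genes` (regulator pool) and `stable = TRUE`.
#' @examples
#' net <- generate_true_network(20, sparsity = 2, tf_fraction = 0.5, seed = 1)
#' link_count(net)
#' max(Re(eigen(net, only.values = TRUE)$values)) < 0
#' @export
generate_true_network <- function(n_genes, sparsity = 1.75, tf_fraction = 0.53,
                                  seed = NULL, weight_range = c(0.5, 1.5),
                                  spectral_margin = 0.01, condition_max = 10) {
  stopifnot(n_genes >= 1, sparsity >= 0, spectral_margin > 0)
  if (tf_fraction <= 0 || tf_fraction > 1) {
    abort("tf_fraction must be in (0, 1]")
  }
  n_links <- round(sparsity * n_genes)
  n_tf <- round(tf_fraction * n_genes)
  if (n_tf < 1) {
    abort("tf_fraction too small: no gene would be a regulator")
  }
  if (n_links > n_tf * (n_genes - 1)) {
    abort(sprintf(
      "infeasible: %d links requested but only %d regulator-target slots exist",
      n_links, n_tf * (n_genes - 1)))
  }

  with_seed_opt(seed, {
    genes <- default_genes(n_genes)
    tf <- sort(sample.int(n_genes, n_tf))
    A <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))

    out_deg <- integer(n_genes)
    placed <- 0L
    while (placed < n_links) {
      # hub-heavy regulator choice: out-degree + 1 preferential attachment
      open <- tf[vapply(tf, function(j) sum(A[-j, j] == 0) > 0, logical(1))]
      w <- out_deg[open] + 1
      reg <- if (length(open) == 1L) open else sample(open, 1L, prob = w)
      free <- setdiff(which(A[, reg] == 0), reg)
      tgt <- if (length(free) == 1L) free else sample(free, 1L)
      A[tgt, reg] <- sample(c(-1, 1), 1L) * runif(1, weight_range[1], weight_range[2])
      out_deg[reg] <- out_deg[reg] + 1L
      placed <- placed + 1L
    }
    diag(A) <- -1

    # damp interactions until the linear system is stable and well
    # conditioned (kappa is the 2-norm condition number)
    unstable <- function(A) {
      max(Re(eigen(A, only.values = TRUE)$values)) > -spectral_margin ||
        kappa(A, exact = TRUE) > condition_max
    }
    while (unstable(A)) {
      off <- A
      diag(off) <- 0
      A <- off * 0.9
      diag(A) <- -1
    }
    structure(A, tf_genes = genes[tf], stable = TRUE)
  })
}

#' Build a single-knockdown perturbation design matrix
#'
#' One experiment per gene per replicate: experiment `k * N + i` knocks down
#' gene `i`, encoded as -1 in row `i` and 0 elsewhere. `replicates` copies of
#' the `N x N` block `-I` are concatenated horizontally, giving an
#' `N x (replicates * N)` matrix.
#'
#' @param n_genes number of genes.
#' @param replicates number of replicate blocks (columns = replicates * N).
#' @param genes optional gene labels.
#' @return numeric matrix with entries in \{-1, 0\}.
#' @examples
#' make_design(3, replicates = 2)
#' @export
make_design <- function(n_genes, replicates = 3, genes = default_genes(n_genes)) {
  stopifnot(n_genes >= 1, replicates >= 1)
  block <- -diag(n_genes)
  P <- do.call(cbind, replicate(replicates, block, simplify = FALSE))
  rownames(P) <- genes
  colnames(P) <- as.vector(vapply(
    seq_len(replicates),
    function(k) paste0(genes, "_r", k),
    character(n_genes)))
  P
}

#' Simulate noise-free steady-state expression
#'
#' Under the linear steady-state model the log2 fold-change response to the
#' perturbations in `design` is `Y = -A^{-1} P`. The true (stable) network is
#' invertible, so the exact inverse is used here; candidate networks from
#' inference are instead pushed through the pseudoinverse in
#' [predict_expression()].
#'
#' @param net invertible square network matrix.
#' @param design perturbation design matrix with matching gene rows.
#' @return matrix of log2 fold changes, genes x experiments.
#' @export
simulate_expression <- function(net, design) {
  net <- as_network_matrix(net)
  check_same_genes(net, design, "network", "design")
  if (rcond(net) < 1e-12) {
    abort(paste("network matrix is numerically singular;",
                "regenerate it or use predict_expression() (pseudoinverse)"))
  }
  Y <- -solve(net, design)
  dimnames(Y) <- dimnames(design)
  Y
}

#' Named signal-to-noise presets
#'
#' `"low"` noise corresponds to SNR 10, `"high"` noise to SNR 0.1. These are
#' this package's documented stand-ins for the benchmark's two noise levels;
#' any positive SNR can be passed to [add_noise()] directly.
#'
#' @param level `"low"` or `"high"` (noise level, not SNR level).
#' @return a positive SNR value.
#' @export
snr_preset <- function(level = c("low", "high")) {
  level <- match.arg(level)
  c(low = 10, high = 0.1)[[level]]
}

#' Add SNR-controlled Gaussian noise to an expression matrix
#'
#' Noise is i.i.d. Gaussian with standard deviation calibrated analytically
#' so that the realized signal-to-noise ratio, defined as
#' `sigma_min(Y) / sigma_max(E)` (smallest singular value of the signal over
#' the largest singular value of the noise), matches `snr` in expectation:
#' for an `N x M` Gaussian matrix the largest singular value concentrates
#' near `sigma * (sqrt(N) + sqrt(M))`.
#'
#' @param y expression matrix (the noise-free signal).
#' @param snr target signal-to-noise ratio, > 0. `Inf` returns `y` unchanged.
#' @param seed optional integer seed for a reproducible draw.
#' @return `y + E`, with attributes `sigma` (noise sd) and `realized_snr`.
#' @export
add_noise <- function(y, snr = snr_preset("low"), seed = NULL) {
  stopifnot(is.numeric(snr), length(snr) == 1, snr > 0)
  if (is.infinite(snr)) {
    return(structure(y, sigma = 0, realized_snr = Inf))
  }
  d <- svd(y, nu = 0, nv = 0)$d
  sigma <- min(d) / (snr * (sqrt(nrow(y)) + sqrt(ncol(y))))
  with_seed_opt(seed, {
    E <- matrix(rnorm(length(y), sd = sigma), nrow(y), ncol(y))
    realized <- if (sigma > 0) min(d) / max(svd(E, nu = 0, nv = 0)$d) else Inf
    structure(y + E, sigma = sigma, realized_snr = realized)
  })
}
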