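# Small fixtures shared across test files; everything is built in code.

# Square weight matrix from entries given row-wise, with gene names attached.
toy_net <- function(entries, n = sqrt(length(entries)), genes = paste0("G", seq_len(n))) {
  matrix(entries, n, n, byrow = TRUE, dimnames = list(genes, genes))
}

# Network from a directed edge list (regulator -> target) on n genes,
# diagonal decay -1 so it is invertible.
edge_net <- function(edges, n, weights = rep(1, nrow(edges))) {
  genes <- paste0("G", seq_len(n))
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  A[cbind(edges[, 2], edges[, 1])] <- weights
  diag(A) <- -1
  A
}

# A complete simulated benchmark instance: stable truth, design, clean and
# noisy expression.
sim_case <- function(n_genes, sparsity = 1.75, tf_fraction = 0.5, seed = 1,
                     replicates = 3, snr = Inf, ...) {
  net <- generate_true_network(n_genes, sparsity, tf_fraction, seed = seed, ...)
  design <- make_design(n_genes, replicates, genes = rownames(net))
  y0 <- simulate_expression(net, design)
  y <- if (is.infinite(snr)) y0 else add_noise(y0, snr = snr, seed = seed + 1000L)
  list(net = net, design = design, y0 = y0, y = y)
}
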