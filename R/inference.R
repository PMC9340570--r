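#' Infer a sparsity sweep with lasso (L1) regression paths
#'
#' Fits the steady-state relation `A Y = -P` row by row: the i-th network
#' row is an L1-penalized regression (no intercept, unstandardized) of the
#' i-th design row, negated, on the expression of all genes across
#' experiments. A shared log-spaced penalty grid is walked from the
#' all-zero solution downwards; the signed coefficient network at each grid
#' point is collected and the sweep is assembled so that every integer link
#' count between `round(min_lpg * N)` and `round(max_lpg * N)` is present:
#' link counts the path skips are filled by weight-cutoff truncation of the
#' nearest denser path network.
#'
#' @param y expression matrix, genes x experiments (log2 fold changes).
#' @param design matching perturbation design matrix.
#' @param min_lpg,max_lpg sweep bounds in links per gene (default 1-5).
#' @param nlambda number of penalty grid points.
#' @param lambda_min_ratio ratio of the smallest to the largest penalty.
#' @return a [grn_sweep()] with `method = "lasso"`.
#' @export
infer_lasso_sweep <- function(y, design, min_lpg = 1, max_lpg = 5,
                              nlambda = 200, lambda_min_ratio = 1e-4) {
  check_same_genes(y, design, "expression", "design")
  n <- nrow(y)
  m <- ncol(y)
  genes <- rownames(y) %||% default_genes(n)

  dead <- apply(y, 1, function(r) var(r) == 0)
  if (any(dead)) {
    warn(sprintf("%d expression row(s) with zero variance cannot act as regulators: %s",
                 sum(dead), paste(genes[dead], collapse = ", ")))
  }

  X <- t(y)
  resp <- -t(design)
  # glmnet's entry point for unstandardized, intercept-free gaussian fits:
  # the smallest penalty with an all-zero solution is max |X' y| / m
  lmax <- max(abs(crossprod(X, resp))) / m
  lambda <- exp(seq(log(lmax * 1.001), log(lmax * lambda_min_ratio),
                    length.out = nlambda))

  coefs <- array(0, dim = c(n, n, nlambda)) # target x regulator x penalty
  for (i in seq_len(n)) {
    fit <- glmnet::glmnet(X, resp[, i], alpha = 1, lambda = lambda,
                          intercept = FALSE, standardize = FALSE,
                          exclude = which(dead))
    b <- as.matrix(fit$beta)
    # glmnet may stop early on the path; pad with the last fitted solution
    if (ncol(b) < nlambda) {
      b <- cbind(b, b[, rep(ncol(b), nlambda - ncol(b)), drop = FALSE])
    }
    coefs[i, , ] <- b
  }

  path <- lapply(seq_len(nlambda), function(l) {
    A <- coefs[, , l]
    dimnames(A) <- list(genes, genes)
    A
  })
  counts <- vapply(path, link_count, integer(1))

  ks <- seq.int(round(min_lpg * n), round(max_lpg * n))
  candidates <- vector("list", length(ks))
  for (idx in seq_along(ks)) {
    k <- ks[idx]
    hit <- which(counts == k)
    if (length(hit) > 0) {
      candidates[[idx]] <- path[[hit[1]]] # sparsest penalty achieving k
    } else {
      donor <- which(counts > k)
      if (length(donor) == 0) break
      donor <- donor[which.min(counts[donor])]
      candidates[[idx]] <- keep_k(path[[donor]], k)
    }
  }
  kept <- !vapply(candidates, is.null, logical(1))
  if (!all(kept)) {
    warn(sprintf("lasso path too sparse for the requested range; sweep truncated at %d links",
                 max(ks[kept])))
  }
  grn_sweep(candidates[kept], method = "lasso")
}

#' Infer a sparsity sweep with ridge (L2) regression and weight cutoffs
#'
#' Fits the same row-wise steady-state model as [infer_lasso_sweep()] but
#' with an L2 penalty at one fixed value, which has the closed form
#' `A = -P Y' (Y Y' + penalty I)^{-1}` and produces a fully dense signed
#' network; the sweep is then extracted by keeping the k largest-|weight|
#' off-diagonal entries for each target link count ([extract_sweep()]).
#'
#' @inheritParams infer_lasso_sweep
#' @param penalty the fixed ridge penalty (default 1).
#' @return a [grn_sweep()] with `method = "ridge"`.
#' @export
infer_ridge_sweep <- function(y, design, min_lpg = 1, max_lpg = 5,
                              penalty = 1) {
  check_same_genes(y, design, "expression", "design")
  stopifnot(penalty > 0)
  n <- nrow(y)
  if (any(apply(y, 1, function(r) var(r) == 0))) {
    warn("expression rows with zero variance found; their ridge weights are uninformative")
  }
  A <- -design %*% t(y) %*% solve(tcrossprod(y) + penalty * diag(n))
  dimnames(A) <- list(rownames(y) %||% default_genes(n),
                      rownames(y) %||% default_genes(n))
  extract_sweep(A, min_lpg, max_lpg, method = "ridge")
}

#' Infer a sparsity sweep with tree-ensemble importances
#'
#' For each gene, a regression random forest predicts that gene's expression
#' across experiments from the expression of all other genes, and each
#' predictor receives a nonnegative impurity-importance score. Edge
#' direction is then REVERSED relative to the usual importance convention:
#' the importance of gene j when predicting gene i becomes the weight of the
#' edge i -> j, i.e. the predicted gene is taken as the regulator. The
#' resulting fully connected positive-weight network is cut into a nested
#' sweep with [extract_sweep()].
#'
#' @param y expression matrix, genes x experiments; at least 2 experiments.
#' @param n_trees trees per forest (the benchmark setting is 1000).
#' @param min_lpg,max_lpg sweep bounds in links per gene.
#' @param mtry candidate predictors per split; default `floor(sqrt(N - 1))`.
#' @param seed optional integer seed; forests are seeded per gene from it.
#' @return a [grn_sweep()] with `method = "tree"`; all candidate weights
#'   are nonnegative.
#' @export
infer_tree_sweep <- function(y, n_trees = 1000, min_lpg = 1, max_lpg = 5,
                             mtry = NULL, seed = NULL) {
  n <- nrow(y)
  if (ncol(y) < 2) abort("tree inference needs at least 2 experiments")
  genes <- rownames(y) %||% default_genes(n)
  mtry <- mtry %||% max(1L, floor(sqrt(n - 1)))

  dead <- apply(y, 1, function(r) var(r) == 0)
  if (any(dead)) {
    inform(sprintf("constant expression row(s) get zero importance as predictors: %s",
                   paste(genes[dead], collapse = ", ")))
  }

  W <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    dat <- as.data.frame(t(y[-i, , drop = FALSE]))
    names(dat) <- paste0("x", seq_len(n)[-i])
    dat$.target <- y[i, ]
    fit <- ranger::ranger(
      dependent.variable.name = ".target", data = dat,
      num.trees = n_trees, mtry = min(mtry, n - 1),
      importance = "impurity",
      seed = if (is.null(seed)) NULL else as.integer(seed) + i,
      num.threads = 1)
    imp <- pmax(fit$variable.importance, 0)
    # reversed direction: predicted gene i is the regulator of predictor j
    W[seq_len(n)[-i], i] <- imp[paste0("x", seq_len(n)[-i])]
  }
  extract_sweep(W, min_lpg, max_lpg, method = "tree")
}
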