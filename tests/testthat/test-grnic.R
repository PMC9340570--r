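test_that("pseudoinverse prediction reproduces identity and zero algebra", {
  A <- toy_net(c(-1, 0, 0, -1))
  P <- -diag(2)
  dimnames(P) <- dimnames(A)
  yhat <- predict_expression(A, P, sv_threshold = 0.5)
  expect_equal(unname(yhat), -diag(2))

  Z <- toy_net(rep(0, 4))
  yz <- predict_expression(Z, P, sv_threshold = 0.5)
  expect_equal(unname(yz), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_true(isTRUE(attr(yz, "degenerate")))
})

test_that("pseudoinverse prediction matches the direct inverse when the safeguard is off", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:8, 1)
    repeat {
      A <- matrix(rnorm(n * n), n, n)
      if (kappa(A, exact = TRUE) < 10) break
    }
    dimnames(A) <- list(paste0("G", 1:n), paste0("G", 1:n))
    P <- -diag(n)
    dimnames(P) <- dimnames(A)
    expect_equal(unname(predict_expression(A, P, sv_threshold = 1e-10)),
                 unname(-solve(A, P)), tolerance = 1e-8)
  }
})

test_that("the default safeguard threshold comes from the measured matrix and rarely binds", {
  cs <- sim_case(15, sparsity = 1.5, seed = 2, snr = 10)
  # threshold = 1 / sigma_max(Y) lies below the singular values of any
  # candidate consistent with A Y = -P, so the truth passes untouched
  yhat <- predict_expression(cs$net, cs$design, measured = cs$y)
  expect_equal(unname(yhat), unname(-solve(cs$net, cs$design)), tolerance = 1e-8)
  expect_false(isTRUE(attr(yhat, "degenerate")))
})

test_that("penalty counts genes regulating at least one other gene", {
  expect_equal(penalty_K(toy_net(rep(0, 16), 4)), 0L)
  full5 <- matrix(1, 5, 5)
  expect_equal(penalty_K(full5), 5L)
  # edges 1->2, 1->3, 2->3 on 4 genes: two distinct sources
  net <- edge_net(rbind(c(1, 2), c(1, 3), c(2, 3)), 4)
  expect_equal(penalty_K(net), 2L)
  # a gene regulating only itself is not a regulator
  selfonly <- toy_net(c(5, 0, 0, 0), 2)
  expect_equal(penalty_K(selfonly), 0L)
})

test_that("badness of fit is an RMS difference after per-matrix max-abs scaling", {
  m <- toy_net(c(1, -2, 0.5, 4), 2)
  expect_equal(badness_of_fit(m, m), 0)
  # doubling is invisible after scaling
  expect_equal(badness_of_fit(2 * m, m), 0)
  # sign flip: difference is twice the scaled measured matrix
  expect_equal(badness_of_fit(-m, m), 2 * sqrt(mean((m / 4)^2)))
  # hand-computed 2x2 case: pred/1 - meas/2 entrywise
  pred <- matrix(c(1, 0, 0, 1), 2)
  meas <- matrix(c(2, 2, 0, 0), 2)
  expect_equal(badness_of_fit(pred, meas),
               sqrt(mean(c(1 - 1, 0 - 1, 0, 1)^2)))
  expect_error(badness_of_fit(matrix(0, 2, 3), matrix(0, 2, 2)), "mismatch")
})

test_that("grnic normalization chain matches hand arithmetic on a 3-candidate sweep", {
  # three nested candidates on a 4-gene system
  sw <- grn_sweep(list(
    edge_net(rbind(c(1, 2)), 4),
    edge_net(rbind(c(1, 2), c(2, 3)), 4),
    edge_net(rbind(c(1, 2), c(2, 3), c(3, 4)), 4)))
  truth <- sw$candidates[[3]]
  P <- make_design(4, 1, genes = rownames(truth))
  Y <- simulate_expression(truth, P)
  res <- grnic_scores(sw, P, Y)

  # independent recomputation of the chain from the exported primitives
  k_raw <- vapply(sw$candidates, penalty_K, numeric(1))
  e_raw <- vapply(sw$candidates, function(a) {
    badness_of_fit(predict_expression(a, P, measured = Y), Y)
  }, numeric(1))
  mm <- function(x) if (diff(range(x)) == 0) rep(0, length(x)) else
    (x - min(x)) / (max(x) - min(x))
  l_norm <- mm(exp(mm(e_raw)))
  k_norm <- mm(k_raw)
  expect_equal(res$table$k_raw, k_raw)
  expect_equal(res$table$fit_error_raw, e_raw)
  expect_equal(res$table$l_norm, l_norm)
  expect_equal(res$table$k_norm, k_norm)
  expect_equal(res$table$grnic, k_norm + l_norm)
  expect_equal(res$selected_index, which.min(k_norm + l_norm))
  expect_true(all(res$table$k_norm >= 0 & res$table$k_norm <= 1))
  expect_true(all(res$table$l_norm >= 0 & res$table$l_norm <= 1))
  expect_true(all(res$table$grnic >= 0 & res$table$grnic <= 2))
})

test_that("degenerate normalizations map constant terms to zero", {
  single <- grn_sweep(list(edge_net(rbind(c(1, 2)), 3)))
  P <- make_design(3, 1, genes = paste0("G", 1:3))
  Y <- simulate_expression(edge_net(rbind(c(1, 2)), 3), P)
  res <- grnic_scores(single, P, Y)
  expect_equal(res$table$grnic, 0)
  expect_equal(res$selected_index, 1L)
})

test_that("a dominating candidate is always selected", {
  # candidate 2 is the truth: fewest-error; candidate 3 adds a regulator
  truth <- edge_net(rbind(c(1, 2), c(1, 3)), 4, weights = c(1, 0.8))
  noisy <- truth
  noisy[2, 4] <- 0.3
  noisy[3, 4] <- 0.2
  sparse1 <- edge_net(rbind(c(1, 2)), 4)
  sw <- grn_sweep(list(sparse1, truth, noisy))
  P <- make_design(4, 1, genes = rownames(truth))
  Y <- simulate_expression(truth, P)
  res <- grnic_scores(sw, P, Y)
  expect_equal(res$selected_index, 2L)
})

test_that("selection is invariant under simultaneous gene permutation", {
  cs <- sim_case(12, sparsity = 1.5, seed = 13, snr = 10)
  sw <- infer_ridge_sweep(cs$y, cs$design, min_lpg = 1, max_lpg = 3)
  res <- grnic_scores(sw, cs$design, cs$y)
  perm <- withr::with_seed(1, sample(12))
  swp <- grn_sweep(lapply(sw$candidates, function(a) a[perm, perm]),
                   method = sw$method)
  resp <- grnic_scores(swp, cs$design[perm, ], cs$y[perm, ])
  expect_equal(resp$selected_index, res$selected_index)
  expect_equal(resp$table$grnic, res$table$grnic, tolerance = 1e-10)
})

test_that("normalized badness of fit is monotone in the raw error", {
  cs <- sim_case(12, sparsity = 1.5, seed = 14, snr = 10)
  sw <- infer_ridge_sweep(cs$y, cs$design, min_lpg = 1, max_lpg = 3)
  res <- grnic_scores(sw, cs$design, cs$y)
  ord <- order(res$table$fit_error_raw)
  expect_true(all(diff(res$table$l_norm[ord]) >= 0))
})

test_that("shuffling preserves column multisets and destroys structure", {
  cs <- sim_case(10, sparsity = 1.8, seed = 15, snr = 10)
  yhat <- predict_expression(cs$net, cs$design, measured = cs$y)
  sh <- shuffle_control(yhat, seed = 1)
  for (j in seq_len(ncol(yhat))) {
    expect_equal(unname(sort(sh[, j])), unname(sort(yhat[, j])))
  }
  expect_identical(shuffle_control(yhat, seed = 4), shuffle_control(yhat, seed = 4))
  # single-gene matrices cannot change
  one <- matrix(1:5, 1, 5)
  expect_equal(shuffle_control(one, seed = 2), one, ignore_attr = TRUE)
  # structure loss: shuffled predictions fit worse on average
  base <- badness_of_fit(yhat, cs$y)
  shuffled <- vapply(1:100, function(s) {
    badness_of_fit(shuffle_control(yhat, seed = s), cs$y)
  }, numeric(1))
  expect_gt(mean(shuffled), base)
})
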