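test_that("additive map encodes haplotype half-counts", {
  expect_equal(unname(additive_map(2)), rbind(c(1, 0), c(0, 1), c(0.5, 0.5)))
  A8 <- additive_map(8)
  expect_equal(dim(A8), c(36L, 8L))
  expect_equal(rowSums(A8), setNames(rep(1, 36), rownames(A8)))
  A3 <- additive_map(3)
  expect_equal(unname(A3["A.C", ]), c(0.5, 0, 0.5))
  expect_error(additive_map(1), "at least 2")
})

test_that("contrast bases are orthonormal and sum to zero", {
  expect_equal(ncol(sum_to_zero_contrasts(1)), 0L)
  C2 <- sum_to_zero_contrasts(2)
  expect_equal(unname(abs(C2[, 1])), rep(1 / sqrt(2), 2))
  expect_equal(sum(C2), 0)
  for (K in c(3, 4, 8)) {
    C <- sum_to_zero_contrasts(K)
    expect_lt(max(abs(crossprod(C) - diag(K - 1))), 1e-12)
    expect_lt(max(abs(colSums(C))), 1e-12)
  }
})

test_that("design matrix assembles [1 | covariates | DAMC]", {
  dip <- toy_dip(3, 6, seed = 2)
  states <- argmax_states(dip)
  # identity partition: effect rows are contrast rows of each haplotype
  X <- build_design(states, dip, c(0, 1, 2))
  C <- sum_to_zero_contrasts(3)
  A <- additive_map(3)
  expect_equal(X[, -1, drop = FALSE],
               (A %*% C)[states, , drop = FALSE], ignore_attr = TRUE)
  # one-block partition: intercept only
  X1 <- build_design(states, dip, c(0, 0, 0))
  expect_equal(ncol(X1), 1L)
  # heterozygote A/B under partition {A,B},{C}: allele half-counts (1, 0)
  dip3 <- diplotype_priors(matrix(c(0, 0, 0, 1, 0, 0), 1), LETTERS[1:3])
  M <- series_matrix(allelic_series(c(0, 0, 1)))
  DAM <- additive_map(3)[4, , drop = FALSE] %*% M
  expect_equal(drop(DAM), c(1, 0))
  # covariates sit between intercept and effects
  cov <- matrix(rnorm(6), 6, 1)
  Xc <- build_design(states, dip, c(0, 1, 2), covariates = cov)
  expect_equal(ncol(Xc), 1 + 1 + 2)
  expect_equal(Xc[, 2], cov[, 1], ignore_attr = TRUE)
})

test_that("collapsed likelihood equals the dense multivariate-t density", {
  set.seed(5)
  for (J in c(3, 4, 5)) {
    N <- 4 * J
    dip <- toy_dip(J, N, seed = J)
    states <- argmax_states(dip)
    y <- rnorm(N)
    hy <- series_hyper(kappa = 3, lambda = 2, tau = 1.5)
    for (s in all_series(J)) {
      got <- collapsed_loglik(y, states, dip, s, 0.8, hy)
      want <- dense_mvt_loglik(y, states, dip, s, 0.8, 3, 2, 1.5)
      expect_lt(abs(got - want), 1e-8)
    }
  }
})

test_that("collapsed likelihood matches brute-force numerical integration", {
  dip <- toy_dip(3, 8, seed = 6)
  states <- argmax_states(dip)
  set.seed(6)
  y <- rnorm(8)
  s <- allelic_series(c(0, 1, 0))
  hy <- series_hyper(kappa = 3, lambda = 2, tau = 1.5)
  got <- collapsed_loglik(y, states, dip, s, 0.8, hy)
  want <- quadrature_loglik_k2(y, states, dip, s, 0.8, 3, 2, 1.5)
  expect_lt(abs(got - want) / abs(want), 1e-6)
})

test_that("improper limit agrees with the finite-hyperparameter path", {
  dip <- toy_dip(4, 12, seed = 7)
  states <- argmax_states(dip)
  set.seed(7)
  y <- rnorm(12)
  s1 <- c(0, 1, 0, 1); s2 <- c(0, 1, 2, 0)
  d_imp <- collapsed_loglik(y, states, dip, s1, 0.8) -
    collapsed_loglik(y, states, dip, s2, 0.8)
  hy <- series_hyper(kappa = 1e-8, lambda = 1e-8, tau = 1e6)
  d_fin <- collapsed_loglik(y, states, dip, s1, 0.8, hy) -
    collapsed_loglik(y, states, dip, s2, 0.8, hy)
  expect_lt(abs(d_imp - d_fin), 1e-4)
})

test_that("collapsed likelihood invariances hold", {
  dip <- toy_dip(4, 10, seed = 8)
  states <- argmax_states(dip)
  set.seed(8)
  y <- rnorm(10)
  base <- collapsed_loglik(y, states, dip, c(0, 1, 0, 2), 0.6)
  # exchanging individuals
  perm <- sample(10)
  dipp <- diplotype_priors(dip$probs[perm, ], dip$founders)
  expect_equal(collapsed_loglik(y[perm], states[perm], dipp,
                                c(0, 1, 0, 2), 0.6), base)
  # relabeling alleles (column permutation of M)
  expect_equal(collapsed_loglik(y, states, dip, c(1, 0, 1, 2), 0.6), base)
  expect_equal(collapsed_loglik(y, states, dip, c(2, 0, 2, 1), 0.6), base)
  # phi = 0 flattens the series
  l0 <- vapply(all_series(4), function(s)
    collapsed_loglik(y, states, dip, s, 0), numeric(1))
  expect_lt(diff(range(l0)), 1e-10)
  # adding a constant shifts all series equally under the improper limit
  d1 <- collapsed_loglik(y, states, dip, c(0, 1, 0, 2), 0.6) -
    collapsed_loglik(y, states, dip, c(0, 0, 1, 0), 0.6)
  d2 <- collapsed_loglik(y + 3.7, states, dip, c(0, 1, 0, 2), 0.6) -
    collapsed_loglik(y + 3.7, states, dip, c(0, 0, 1, 0), 0.6)
  expect_lt(abs(d1 - d2), 1e-8)
  expect_error(collapsed_loglik(c(y[-1], NA), states, dip, c(0, 1, 0, 2), 0.6),
               "finite")
})

test_that("compiled likelihood kernels match the reference implementation", {
  set.seed(9)
  for (rep in 1:20) {
    J <- sample(2:6, 1)
    N <- sample(5:30, 1)
    dip <- toy_dip(J, N, seed = rep)
    y <- rnorm(N)
    ctx <- qtlseries:::lik_context(y, additive_map(J)[argmax_states(dip), ])
    K <- sample.int(J, 1)
    a <- canonical_series_for_test(J, K)
    B <- sum_to_zero_contrasts(K)[a + 1L, , drop = FALSE]
    phi <- runif(1, 0, 2)
    expect_equal(qtlseries:::loglik_improper_gram(ctx, B, phi),
                 qtlseries:::loglik_improper_gram_r(ctx, B, phi))
    expect_equal(qtlseries:::loglik_finite_gram(ctx, B, phi, 2, 1, 1.5),
                 qtlseries:::loglik_finite_gram_r(ctx, B, phi, 2, 1, 1.5))
  }
})

test_that("effects conditional is a coherent normal-gamma update", {
  # flat-effect limit: posterior mean approaches the least-squares estimate
  set.seed(10)
  J <- 3; N <- 60
  des <- balanced_homozygous_design(J, N)
  y <- rnorm(N, c(-1, 0, 1)[des$states])
  ec <- effects_conditional(y, des$states, des$diplotypes, c(0, 1, 2), 1e6)
  X <- build_design(des$states, des$diplotypes, c(0, 1, 2))
  ls <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_lt(max(abs(ec$mean - ls)), 1e-4)
  # simulation sanity: K = 2, posterior mean near truth
  sim <- simulate_qtl(J = 4, N = 50, K = 2, h2 = 0.5, seed = 11)
  ec2 <- effects_conditional(sim$y, sim$states, sim$diplotypes, sim$series, 1)
  sd2 <- sqrt(diag(solve(ec2$precision)) * ec2$rate / (ec2$shape - 1))
  C <- sum_to_zero_contrasts(2)
  truth <- c(mean(sim$beta_alle), drop(crossprod(C, sim$beta_alle)))
  expect_true(all(abs(ec2$mean - truth) < 3 * sd2 + 0.2))
  # degenerate input: zero-variance phenotype with phi = 0
  expect_error(effects_conditional(rep(1, N), des$states, des$diplotypes,
                                   rep(0, J), 0),
               "degenerate")
})
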