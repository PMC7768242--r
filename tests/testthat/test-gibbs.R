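test_that("chains are bit-reproducible under a fixed seed", {
  sim <- simulate_qtl(J = 4, N = 40, K = 2, h2 = 0.5, seed = 21)
  f1 <- series_fit(sim$y, sim$diplotypes, n_iter = 200, seed = 22)
  f2 <- series_fit(sim$y, sim$diplotypes, n_iter = 200, seed = 22)
  expect_identical(f1$series, f2$series)
  expect_identical(f1$bhap, f2$bhap)
  expect_identical(f1$phi, f2$phi)
  f3 <- series_fit(sim$y, sim$diplotypes, n_iter = 200, seed = 23)
  expect_false(identical(f1$series, f3$series))
})

test_that("decoupled updates recover their priors", {
  # with phi = 0 the likelihood is flat in the series, so the tree-mode
  # partition chain must be stationary at the prior table
  set.seed(24)
  tr <- sample_coalescent_tree(4)
  prior <- tree_partition_prior(tr, a_alpha = 1, b_alpha = 1)
  des <- balanced_homozygous_design(4, 16)
  y <- rnorm(16)
  fit <- series_fit(y, des$diplotypes, prior = "tree", tree = prior,
                    n_iter = 8000, burn_in = 500, seed = 25, fix_phi = 0)
  expect_lt(tv_to_prior(fit$series[-(1:500)], prior), 0.05)
  # CRP mode at fixed alpha: K distribution matches the Ewens prior
  fit2 <- series_fit(y, des$diplotypes, prior = "crp", n_iter = 8000,
                     burn_in = 500, seed = 26, fix_phi = 0, fix_alpha = 1)
  empK <- tabulate(fit2$K[-(1:500)], 4) / 7500
  crpK <- prior_k_distribution(crp_partition_prior(4, alpha = 1))
  expect_lt(0.5 * sum(abs(empK - crpK)), 0.05)
})

test_that("prior phi draws follow the half-t through the latent pair", {
  # the latent (eta, psi) construction must push forward to Half-t(v); the
  # induced prior on h2 = phi^2 / (phi^2 + 1) then has its mode at zero and a
  # decreasing density over the lower half (v = 2; the exact pushforward
  # density is proportional to h^(-1/2) (2 - h)^(-3/2), which dips at
  # h = 0.5 and stays well below the origin thereafter)
  set.seed(27)
  n <- 40000
  eta <- rnorm(n)
  psi <- 1 / rgamma(n, 1, rate = 1)     # v = 2
  phi <- abs(eta) * sqrt(psi)
  ks <- suppressWarnings(ks.test(phi, function(q) 2 * pt(q, df = 2) - 1))
  expect_gt(ks$p.value, 0.01)
  h2 <- phi^2 / (1 + phi^2)
  counts <- hist(h2, breaks = seq(0, 1, 0.1), plot = FALSE)$counts
  expect_true(all(diff(counts[1:5]) < 0))
  expect_true(all(counts[1] > 2 * counts[-1]))
})

test_that("point-mass inputs freeze the corresponding updates", {
  sim <- simulate_qtl(J = 4, N = 30, K = 2, h2 = 0.5, seed = 28)
  # point-mass diplotype priors: states never move
  fit <- series_fit(sim$y, sim$diplotypes, n_iter = 100, seed = 29,
                    store_diplotypes = TRUE)
  expect_true(all(fit$diplotype_states[, 1] == sim$states[1]))
  expect_identical(fit$diplotype_states[1, ], fit$diplotype_states[100, ])
  # point-mass partition prior: the series never moves
  pm <- qtlseries:::new_partition_prior("0,0,1,1", 1, 4, "restricted")
  fit2 <- series_fit(sim$y, sim$diplotypes, prior = "tree", tree = pm,
                     n_iter = 100, seed = 30)
  expect_true(all(fit2$series == "0,0,1,1"))
  # a tree that forbids a series: that series is never sampled
  trX <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  fit3 <- series_fit(sim$y, sim$diplotypes, prior = "tree", tree = trX,
                     n_iter = 400, seed = 31)
  expect_false(any(fit3$series == "0,1,1,0"))
})

test_that("null-model state is handled and recorded coherently", {
  set.seed(32)
  des <- balanced_homozygous_design(3, 18)
  y <- rnorm(18)
  fit <- series_fit(y, des$diplotypes, prior = "fixed",
                    fixed_series = c(0, 0, 0), n_iter = 300, seed = 33)
  expect_true(all(fit$K == 1L))
  # haplotype effects collapse to the intercept
  expect_equal(fit$bhap[, 1], fit$mu)
  expect_equal(fit$bhap[, 2], fit$mu)
  # phi still explores its prior
  expect_gt(stats::sd(fit$phi), 0.1)
})

test_that("the sampler recovers a strong biallelic signal", {
  sim <- simulate_qtl(J = 8, N = 400, K = 2, h2 = 0.8, seed = 34)
  fit <- series_fit(sim$y, sim$diplotypes, n_iter = 800, seed = 35)
  ev <- evaluate_against_truth(fit, sim$series, sim$bhap)
  expect_identical(ev$accuracy01, 1L)
  expect_gt(ev$certainty, 0.5)
})

test_that("diplotype update draws from the exact conditional posterior", {
  # two founders, uncertain diplotypes: with all other parameters held fixed,
  # repeated diplotype updates must reproduce the hand-computed per-individual
  # posterior over the three states
  set.seed(36)
  J <- 2; N <- 6
  probs <- matrix(rep(c(0.4, 0.4, 0.2), N), N, byrow = TRUE)
  dip <- diplotype_priors(probs, c("A", "B"))
  y <- c(1.2, 0.8, 1.1, -0.9, -1.2, -1)
  ctx <- qtlseries:::make_context(y, dip, NULL, series_hyper(), "fixed", NULL,
                                  allelic_series(c(0, 1)), NULL, NULL)
  state <- list(assign = c(0L, 1L), K = 2L, states = rep(1L, N), mu = 0.1,
                gamma = numeric(0), beta = 0.9, sigma = 0.8,
                eta = 1, psi = 1, phi = 1)
  gctx <- qtlseries:::refresh_grams(ctx, state$states)
  n_draw <- 4000
  tallies <- matrix(0, N, 3)
  for (r in seq_len(n_draw)) {
    st <- qtlseries:::step_diplotypes(ctx, gctx, state)$state
    tallies[cbind(1:N, st$states)] <- tallies[cbind(1:N, st$states)] + 1
  }
  g <- drop(additive_map(2) %*% qtlseries:::haplotype_effects(ctx, state))
  for (i in seq_len(N)) {
    post <- dnorm(y[i], g, state$sigma) * probs[i, ]
    post <- post / sum(post)
    se <- sqrt(post * (1 - post) / n_draw)
    expect_true(all(abs(tallies[i, ] / n_draw - post) < 4 * se + 0.01))
  }
})
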