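# Shared fixtures and independent oracles used across the suite. Everything
# is generated in code; no stored data.

# random restricted-growth assignment of J haplotypes into exactly K alleles
canonical_series_for_test <- function(J, K) {
  a <- c(seq_len(K) - 1L, sample.int(K, J - K, replace = TRUE) - 1L)
  unclass(allelic_series(a))
}

toy_dip <- function(J, N, seed = 1, uncertain = FALSE) {
  set.seed(seed)
  S <- J + J * (J - 1L) / 2
  probs <- if (uncertain) {
    p <- matrix(stats::rexp(N * S), N)
    p / rowSums(p)
  } else {
    s <- sample.int(J, N, replace = TRUE)
    p <- matrix(0, N, S)
    p[cbind(seq_len(N), s)] <- 1
    p
  }
  diplotype_priors(probs, LETTERS[seq_len(J)])
}

argmax_states <- function(dip) max.col(dip$probs, ties.method = "first")

# Independent dense multivariate-t density for the collapsed likelihood with
# finite hyperparameters: builds the full N x N covariance, no low-rank tricks.
dense_mvt_loglik <- function(y, states, dip, series, phi, kappa, lambda, tau,
                             covariates = NULL) {
  X <- build_design(states, dip, series, covariates)
  K <- attr(allelic_series(series), "K")
  qf <- ncol(X) - (K - 1L)
  V <- diag(c(rep(tau^2, qf), rep(phi^2, K - 1L)), nrow = ncol(X))
  N <- length(y)
  Sig <- diag(N) + X %*% V %*% t(X)
  Q <- drop(t(y) %*% solve(Sig, y))
  lgamma((kappa + N) / 2) - lgamma(kappa / 2) + kappa / 2 * log(lambda / 2) -
    N / 2 * log(2 * pi) - 0.5 * c(determinant(Sig)$modulus) -
    (kappa + N) / 2 * log((lambda + Q) / 2)
}

# Brute-force numerical integration of the collapsed likelihood over
# (sigma^-2, mu, beta) for a K = 2 series with finite hyperparameters.
quadrature_loglik_k2 <- function(y, states, dip, series, phi, kappa, lambda,
                                 tau) {
  X <- build_design(states, dip, series)
  stopifnot(ncol(X) == 2L)
  f_s <- function(sv) vapply(sv, function(s) {
    f_mu <- function(mv) vapply(mv, function(m) {
      f_b <- function(bv) vapply(bv, function(b) {
        prod(stats::dnorm(y, X %*% c(m, b), 1 / sqrt(s))) *
          stats::dnorm(b, 0, phi / sqrt(s))
      }, numeric(1))
      stats::integrate(f_b, -Inf, Inf, rel.tol = 1e-10)$value *
        stats::dnorm(m, 0, tau / sqrt(s))
    }, numeric(1))
    stats::integrate(f_mu, -Inf, Inf, rel.tol = 1e-10)$value *
      stats::dgamma(s, kappa / 2, rate = lambda / 2)
  }, numeric(1))
  log(stats::integrate(f_s, 0, Inf, rel.tol = 1e-9)$value)
}

# 1-D quadrature of the improper collapsed likelihood against the half-t
# prior on phi: the marginal likelihood of a fixed-series model.
quadrature_evidence <- function(y, states, dip, series, v = 2) {
  shift <- collapsed_loglik(y, states, dip, series, 1)
  f <- function(pv) vapply(pv, function(p)
    exp(collapsed_loglik(y, states, dip, series, p) - shift) *
      2 * stats::dt(p, df = v), numeric(1))
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value) + shift
}

# batch-means standard error for autocorrelated chains
chain_se <- function(x, n_batch = 40L) {
  b <- floor(length(x) / n_batch)
  m <- vapply(seq_len(n_batch), function(i)
    mean(x[((i - 1L) * b + 1L):(i * b)]), numeric(1))
  stats::sd(m) / sqrt(n_batch)
}

# total variation between an empirical table of series keys and a prior table
tv_to_prior <- function(keys, prior) {
  emp <- table(keys) / length(keys)
  all_k <- union(names(emp), prior$keys)
  e <- ifelse(all_k %in% names(emp), as.numeric(emp[all_k]), 0)
  p <- ifelse(all_k %in% prior$keys,
              prior$prob[match(all_k, prior$keys)], 0)
  0.5 * sum(abs(e - p))
}

# one full Geweke comparison: marginal-conditional vs successive-conditional
# moments for the complete sampler on a small problem with proper priors.
geweke_zscores <- function(J = 3, N = 8, n = 30000, seed = 99) {
  set.seed(seed)
  hy <- series_hyper(kappa = 4, lambda = 4, tau = 1.5, v = 2,
                     a_alpha = 1, b_alpha = 1)
  dip <- toy_dip(J, N, seed = seed, uncertain = TRUE)
  mk <- function(y) qtlseries:::make_context(y, dip, NULL, hy, "crp", NULL,
                                             NULL, NULL, NULL)
  ctx0 <- mk(rep(0, N))
  stats_of <- function(st, y)
    c(K = st$K, h2 = st$phi^2 / (1 + st$phi^2), mu = st$mu,
      prec = 1 / st$sigma^2, alpha = st$alpha, m_state = mean(st$states),
      y1 = y[1L])
  mc <- matrix(NA_real_, n, 7L)
  for (i in seq_len(n)) {
    st <- qtlseries:::prior_draw(ctx0)
    y <- qtlseries:::redraw_y(ctx0, st)
    mc[i, ] <- stats_of(st, y)
  }
  sc <- matrix(NA_real_, n, 7L)
  st <- qtlseries:::prior_draw(ctx0)
  y <- qtlseries:::redraw_y(ctx0, st)
  for (i in seq_len(n)) {
    ctx <- mk(y)
    gctx <- qtlseries:::refresh_grams(ctx, st$states)
    st <- qtlseries:::step_partition_crp(ctx, gctx, st)
    st <- qtlseries:::step_effects(ctx, gctx, st)
    st <- qtlseries:::step_phi(ctx, gctx, st)
    upd <- qtlseries:::step_diplotypes(ctx, gctx, st)
    st <- upd$state
    y <- qtlseries:::redraw_y(ctx, st)
    sc[i, ] <- stats_of(st, y)
  }
  vapply(seq_len(7L), function(k)
    (mean(mc[, k]) - mean(sc[, k])) /
      sqrt(chain_se(mc[, k])^2 + chain_se(sc[, k])^2), numeric(1))
}
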