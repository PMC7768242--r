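# Partially collapsed Gibbs sampler for the allele-based association model.
#
# Each iteration follows four steps: (1) update the allelic series haplotype-
# by-haplotype, in freshly randomized order, with the effects and error scale
# collapsed (multivariate-t likelihood) -- plus the Escobar-West concentration
# update under the CRP prior; (2) jointly redraw the intercept/covariate
# coefficients, allele effects and error scale from their normal-gamma
# conditional (the effect dimension tracks K, so no stale effects are ever
# read); (3) update the relative allele-effect scale phi through its two
# conditionally conjugate latents (parameter expansion); (4) jointly update
# the diplotype states individual-by-individual.

# Build the immutable sampling context.
make_context <- function(y, dip, covariates, hyper, prior_mode, prior_table,
                         fixed_series, fix_phi, fix_alpha) {
  J <- length(dip$founders)
  A <- additive_map(J, dip$founders)
  lp_dip <- log(dip$probs)
  point_mass <- is_point_mass(dip)
  C_list <- lapply(1:J, sum_to_zero_contrasts)
  prior_env <- NULL
  if (prior_mode == "tree") {
    prior_env <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(prior_table$keys))
      assign(prior_table$keys[i], prior_table$log_prob[i], envir = prior_env)
  }
  if (is.null(hyper$b_alpha)) hyper$b_alpha <- elicit_b_alpha(J, hyper$a_alpha, 0.5)
  improper <- hyper$improper_scale && hyper$improper_intercept
  if (!improper && (hyper$improper_scale || hyper$improper_intercept))
    stop("use either all-improper or all-finite hyperparameters")
  list(y = y, N = length(y), J = J, A = A, S = nrow(A),
       founders = dip$founders, dip = dip, lp_dip = lp_dip,
       point_mass = point_mass, covariates = covariates,
       C_list = C_list, hyper = hyper, improper = improper,
       prior_mode = prior_mode, prior_table = prior_table,
       prior_env = prior_env, fixed_series = fixed_series,
       fix_phi = fix_phi, fix_alpha = fix_alpha)
}

refresh_grams <- function(ctx, states) {
  lik_context(ctx$y, ctx$A[states, , drop = FALSE], ctx$covariates)
}

# Collapsed log likelihood for an assignment vector in any labelling.
loglik_assign <- function(ctx, gctx, assign, phi) {
  aa <- match(assign, unique(assign))
  B <- ctx$C_list[[max(aa)]][aa, , drop = FALSE]
  if (ctx$improper) loglik_improper_gram(gctx, B, phi)
  else loglik_finite_gram(gctx, B, phi, ctx$hyper$kappa, ctx$hyper$lambda,
                          ctx$hyper$tau)
}

gumbel_pick <- function(logw) {
  which.max(logw - log(-log(stats::runif(length(logw)))))
}

# Step 1 (CRP): sweep haplotypes in random order; conditional weights are the
# collapsed likelihood times the CRP conditional prior; then update alpha.
step_partition_crp <- function(ctx, gctx, state) {
  alpha <- if (is.null(ctx$fix_alpha)) state$alpha else ctx$fix_alpha
  a <- state$assign
  for (j in sample.int(ctx$J)) {
    others <- a[-j]
    lbl <- unique(others)
    sizes <- tabulate(match(others, lbl))
    nc <- length(lbl) + 1L
    logw <- numeric(nc)
    newlbl <- max(a) + 1L
    cand <- c(lbl, newlbl)
    for (ci in seq_len(nc)) {
      a[j] <- cand[ci]
      logw[ci] <- loglik_assign(ctx, gctx, a, state$phi)
    }
    logw <- logw + log(c(sizes, alpha))
    a[j] <- cand[gumbel_pick(logw)]
  }
  state$assign <- canonical_assignment(a)
  state$K <- max(state$assign) + 1L
  if (is.null(ctx$fix_alpha))
    state$alpha <- draw_alpha_escobar_west(state$alpha, state$K, ctx$J,
                                           ctx$hyper$a_alpha, ctx$hyper$b_alpha)
  state
}

# Escobar-West two-step update of the concentration parameter given K and J.
draw_alpha_escobar_west <- function(alpha, K, J, a, b) {
  u <- stats::rbeta(1, alpha + 1, J)
  rate <- b - log(u)
  odds <- (a + K - 1) / (J * rate)
  shape <- if (stats::runif(1) < odds / (1 + odds)) a + K else a + K - 1
  stats::rgamma(1, shape, rate = rate)
}

# Step 1 (tree): conditional weights use the marginal tree prior table,
# treated as exchangeable, with the sweep order randomized every iteration.
step_partition_tree <- function(ctx, gctx, state) {
  a <- state$assign
  for (j in sample.int(ctx$J)) {
    others <- a[-j]
    lbl <- unique(others)
    nc <- length(lbl) + 1L
    cand <- c(lbl, max(a) + 1L)
    logw <- rep(-Inf, nc)
    for (ci in seq_len(nc)) {
      a[j] <- cand[ci]
      lp <- get0(series_key(allelic_series(a)), envir = ctx$prior_env,
                 ifnotfound = -Inf)
      if (is.finite(lp))
        logw[ci] <- lp + loglik_assign(ctx, gctx, a, state$phi)
    }
    if (all(!is.finite(logw)))
      stop("current allelic series lies outside the tree prior support")
    a[j] <- cand[gumbel_pick(logw)]
  }
  state$assign <- canonical_assignment(a)
  state$K <- max(state$assign) + 1L
  state
}

# Step 2: joint draw of (theta, sigma) from the normal-gamma conditional.
step_effects <- function(ctx, gctx, state) {
  K <- state$K
  B <- ctx$C_list[[K]][state$assign + 1L, , drop = FALSE]
  ec <- effects_conditional_gram(gctx, B, state$phi, ctx$hyper)
  s2inv <- stats::rgamma(1, ec$shape, rate = ec$rate)
  sigma <- 1 / sqrt(s2inv)
  p <- ec$qf + ec$n_eff
  theta <- drop(ec$mean) + sigma * backsolve(ec$chol_precision, stats::rnorm(p))
  state$mu <- theta[1L]
  state$gamma <- if (ec$qf > 1L) theta[2:ec$qf] else numeric(0)
  state$beta <- if (ec$n_eff > 0L) theta[(ec$qf + 1L):p] else rep(0, K - 1L)
  state$sigma <- sigma
  state
}

# Step 3: parameter-expanded update of phi = |eta| * sqrt(psi). psi is
# inverse-gamma conjugate to the prior of the latent effects, eta is normal
# conjugate to the likelihood; the move jointly rescales (phi, beta).
step_phi <- function(ctx, gctx, state) {
  if (!is.null(ctx$fix_phi)) return(state)
  v <- ctx$hyper$v
  p_eff <- if (state$K > 1L && state$phi > 0) state$K - 1L else 0L
  if (p_eff > 0L) {
    bb <- sum(state$beta^2)
    psi <- 1 / stats::rgamma(1, (v + p_eff) / 2,
                             rate = (v + bb / (state$sigma^2 * state$eta^2)) / 2)
    xi <- state$beta / state$eta
    B <- ctx$C_list[[state$K]][state$assign + 1L, , drop = FALSE]
    u <- drop(B %*% xi)                               # length J
    uGu <- drop(crossprod(u, gctx$WtW %*% u))
    thF <- c(state$mu, state$gamma)
    r <- sum(u * gctx$Wty) - drop(crossprod(u, t(gctx$FtW) %*% thF))
    prec <- 1 + uGu / state$sigma^2
    eta <- stats::rnorm(1, (r / state$sigma^2) / prec, sqrt(1 / prec))
    state$beta <- eta * xi
  } else {
    psi <- 1 / stats::rgamma(1, v / 2, rate = v / 2)
    eta <- stats::rnorm(1)
  }
  state$eta <- eta
  state$psi <- psi
  state$phi <- abs(eta) * sqrt(psi)
  state
}

# Step 4: joint diplotype-state update; each individual independently, with
# probabilities proportional to the normal likelihood times the prior row.
step_diplotypes <- function(ctx, gctx, state) {
  if (ctx$point_mass) return(list(state = state, gctx = gctx, changed = FALSE))
  g <- state_means(ctx, state)                        # length S
  resid <- ctx$y
  if (!is.null(ctx$covariates) && length(state$gamma))
    resid <- resid - drop(as.matrix(ctx$covariates) %*% state$gamma)
  # log lik matrix N x S, then Gumbel-max categorical draws row by row
  ll <- -0.5 * outer(resid, g, "-")^2 / state$sigma^2
  w <- ctx$lp_dip + ll
  gmat <- -log(-log(matrix(stats::runif(ctx$N * ctx$S), ctx$N, ctx$S)))
  gmat[!is.finite(w)] <- -Inf
  state$states <- max.col(w + gmat, ties.method = "first")
  list(state = state, gctx = refresh_grams(ctx, state$states), changed = TRUE)
}

# Per-state phenotype means mu + (A M C beta): allele effects mapped through
# the additive map (rows of A M sum to one, so the intercept passes through).
state_means <- function(ctx, state) {
  beta_alle <- state$mu + drop(ctx$C_list[[state$K]] %*% state$beta)
  drop(ctx$A %*% beta_alle[state$assign + 1L])
}

haplotype_effects <- function(ctx, state) {
  beta_alle <- state$mu + drop(ctx$C_list[[state$K]] %*% state$beta)
  beta_alle[state$assign + 1L]
}

# Draw a full state (and optionally data) from the prior; requires finite
# hyperparameters. Used for sampler validation.
prior_draw <- function(ctx) {
  h <- ctx$hyper
  if (ctx$improper) stop("prior draws need finite hyperparameters")
  alpha <- if (is.null(ctx$fix_alpha))
    stats::rgamma(1, h$a_alpha, rate = h$b_alpha) else ctx$fix_alpha
  if (ctx$prior_mode == "crp") {
    a <- 0L
    for (j in 2:ctx$J) {
      sizes <- tabulate(a + 1L)
      p <- crp_conditional(sizes, alpha)
      k <- sample.int(length(p), 1L, prob = p) - 1L
      a <- c(a, if (k < length(sizes)) k else length(sizes))
    }
  } else if (ctx$prior_mode == "tree") {
    key <- sample(ctx$prior_table$keys, 1L, prob = ctx$prior_table$prob)
    a <- unclass(series_from_key(key))
  } else {
    a <- unclass(allelic_series(ctx$fixed_series))
  }
  K <- max(a) + 1L
  eta <- stats::rnorm(1)
  psi <- 1 / stats::rgamma(1, h$v / 2, rate = h$v / 2)
  phi <- if (is.null(ctx$fix_phi)) abs(eta) * sqrt(psi) else ctx$fix_phi
  sigma <- 1 / sqrt(stats::rgamma(1, h$kappa / 2, rate = h$lambda / 2))
  mu <- stats::rnorm(1, 0, sigma * h$tau)
  q <- if (is.null(ctx$covariates)) 0L else ncol(ctx$covariates)
  gamma <- stats::rnorm(q, 0, sigma * h$tau)
  beta <- stats::rnorm(K - 1L, 0, sigma * phi)
  states <- vapply(seq_len(ctx$N), function(i)
    sample.int(ctx$S, 1L, prob = ctx$dip$probs[i, ]), integer(1))
  list(assign = a, K = K, states = states, mu = mu, gamma = gamma,
       beta = beta, sigma = sigma, eta = eta, psi = psi, phi = phi,
       alpha = alpha)
}

# Redraw the phenotype from the likelihood at the current state (Geweke-style
# successive-conditional simulation).
redraw_y <- function(ctx, state) {
  g <- state_means(ctx, state)
  m <- g[state$states]
  if (!is.null(ctx$covariates) && length(state$gamma))
    m <- m + drop(as.matrix(ctx$covariates) %*% state$gamma)
  stats::rnorm(ctx$N, m, state$sigma)
}

#' Fit the allele-based association model at a QTL
#'
#' Draws posterior samples of the allelic series (the partition of founder
#' haplotypes into functional alleles), allele and haplotype effects, error
#' scale, relative effect size, diplotype states, and (under the CRP prior)
#' the concentration parameter, using a partially collapsed Gibbs sampler.
#'
#' @param y numeric phenotype vector, one value per individual.
#' @param diplotypes a [diplotype_priors] object with one row per individual.
#' @param prior allelic series prior: `"crp"` (default; unknown coalescent
#'   tree), `"tree"` (explicit tree or precomputed [partition_prior]), or
#'   `"fixed"` (known series: the haplotype-based "Full" model with all
#'   singletons, the null one-allele model, or an oracle series).
#' @param tree for `prior = "tree"`: an [ape::phylo], a `multiPhylo` (averaged
#'   over trees), or a [partition_prior].
#' @param fixed_series for `prior = "fixed"`: an [allelic_series].
#' @param covariates optional N x q numeric matrix of flat-prior covariates.
#' @param hyper a [series_hyper] object.
#' @param n_iter total Gibbs iterations recorded.
#' @param burn_in iterations discarded by summaries (default 10% of `n_iter`).
#' @param seed integer seed for exact reproducibility; `NULL` leaves the RNG
#'   state untouched.
#' @param fix_phi optionally hold the relative effect scale fixed.
#' @param fix_alpha optionally hold the concentration parameter fixed (CRP).
#' @param store_diplotypes record the sampled diplotype states per iteration.
#' @param verbose print progress every 1000 iterations.
#' @return An object of class `series_fit` with per-iteration records:
#'   `series` (restricted-growth keys), `K`, `mu`, `sigma`, `phi`, `alpha`,
#'   `bhap` (n_iter x J posterior haplotype effects), plus the inputs and
#'   configuration. Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `plot`, `simulate`.
#' @examples
#' sim <- simulate_qtl(J = 4, N = 60, K = 2, h2 = 0.6, seed = 1)
#' fit <- series_fit(sim$y, sim$diplotypes, n_iter = 300, seed = 2)
#' summary(fit)
#' @export
series_fit <- function(y, diplotypes, prior = c("crp", "tree", "fixed"),
                       tree = NULL, fixed_series = NULL, covariates = NULL,
                       hyper = series_hyper(), n_iter = 10000,
                       burn_in = floor(n_iter / 10), seed = NULL,
                       fix_phi = NULL, fix_alpha = NULL,
                       store_diplotypes = FALSE, verbose = FALSE) {
  prior <- match.arg(prior)
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("'y' must be finite")
  if (length(y) != nrow(diplotypes$probs))
    stop("'y' and 'diplotypes' must cover the same individuals")
  if (burn_in >= n_iter) stop("'burn_in' must be smaller than 'n_iter'")
  prior_table <- NULL
  if (prior == "tree") {
    if (inherits(tree, "partition_prior")) prior_table <- tree
    else if (inherits(tree, c("phylo", "multiPhylo")))
      prior_table <- tree_partition_prior(tree, a_alpha = hyper$a_alpha,
                                          b_alpha = hyper$b_alpha,
                                          founders = diplotypes$founders)
    else stop("'tree' must be a phylo, multiPhylo or partition_prior")
    if (prior_table$J != length(diplotypes$founders))
      stop("tree prior and diplotypes disagree on the number of founders")
  }
  if (prior == "fixed") {
    if (is.null(fixed_series)) stop("'fixed_series' is required with prior = 'fixed'")
    fixed_series <- allelic_series(fixed_series)
    if (length(fixed_series) != length(diplotypes$founders))
      stop("'fixed_series' must cover all founders")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  ctx <- make_context(y, diplotypes, covariates, hyper, prior, prior_table,
                      fixed_series, fix_phi, fix_alpha)

  # initialization: one-allele series (tree: highest-prior series), diplotype
  # prior argmax, phi = 0.5, alpha at its prior mean
  state <- list(
    assign = switch(prior,
                    crp = rep(0L, ctx$J),
                    tree = unclass(series_from_key(prior_table$keys[1L])),
                    fixed = unclass(fixed_series)),
    states = max.col(diplotypes$probs, ties.method = "first"),
    mu = mean(y), gamma = rep(0, if (is.null(covariates)) 0 else ncol(covariates)),
    sigma = stats::sd(y) + 1e-12, eta = sqrt(0.5), psi = 0.5,
    phi = if (is.null(fix_phi)) 0.5 else fix_phi,
    alpha = if (is.null(fix_alpha)) ctx$hyper$a_alpha / ctx$hyper$b_alpha
            else fix_alpha)
  state$K <- max(state$assign) + 1L
  state$beta <- rep(0, state$K - 1L)
  gctx <- refresh_grams(ctx, state$states)

  keys <- character(n_iter); Kv <- integer(n_iter)
  mu <- sigma <- phi <- alpha <- qb <- numeric(n_iter)
  bhap <- matrix(NA_real_, n_iter, ctx$J,
                 dimnames = list(NULL, ctx$founders))
  q_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  gmat <- if (q_cov > 0L) matrix(NA_real_, n_iter, q_cov) else NULL
  Dm <- if (store_diplotypes) matrix(NA_integer_, n_iter, ctx$N) else NULL

  for (it in seq_len(n_iter)) {
    state <- switch(prior,
                    crp = step_partition_crp(ctx, gctx, state),
                    tree = step_partition_tree(ctx, gctx, state),
                    fixed = state)
    state <- step_effects(ctx, gctx, state)
    state <- step_phi(ctx, gctx, state)
    upd <- step_diplotypes(ctx, gctx, state)
    state <- upd$state; gctx <- upd$gctx
    keys[it] <- series_key(allelic_series(state$assign))
    Kv[it] <- state$K
    mu[it] <- state$mu; sigma[it] <- state$sigma; phi[it] <- state$phi
    alpha[it] <- state$alpha
    qb[it] <- sum(state$beta^2) / state$sigma^2
    bhap[it, ] <- haplotype_effects(ctx, state)
    if (q_cov > 0L) gmat[it, ] <- state$gamma
    if (store_diplotypes) Dm[it, ] <- state$states
    if (verbose && it %% 1000L == 0L)
      message("iteration ", it, ": K = ", state$K)
  }
  structure(list(series = keys, K = Kv, mu = mu, sigma = sigma, phi = phi,
                 alpha = alpha, qb = qb, bhap = bhap, gamma = gmat,
                 diplotype_states = Dm,
                 y = y, diplotypes = diplotypes, covariates = covariates,
                 prior_mode = prior, prior_table = prior_table,
                 fixed_series = fixed_series, hyper = ctx$hyper,
                 n_iter = n_iter, burn_in = burn_in, seed = seed,
                 fix_phi = fix_phi, fix_alpha = fix_alpha,
                 founders = ctx$founders, call = match.call()),
            class = "series_fit")
}
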