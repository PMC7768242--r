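# Marginal likelihood estimation from Gibbs output, via a Chib-style block
# decomposition at the fixed ordinate (M*, phi*):
#   log m(y) = log p(y | M*, phi*) + log p(M*) + log p(phi*)
#            - log p(M* | y) - log p(phi* | M*, y),
# with the effects and error scale analytically collapsed in p(y | M, phi).
# p(M*|y) is the posterior frequency from the main chain; p(phi*|M*,y) is a
# Rao-Blackwell average of the one-dimensional conditional p(phi | beta,
# sigma) over a reduced run with the series fixed at M*. Under improper
# error/intercept priors the estimate is defined up to a constant shared by
# all models with the same flat block, so only differences (Bayes factors)
# between such models are meaningful.

half_t_log_density <- function(phi, v) log(2) + stats::dt(phi, df = v, log = TRUE)

# Rao-Blackwell estimate of the posterior density of phi at phi_star, from
# per-iteration (K - 1, beta'beta / sigma^2) records of a chain with M fixed.
phi_posterior_density <- function(phi_star, k_eff, qb, v, n_grid = 800L) {
  u <- seq(log(1e-6), log(1e4), length.out = n_grid)
  lht <- half_t_log_density(exp(u), v)
  vals <- vapply(seq_along(qb), function(g) {
    lf <- -k_eff[g] * u - qb[g] * exp(-2 * u) / 2 + lht + u   # + u: d phi = phi du
    mx <- max(lf)
    Z <- exp(mx) * sum(exp(lf - mx)) * (u[2L] - u[1L])
    lfs <- -k_eff[g] * log(phi_star) - qb[g] / (2 * phi_star^2) +
      half_t_log_density(phi_star, v)
    exp(lfs) / Z
  }, numeric(1))
  vals
}

batch_se <- function(x, n_batch = 30L) {
  n <- length(x)
  n_batch <- min(n_batch, n)
  b <- floor(n / n_batch)
  m <- vapply(seq_len(n_batch), function(i) mean(x[((i - 1L) * b + 1L):(i * b)]),
              numeric(1))
  stats::sd(m) / sqrt(n_batch)
}

log_prior_series <- function(fit, series) {
  sz <- series_sizes(series)
  K <- length(sz)
  switch(fit$prior_mode,
         fixed = 0,
         tree = {
           i <- match(series_key(allelic_series(series)), fit$prior_table$keys)
           if (is.na(i)) -Inf else fit$prior_table$log_prob[i]
         },
         crp = {
           if (!is.null(fit$fix_alpha))
             return(crp_log_density(series, fit$fix_alpha))
           eK <- crp_ek_marginal(K, length(fit$founders),
                                 fit$hyper$a_alpha, fit$hyper$b_alpha)
           log(eK) + sum(lgamma(sz))
         })
}

# Collapsed likelihood ordinate with the diplotype states marginalized: exact
# for point-mass priors, otherwise a Monte-Carlo average over prior draws.
loglik_ordinate <- function(fit, series, phi, n_dip_draws) {
  dip <- fit$diplotypes
  if (is_point_mass(dip)) {
    states <- max.col(dip$probs, ties.method = "first")
    return(list(value = collapsed_loglik(fit$y, states, dip, series, phi,
                                         fit$hyper, fit$covariates), se = 0))
  }
  ll <- vapply(seq_len(n_dip_draws), function(r) {
    states <- vapply(seq_len(nrow(dip$probs)), function(i)
      sample.int(ncol(dip$probs), 1L, prob = dip$probs[i, ]), integer(1))
    collapsed_loglik(fit$y, states, dip, series, phi, fit$hyper, fit$covariates)
  }, numeric(1))
  mx <- max(ll)
  w <- exp(ll - mx)
  est <- mx + log(mean(w))
  list(value = est, se = stats::sd(w) / (mean(w) * sqrt(n_dip_draws)))
}

#' Chib marginal likelihood estimate for an allele-based model fit
#'
#' Estimates the log marginal likelihood of the fitted model from the Gibbs
#' output using a Chib-style decomposition at a high-posterior ordinate: the
#' chain's MAP allelic series and a high-density value of the relative effect
#' scale. One reduced run with the series fixed at the MAP supplies the
#' Rao-Blackwellized posterior ordinate of the effect scale. Under the
#' default improper priors the value is reported up to a constant shared by
#' all models with the same individuals and flat (intercept/covariate) block,
#' which cancels in Bayes factors between such models.
#'
#' @param fit a [series_fit].
#' @param n_reduced iterations for the reduced run (series fixed at the MAP).
#' @param n_dip_draws Monte-Carlo draws for the diplotype-marginalized
#'   likelihood ordinate when diplotypes are uncertain.
#' @param seed seed for the reduced run and ordinate Monte Carlo.
#' @return An object of class `evidence_estimate` with `log_marginal`
#'   (relative when priors are improper), `mc_se`, the `ordinate`, and the
#'   flat-block signature used to validate Bayes factor comparisons.
#' @export
marginal_likelihood <- function(fit, n_reduced = 4000, n_dip_draws = 200,
                                seed = NULL) {
  idx <- post_idx(fit)
  tab <- sort(table(fit$series[idx]), decreasing = TRUE)
  map_key <- names(tab)[1L]
  series <- series_from_key(map_key)
  p_map <- as.numeric(tab[1L]) / length(idx)
  if (p_map <= 0) stop("ordinate has zero posterior mass; run a longer chain")
  lp_M_post <- log(p_map)
  se_M <- if (fit$prior_mode == "fixed") 0 else
    batch_se(as.numeric(fit$series[idx] == map_key)) / p_map
  lp_M_prior <- log_prior_series(fit, series)

  if (!is.null(fit$fix_phi)) {
    ord <- loglik_ordinate(fit, series, fit$fix_phi, n_dip_draws)
    est <- ord$value + lp_M_prior - lp_M_post
    return(new_evidence(est, sqrt(ord$se^2 + se_M^2), map_key, fit$fix_phi,
                        0L, fit))
  }
  reduced <- if (fit$prior_mode == "fixed") fit else
    series_fit(fit$y, fit$diplotypes, prior = "fixed", fixed_series = series,
               covariates = fit$covariates, hyper = fit$hyper,
               n_iter = n_reduced, seed = seed, fix_alpha = fit$fix_alpha)
  ridx <- post_idx(reduced)
  phi_star <- stats::median(reduced$phi[ridx])
  k_eff <- reduced$K[ridx] - 1L
  dens <- phi_posterior_density(phi_star, k_eff, reduced$qb[ridx], fit$hyper$v)
  lp_phi_post <- log(mean(dens))
  se_phi <- batch_se(dens) / mean(dens)
  lp_phi_prior <- half_t_log_density(phi_star, fit$hyper$v)
  if (!is.null(seed)) set.seed(seed + 1L)
  ord <- loglik_ordinate(fit, series, phi_star, n_dip_draws)
  est <- ord$value + lp_M_prior + lp_phi_prior - lp_M_post - lp_phi_post
  new_evidence(est, sqrt(ord$se^2 + se_M^2 + se_phi^2), map_key, phi_star,
               if (fit$prior_mode == "fixed") 0L else n_reduced, fit)
}

new_evidence <- function(log_marginal, mc_se, map_key, phi_star, n_reduced, fit) {
  structure(list(log_marginal = log_marginal, mc_se = mc_se,
                 ordinate = list(series = map_key, phi = phi_star),
                 n_reduced_runs = as.integer(n_reduced > 0L),
                 improper = fit$hyper$improper_scale,
                 block = list(N = length(fit$y),
                              qf = 1L + if (is.null(fit$covariates)) 0L else
                                ncol(fit$covariates)),
                 model = fit$prior_mode),
            class = "evidence_estimate")
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat("Chib marginal likelihood estimate (", x$model, " model)\n", sep = "")
  cat(sprintf("  log m(y) = %.4f  (MC se %.4f)%s\n", x$log_marginal, x$mc_se,
              if (x$improper) "  [up to a constant shared by models with the same flat block]"
              else ""))
  cat("  ordinate: series", x$ordinate$series, ", phi =",
      format(x$ordinate$phi, digits = 4), "\n")
  invisible(x)
}

#' Log Bayes factor between two models
#'
#' Difference of two Chib log marginal likelihood estimates. Under improper
#' error/intercept priors the unknown common constants cancel only between
#' models fit to the same individuals with the same flat block, which is
#' checked.
#'
#' @param est1,est2 [marginal_likelihood()] estimates.
#' @return List with `log_bf` (in favor of `est1`) and combined `mc_se`.
#' @export
bayes_factor <- function(est1, est2) {
  if (est1$improper != est2$improper ||
      !identical(est1$block, est2$block))
    stop("Bayes factor undefined: models have different improper prior blocks")
  list(log_bf = est1$log_marginal - est2$log_marginal,
       mc_se = sqrt(est1$mc_se^2 + est2$mc_se^2))
}
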