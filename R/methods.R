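post_idx <- function(fit) {
  if (fit$burn_in >= fit$n_iter) stop("burn-in leaves an empty chain")
  (fit$burn_in + 1L):fit$n_iter
}

#' @export
print.series_fit <- function(x, ...) {
  idx <- post_idx(x)
  tab <- sort(table(x$series[idx]), decreasing = TRUE)
  cat("Allele-based QTL model fit (", x$prior_mode, " prior)\n", sep = "")
  cat("  ", length(x$y), "individuals,", length(x$founders), "founder haplotypes\n")
  cat("  ", x$n_iter, "Gibbs iterations (burn-in", x$burn_in, ")\n")
  cat("  MAP allelic series:", names(tab)[1L],
      sprintf("(posterior probability %.3f)\n", tab[1L] / length(idx)))
  cat(sprintf("  Posterior expected number of alleles: %.2f\n",
              mean(x$K[idx])))
  invisible(x)
}

#' Posterior summary of an allele-based model fit
#'
#' Tabulates the visited allelic series and the posterior distribution of the
#' number of alleles, and computes haplotype effect posteriors with highest
#' posterior density intervals (shortest contiguous interval on the sorted
#' samples).
#'
#' @param object a [series_fit].
#' @param hpd_level HPD interval level (default 0.95).
#' @param top number of top series to tabulate.
#' @param ... unused.
#' @return An object of class `summary.series_fit` with elements
#'   `top_series` (data frame: series, K, probability), `k_distribution`,
#'   `expected_k`, `effects` (posterior mean haplotype effects), and
#'   `hpd` (J x 2).
#' @export
summary.series_fit <- function(object, hpd_level = 0.95, top = 10L, ...) {
  idx <- post_idx(object)
  if (length(idx) == 0L) stop("empty chain")
  tab <- sort(table(object$series[idx]), decreasing = TRUE) / length(idx)
  top_series <- data.frame(
    series = names(tab),
    K = vapply(names(tab), function(k) attr(series_from_key(k), "K"), integer(1)),
    probability = as.numeric(tab), row.names = NULL)
  kd <- tabulate(object$K[idx], nbins = length(object$founders)) / length(idx)
  names(kd) <- seq_along(kd)
  B <- object$bhap[idx, , drop = FALSE]
  hpd <- t(apply(B, 2L, hpd_interval, level = hpd_level))
  colnames(hpd) <- c("lower", "upper")
  structure(list(top_series = utils::head(top_series, top),
                 n_series = nrow(top_series),
                 k_distribution = kd, expected_k = sum(seq_along(kd) * kd),
                 effects = colMeans(B), hpd = hpd, hpd_level = hpd_level,
                 prior_mode = object$prior_mode),
            class = "summary.series_fit")
}

#' @export
print.summary.series_fit <- function(x, ...) {
  cat("Top posterior allelic series (", x$n_series, " visited):\n", sep = "")
  print(transform(x$top_series, probability = round(probability, 4)))
  cat(sprintf("\nPosterior expected number of alleles: %.2f\n", x$expected_k))
  cat("Posterior distribution of K:\n")
  print(round(x$k_distribution, 4))
  cat("\nHaplotype effects (posterior mean and ",
      format(100 * x$hpd_level), "% HPD):\n", sep = "")
  print(round(cbind(mean = x$effects, x$hpd), 4))
  invisible(x)
}

# shortest contiguous interval containing `level` of the samples
hpd_interval <- function(x, level = 0.95) {
  s <- sort(x)
  n <- length(s)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(s[1L], s[n]))
  i <- which.min(s[k:n] - s[1:(n - k + 1L)])
  c(s[i], s[i + k - 1L])
}

#' @export
coef.series_fit <- function(object, ...) {
  colMeans(object$bhap[post_idx(object), , drop = FALSE])
}

#' @export
fitted.series_fit <- function(object, ...) {
  A <- additive_map(length(object$founders), object$founders)
  states <- max.col(object$diplotypes$probs, ties.method = "first")
  m <- drop(A[states, , drop = FALSE] %*% coef(object))
  if (!is.null(object$covariates))
    m <- m + drop(as.matrix(object$covariates) %*%
                    colMeans(object$gamma[post_idx(object), , drop = FALSE]))
  m
}

#' @export
residuals.series_fit <- function(object, ...) object$y - fitted(object)

#' Posterior predictive draws from a fitted allele-based model
#'
#' Draws `nsim` phenotype vectors by sampling posterior iterations and
#' simulating from the normal likelihood at each sampled state (using the
#' prior-argmax diplotype states).
#'
#' @param object a [series_fit].
#' @param nsim number of replicate phenotype vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @export
simulate.series_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample(post_idx(object), nsim, replace = TRUE)
  A <- additive_map(length(object$founders), object$founders)
  states <- max.col(object$diplotypes$probs, ties.method = "first")
  out <- vapply(idx, function(it) {
    m <- drop(A[states, , drop = FALSE] %*% object$bhap[it, ])
    stats::rnorm(length(m), m, object$sigma[it])
  }, numeric(length(object$y)))
  as.data.frame(out)
}

#' @export
plot.series_fit <- function(x, ...) {
  s <- summary(x)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(s$k_distribution, xlab = "Number of alleles K",
                    ylab = "Posterior probability",
                    main = "Allelic series size")
  J <- length(s$effects)
  graphics::plot(seq_len(J), s$effects, ylim = range(s$hpd), xaxt = "n",
                 xlab = "Founder haplotype", ylab = "Effect",
                 main = "Haplotype effects", pch = 19)
  graphics::axis(1, at = seq_len(J), labels = names(s$effects))
  graphics::segments(seq_len(J), s$hpd[, 1L], seq_len(J), s$hpd[, 2L])
  invisible(x)
}

#' Score a fit against the simulated truth
#'
#' Computes the three simulation metrics: whether the maximum a posteriori
#' allelic series equals the truth (0-1 accuracy), the posterior mass on the
#' true series (posterior certainty), and the mean squared error of the
#' posterior haplotype effects against the true effects, averaged over
#' posterior samples. Effects are centered before the MSE because true allele
#' effects are zero-mean while posterior haplotype effects carry the
#' intercept.
#'
#' @param fit a [series_fit].
#' @param truth_series the generating [allelic_series].
#' @param truth_effects length-J vector of true haplotype effects.
#' @return List with `accuracy01`, `certainty`, `mse`.
#' @export
evaluate_against_truth <- function(fit, truth_series, truth_effects) {
  idx <- post_idx(fit)
  key <- series_key(allelic_series(truth_series))
  tab <- table(fit$series[idx])
  map_key <- names(tab)[which.max(tab)]
  tr <- truth_effects - mean(truth_effects)
  B <- fit$bhap[idx, , drop = FALSE]
  Bc <- B - rowMeans(B)
  mse <- mean(rowMeans(sweep(Bc, 2L, tr)^2))
  list(accuracy01 = as.integer(map_key == key),
       certainty = as.numeric(if (key %in% names(tab)) tab[[key]] / length(idx) else 0),
       mse = mse)
}
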