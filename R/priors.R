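#' @title Prior distributions over the allelic series
#' @description Constructors and operations for normalized probability tables
#'   over all partitions of the J founder haplotypes: the CRP (Ewens)
#'   marginal, the tree-informed prior obtained by enumerating functional
#'   mutations on a coalescent phylogeny, averages over tree samples, and
#'   variant-consistent restrictions.
#' @name partition_prior
NULL

new_partition_prior <- function(keys, prob, J, source, renormalize = FALSE) {
  prob <- as.numeric(prob)
  keep <- prob > 0
  keys <- keys[keep]; prob <- prob[keep]
  s <- sum(prob)
  if (!renormalize && abs(s - 1) > 1e-8)
    warning("partition prior table sums to ", format(s), "; renormalizing")
  prob <- prob / s
  o <- order(prob, decreasing = TRUE)
  structure(list(keys = keys[o], prob = prob[o], log_prob = log(prob[o]),
                 J = as.integer(J), source = source),
            class = "partition_prior")
}

#' @export
print.partition_prior <- function(x, n = 6L, ...) {
  cat("Partition prior over allelic series (J =", x$J, ", source:", x$source,
      ")\n", length(x$keys), "series with positive mass; top", min(n, length(x$keys)),
      ":\n")
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' @export
as.data.frame.partition_prior <- function(x, ...) {
  data.frame(series = x$keys,
             K = vapply(x$keys, function(k) attr(series_from_key(k), "K"), integer(1)),
             probability = x$prob, row.names = NULL)
}

#' Ewens (CRP) log density of an allelic series
#'
#' The Chinese restaurant process probability of a partition with block sizes
#' \eqn{J_1, ..., J_K}:
#' \eqn{p(M|\alpha) = \Gamma(\alpha)\Gamma(\alpha+J)^{-1} \alpha^K \prod_k \Gamma(J_k)}.
#'
#' @param series an [allelic_series] (or assignment vector).
#' @param alpha concentration parameter, > 0.
#' @return Log probability.
#' @export
crp_log_density <- function(series, alpha) {
  if (alpha <= 0) stop("'alpha' must be positive")
  sz <- series_sizes(series)
  J <- sum(sz)
  lgamma(alpha) - lgamma(alpha + J) + length(sz) * log(alpha) + sum(lgamma(sz))
}

#' CRP conditional assignment probabilities
#'
#' Probability that a haplotype joins each existing allele (proportional to the
#' number of haplotypes already assigned to it) or founds a new allele
#' (proportional to `alpha`), given the assignment of the other haplotypes.
#'
#' @param sizes integer vector of existing allele sizes (may be empty).
#' @param alpha concentration parameter, > 0.
#' @return Probability vector of length `length(sizes) + 1`; the last entry is
#'   the probability of a new allele.
#' @export
crp_conditional <- function(sizes, alpha) {
  if (alpha <= 0) stop("'alpha' must be positive")
  w <- c(sizes, alpha)
  w / sum(w)
}

#' CRP partition prior table
#'
#' Enumerates all partitions of `J` haplotypes and tabulates their CRP
#' probabilities, either at a fixed concentration `alpha` or with `alpha`
#' marginalized against its Gamma(`a_alpha`, `b_alpha`) prior (by adaptive
#' quadrature; the integral depends on a partition only through its number of
#' blocks, so only J one-dimensional integrals are needed).
#'
#' @param J number of founder haplotypes (2..12).
#' @param alpha fixed concentration parameter, or `NULL` to marginalize.
#' @param a_alpha,b_alpha gamma shape/rate used when `alpha` is `NULL`.
#' @param founders optional founder names.
#' @return A [partition_prior].
#' @export
crp_partition_prior <- function(J, alpha = NULL, a_alpha = 1, b_alpha = NULL,
                                founders = NULL) {
  J <- as.integer(J)
  parts <- all_series(J, founders)
  keys <- vapply(parts, series_key, character(1))
  if (!is.null(alpha)) {
    lp <- vapply(parts, crp_log_density, numeric(1), alpha = alpha)
    return(new_partition_prior(keys, exp(lp), J, "crp_fixed_alpha"))
  }
  if (is.null(b_alpha)) b_alpha <- elicit_b_alpha(J, a_alpha, 0.5)
  eK <- vapply(1:J, crp_ek_marginal, numeric(1), J = J, a_alpha = a_alpha,
               b_alpha = b_alpha)
  prob <- vapply(parts, function(p) {
    sz <- series_sizes(p)
    eK[length(sz)] * exp(sum(lgamma(sz)))
  }, numeric(1))
  new_partition_prior(keys, prob, J, "crp_marginal")
}

# --- tree-informed prior ------------------------------------------------------

# Per-config probabilities over all 2^(2J-2) branch mutation configurations,
# and the partition key each config implies. Shared by the fixed-alpha and
# alpha-marginalized tree priors and by the conditional simulator.
tree_config_table <- function(tree, founders = NULL) {
  cb <- canonical_branches(tree, founders)
  n <- cb$n_branch
  if (n > 22L)
    stop("exact enumeration over 2^(2J-2) branch configurations is ",
         "unsupported for J > 12 (got J = ", n / 2 + 1, "); the allelic ",
         "series prior is intractable for this many founders")
  m_all <- 0:(2^n - 1L)
  sig <- vapply(cb$leaf_paths, function(p) bitwAnd(m_all, as.integer(p)),
                integer(length(m_all)))
  keys <- apply(sig, 1L, function(s) paste(match(s, unique(s)) - 1L, collapse = ","))
  list(cb = cb, masks = m_all, keys = keys, n = n)
}

config_probs_fixed_alpha <- function(tab, alpha) {
  h <- 0.5 * alpha * tab$cb$lengths
  lq0 <- -h
  lq1 <- ifelse(h > 0, log1p(-exp(-h)), -Inf)
  lp <- numeric(length(tab$masks))
  for (i in seq_len(tab$n)) {
    on <- bitwAnd(tab$masks, as.integer(2^(i - 1L))) > 0L
    lp <- lp + ifelse(on, lq1[i], lq0[i])
  }
  exp(lp)
}

config_probs_marginal <- function(tab, a_alpha, b_alpha) {
  n <- tab$n
  len <- tab$cb$lengths
  # total length L_W of every branch subset W, by bitmask dynamic programming
  L <- numeric(2^n)
  for (i in seq_len(n)) {
    bit <- as.integer(2^(i - 1L))
    has <- bitwAnd(tab$masks, bit) > 0L
    L[has] <- L[tab$masks[has] - bit + 1L] + len[i]
  }
  f <- (b_alpha / (b_alpha + 0.5 * L))^a_alpha
  # signed superset (Moebius) transform:
  # f[Z] <- sum_{W >= Z} (-1)^{|W \ Z|} f_orig[W]
  for (i in seq_len(n)) {
    bit <- as.integer(2^(i - 1L))
    no <- bitwAnd(tab$masks, bit) == 0L
    f[no] <- f[no] - f[tab$masks[no] + bit + 1L]
  }
  # p(b) = transformed value at the complement (unmutated set) of b
  pmax(f[(2^n - 1L) - tab$masks + 1L], 0)
}

#' Tree-informed prior over allelic series
#'
#' Enumerates all `2^(2J-2)` branch mutation configurations of a coalescent
#' tree, maps each to the allelic series it implies, and accumulates the
#' configuration probabilities -- either at a fixed functional mutation rate
#' `alpha`, or (default) with the rate marginalized exactly against its
#' Gamma(`a_alpha`, `b_alpha`) prior via the inclusion-exclusion closed form,
#' evaluated for all configurations at once by a signed subset transform.
#' Series incompatible with the tree receive probability zero.
#'
#' @param tree a rooted binary [ape::phylo] with branch lengths in coalescent
#'   units (or a `multiPhylo`; the per-tree priors are then averaged, the
#'   tree-sample workflow for posterior tree distributions).
#' @param a_alpha,b_alpha gamma shape/rate for the mutation rate. `b_alpha =
#'   NULL` elicits the rate so the marginalized CRP puts 50% mass on K = 1.
#' @param alpha fixed mutation rate; overrides marginalization when given.
#' @param founders founder names fixing leaf order (default sorted tip labels).
#' @return A [partition_prior].
#' @export
tree_partition_prior <- function(tree, a_alpha = 1, b_alpha = NULL,
                                 alpha = NULL, founders = NULL) {
  if (inherits(tree, "multiPhylo"))
    return(average_partition_priors(lapply(tree, tree_partition_prior,
                                           a_alpha = a_alpha, b_alpha = b_alpha,
                                           alpha = alpha, founders = founders)))
  tab <- tree_config_table(tree, founders)
  if (is.null(alpha)) {
    if (is.null(b_alpha))
      b_alpha <- elicit_b_alpha(length(tab$cb$founders), a_alpha, 0.5)
    p <- config_probs_marginal(tab, a_alpha, b_alpha)
    src <- "tree"
  } else {
    if (alpha <= 0) stop("'alpha' must be positive")
    p <- config_probs_fixed_alpha(tab, alpha)
    src <- "tree_fixed_alpha"
  }
  agg <- rowsum(p, tab$keys)
  new_partition_prior(rownames(agg), agg[, 1L], length(tab$cb$founders), src)
}

#' Average partition priors over a sample of trees
#'
#' Arithmetic mean of the per-tree prior tables, renormalized; approximates
#' the allelic series prior under an uncertain phylogeny by averaging over
#' posterior tree samples.
#'
#' @param priors a non-empty list of [partition_prior] objects over the same J.
#' @return A [partition_prior] with source `"tree_averaged"`.
#' @export
average_partition_priors <- function(priors) {
  if (length(priors) == 0L) stop("'priors' must be a non-empty list")
  J <- priors[[1L]]$J
  if (!all(vapply(priors, function(p) p$J, integer(1)) == J))
    stop("all priors must be over the same number of haplotypes")
  keys <- unique(unlist(lapply(priors, function(p) p$keys)))
  acc <- numeric(length(keys))
  for (p in priors) {
    i <- match(p$keys, keys)
    acc[i] <- acc[i] + p$prob
  }
  new_partition_prior(keys, acc / length(priors), J,
                      if (length(priors) == 1L) priors[[1L]]$source else "tree_averaged")
}

#' Restrict a partition prior to series consistent with a causal variant
#'
#' Keeps only allelic series that refine the functional distinctions implied
#' by a known variant (every pair of haplotypes the variant separates remains
#' separated), then renormalizes.
#'
#' @param prior a [partition_prior].
#' @param variant an [allelic_series] giving the variant's haplotype partition.
#' @return A [partition_prior] with source `"restricted"`.
#' @export
restrict_prior <- function(prior, variant) {
  variant <- allelic_series(variant)
  if (length(variant) != prior$J) stop("'variant' must partition the same J haplotypes")
  keep <- vapply(prior$keys, function(k) series_refines(series_from_key(k), variant),
                 logical(1))
  if (!any(keep)) stop("no series in the prior refines the variant partition")
  new_partition_prior(prior$keys[keep], prior$prob[keep], prior$J, "restricted",
                      renormalize = TRUE)
}

#' Prior distribution of the number of alleles
#'
#' @param prior a [partition_prior].
#' @return Numeric vector of length J; entry K is the prior probability of K
#'   functional alleles.
#' @export
prior_k_distribution <- function(prior) {
  K <- vapply(prior$keys, function(k) attr(series_from_key(k), "K"), integer(1))
  out <- numeric(prior$J)
  for (k in seq_len(prior$J)) out[k] <- sum(prior$prob[K == k])
  names(out) <- seq_len(prior$J)
  out
}

#' Prior probability of the null (one-allele) series under the marginalized CRP
#'
#' Computes \eqn{E_\alpha[\prod_{j=1}^{J-1} j/(\alpha+j)]} by adaptive
#' quadrature against the Gamma(`a_alpha`, `b_alpha`) prior on the
#' concentration parameter.
#'
#' @param J number of founder haplotypes.
#' @param a_alpha,b_alpha gamma shape/rate, > 0.
#' @return Probability that K = 1 a priori.
#' @export
crp_null_mass <- function(J, a_alpha, b_alpha) {
  if (a_alpha <= 0 || b_alpha <= 0) stop("'a_alpha' and 'b_alpha' must be positive")
  expect_gamma(function(a) exp(lgamma(a + 1) - lgamma(a + J) + lgamma(J)),
               a_alpha, b_alpha)
}

# E_alpha[ Gamma(alpha) / Gamma(alpha + J) * alpha^K ] against the gamma
# prior (depends on a series only through its number of blocks K).
crp_ek_marginal <- function(K, J, a_alpha, b_alpha) {
  expect_gamma(function(a) exp(lgamma(a) - lgamma(a + J) +
                                 K * log(pmax(a, 1e-12))),
               a_alpha, b_alpha)
}

# E[g(alpha)] under alpha ~ Gamma(shape, rate), by quantile-transform
# quadrature (integrand bounded on (0, 1)) split at the quantiles of a fixed
# alpha grid so the transition region of g is always resolved, whatever the
# prior scale.
expect_gamma <- function(g, shape, rate) {
  f <- function(t) g(pmin(stats::qgamma(t, shape, rate = rate), 1e12))
  br <- stats::pgamma(10^seq(-6, 6, by = 2), shape, rate = rate)
  pts <- sort(unique(pmin(pmax(c(0, br, 1), 0), 1)))
  pts <- pts[c(TRUE, diff(pts) > 1e-14)]
  tot <- 0
  for (i in seq_len(length(pts) - 1L))
    tot <- tot + stats::integrate(f, pts[i], pts[i + 1L], rel.tol = 1e-10,
                                  abs.tol = 1e-12)$value
  tot
}

#' Elicit the concentration rate for a target null-model mass
#'
#' Finds `b_alpha` such that the marginalized CRP prior probability of the
#' one-allele series equals `target` (e.g. 0.5, giving b_alpha ~ 2.33 at
#' J = 8 with a_alpha = 1). The null mass is monotone increasing in `b_alpha`,
#' so a bracketed root search suffices.
#'
#' @param J number of founder haplotypes.
#' @param a_alpha gamma shape, > 0.
#' @param target desired prior probability of K = 1, in (0, 1).
#' @return The rate `b_alpha`.
#' @export
elicit_b_alpha <- function(J, a_alpha = 1, target = 0.5) {
  if (target <= 0 || target >= 1) stop("'target' must be in (0, 1)")
  f <- function(b) crp_null_mass(J, a_alpha, b) - target
  lo <- 1e-6; hi <- 10
  while (f(hi) < 0 && hi < 1e12) hi <- hi * 10
  while (f(lo) > 0 && lo > 1e-12) lo <- lo / 10
  if (f(hi) < 0 || f(lo) > 0) stop("target null mass unattainable")
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}
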