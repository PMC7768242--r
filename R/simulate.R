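# Coalescent simulation protocol for evaluating allelic series inference:
# sample a Kingman tree over the founders, draw an allelic series conditional
# on a target number of alleles from the tree-induced distribution, assign
# equally spaced allele effects scaled to the target QTL effect size, and add
# exactly rescaled normal error.

#' Sample a Kingman coalescent tree over founder haplotypes
#'
#' Standard Kingman construction: starting from the `J` leaves, repeatedly
#' merge a uniformly chosen pair of lineages, with inter-coalescence times
#' exponential with rate `choose(k, 2)` while `k` lineages remain. Branch
#' lengths are in coalescent units.
#'
#' @param J number of leaves (J >= 2).
#' @param founders leaf labels (default `LETTERS[1:J]`).
#' @return A rooted binary ultrametric [ape::phylo].
#' @export
sample_coalescent_tree <- function(J, founders = NULL) {
  J <- as.integer(J)
  if (J < 2L) stop("'J' must be at least 2")
  if (is.null(founders)) founders <- make_founder_names(J)
  lab <- as.list(founders)
  height <- rep(0, J)
  t <- 0
  while (length(lab) > 1L) {
    k <- length(lab)
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    merged <- sprintf("(%s:%.12g,%s:%.12g)", lab[[pair[1L]]],
                      t - height[pair[1L]], lab[[pair[2L]]], t - height[pair[2L]])
    lab <- c(lab[-pair], merged)
    height <- c(height[-pair], t)
  }
  ape::read.tree(text = paste0(lab[[1L]], ";"))
}

#' Sample an allelic series conditional on the number of alleles
#'
#' Draws from the tree-induced allelic series distribution at fixed mutation
#' rate `alpha`, restricted to series with exactly `K` alleles and
#' renormalized (the number of alleles is deterministic given the series, so
#' conditioning reduces to restriction).
#'
#' @param tree a rooted binary coalescent [ape::phylo].
#' @param alpha functional mutation rate (> 0).
#' @param K target number of alleles.
#' @param founders founder names (default sorted tip labels).
#' @return An [allelic_series].
#' @export
sample_series_given_k <- function(tree, alpha, K, founders = NULL) {
  prior <- tree_partition_prior(tree, alpha = alpha, founders = founders)
  kk <- vapply(prior$keys, function(k) attr(series_from_key(k), "K"), integer(1))
  keep <- kk == K
  if (!any(keep))
    stop("no series with K = ", K, " alleles has positive mass under this tree")
  key <- if (sum(keep) == 1L) prior$keys[keep] else
    sample(prior$keys[keep], 1L, prob = prior$prob[keep])
  series_from_key(key, prior_founders(prior, tree, founders))
}

prior_founders <- function(prior, tree, founders) {
  if (!is.null(founders)) founders else sort(tree$tip.label)
}

#' Balanced homozygous experimental design
#'
#' `N` individuals split as evenly as possible across the `J` homozygous
#' diplotype states (the first `N mod J` founders receive one extra), with
#' point-mass diplotype priors (states known).
#'
#' @param J number of founders.
#' @param N number of individuals.
#' @param founders founder names.
#' @return List with `states` (length N, homozygous state indices) and
#'   `diplotypes` (a point-mass [diplotype_priors]).
#' @export
balanced_homozygous_design <- function(J, N, founders = NULL) {
  if (is.null(founders)) founders <- make_founder_names(J)
  counts <- rep(N %/% J, J) + (seq_len(J) <= N %% J)
  states <- rep(seq_len(J), times = counts)
  S <- J + (J * (J - 1L)) %/% 2L
  probs <- matrix(0, N, S)
  probs[cbind(seq_len(N), states)] <- 1
  list(states = states, diplotypes = diplotype_priors(probs, founders))
}

#' Simulate a single-locus QTL experiment
#'
#' Implements the full generating protocol: a Kingman coalescent tree over
#' the founders (unless supplied), an allelic series drawn conditional on `K`
#' from the tree at mutation rate `alpha`, `K` equally spaced allele effects
#' zero-centered and scaled so their population variance equals `h2`, and a
#' standard normal error vector exactly centered and rescaled to population
#' variance `1 - h2`; phenotypes are `y = D A M beta_alle + eps` under a
#' balanced homozygous design.
#'
#' @param J number of founder haplotypes (default 8).
#' @param N number of individuals (default 400).
#' @param K true number of functional alleles (1..J).
#' @param h2 QTL effect size: proportion of phenotype variance explained,
#'   in `[0, 1]` (`K = 1` forces `h2 = 0`).
#' @param alpha functional mutation rate used when drawing the series.
#' @param tree optional known tree (default: a fresh coalescent draw).
#' @param series optional known series (overrides the conditional draw).
#' @param seed optional RNG seed.
#' @param founders founder names.
#' @return An object of class `qtl_sim`: `tree`, `series`, `beta_alle`,
#'   `bhap` (true haplotype effects), `y`, `states`, `diplotypes`, and the
#'   generating parameters.
#' @export
simulate_qtl <- function(J = 8, N = 400, K, h2, alpha = 1, tree = NULL,
                         series = NULL, seed = NULL, founders = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (K < 1 || K > J) stop("'K' must be in 1..J")
  if (h2 < 0 || h2 > 1) stop("'h2' must be in [0, 1]")
  if (K == 1 && h2 > 0)
    stop("a one-allele series has no detectable signal; use h2 = 0 with K = 1")
  if (is.null(founders)) founders <- make_founder_names(J)
  if (is.null(tree)) tree <- sample_coalescent_tree(J, founders)
  if (is.null(series)) series <- sample_series_given_k(tree, alpha, K, founders)
  series <- allelic_series(series, founders)
  if (attr(series, "K") != K) stop("'series' does not have K alleles")
  des <- balanced_homozygous_design(J, N, founders)
  beta_alle <- if (K == 1) 0 else {
    e <- seq_len(K) - (K + 1) / 2
    e / sqrt(mean(e^2)) * sqrt(h2)
  }
  bhap <- beta_alle[unclass(series) + 1L]
  eps <- stats::rnorm(N)
  eps <- eps - mean(eps)
  s <- sqrt(mean(eps^2))
  eps <- if (s > 0 && h2 < 1) eps / s * sqrt(1 - h2) else rep(0, N)
  A <- additive_map(J, founders)
  y <- unname(drop(A[des$states, , drop = FALSE] %*% bhap)) + eps
  structure(list(tree = tree, series = series, beta_alle = beta_alle,
                 bhap = bhap, y = y, states = des$states,
                 diplotypes = des$diplotypes, J = J, N = N, K = K, h2 = h2,
                 alpha = alpha, founders = founders),
            class = "qtl_sim")
}

#' @export
print.qtl_sim <- function(x, ...) {
  cat("Simulated QTL dataset: J =", x$J, ", N =", x$N, ", K =", x$K,
      ", h2 =", x$h2, "\n")
  cat("True allelic series:", series_key(x$series), "\n")
  invisible(x)
}

#' Misspecify a coalescent tree
#'
#' `"incorrect"` replaces the tree by an independent coalescent draw over the
#' same leaves. `"partial"` applies one random nearest-neighbor interchange to
#' an internal edge and redraws all node times from the Kingman
#' inter-coalescence distribution, assigning times to internal nodes in a
#' random order compatible with the new topology -- a labelled approximation
#' of partial phylogenetic error.
#'
#' @param tree a rooted binary [ape::phylo].
#' @param mode `"partial"` or `"incorrect"`.
#' @param founders founder names.
#' @return A rooted binary ultrametric [ape::phylo] over the same leaves, with
#'   attribute `misspecification` recording the perturbation.
#' @export
misspecify_tree <- function(tree, mode = c("partial", "incorrect"),
                            founders = NULL) {
  mode <- match.arg(mode)
  if (is.null(founders)) founders <- sort(tree$tip.label)
  J <- length(tree$tip.label)
  if (mode == "incorrect") {
    out <- sample_coalescent_tree(J, sample(founders))
    attr(out, "misspecification") <- "incorrect"
    return(out)
  }
  topo <- nni_once(tree)
  out <- resample_coalescent_times(topo)
  attr(out, "misspecification") <- "partial (single NNI + coalescent time resample)"
  out
}

# one uniformly chosen nearest-neighbor interchange at an internal edge
nni_once <- function(tree) {
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  internal <- which(tree$edge[, 2L] > length(tree$tip.label))
  if (length(internal) == 0L) return(tree)
  ei <- internal[sample.int(length(internal), 1L)]
  p <- tree$edge[ei, 1L]; ch <- tree$edge[ei, 2L]
  sib <- setdiff(tree$edge[tree$edge[, 1L] == p, 2L], ch)
  gk <- tree$edge[tree$edge[, 1L] == ch, 2L]
  swap <- gk[sample.int(2L, 1L)]
  e <- tree$edge
  e[e[, 1L] == p & e[, 2L] == sib, 2L] <- swap
  e[e[, 1L] == ch & e[, 2L] == swap, 2L] <- sib
  tree$edge <- e
  tree
}

# fresh Kingman event times assigned to internal nodes in a random order
# compatible with the topology (children coalesce before their parent)
resample_coalescent_times <- function(tree) {
  J <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  times <- rep(0, max(tree$edge))
  done <- c(rep(TRUE, J), rep(FALSE, max(tree$edge) - J))
  t <- 0
  for (k in J:2) {
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    kids_done <- vapply((J + 1L):max(tree$edge), function(nd)
      !done[nd] && all(done[tree$edge[tree$edge[, 1L] == nd, 2L]]), logical(1))
    avail <- ((J + 1L):max(tree$edge))[kids_done]
    nd <- if (length(avail) == 1L) avail else avail[sample.int(length(avail), 1L)]
    times[nd] <- t
    done[nd] <- TRUE
  }
  tree$edge.length <- times[tree$edge[, 1L]] - times[tree$edge[, 2L]]
  tree
}

#' Run the simulation scenario grid
#'
#' For each replicate at each `(K, h2)` setting, simulates one dataset and
#' fits it under the requested prior-information scenarios -- `crp` (no tree),
#' `tree` (true tree), `misspecified` (partially misspecified tree),
#' `incorrect` (unrelated tree), `known` (oracle: series fixed at truth) and
#' `full` (haplotype-based: all-singleton series) -- scoring each fit with
#' [evaluate_against_truth()]. Scenarios share the replicate's tree and data.
#'
#' @param K vector of true allele counts.
#' @param h2 vector of QTL effect sizes.
#' @param scenarios subset of the six scenario names.
#' @param replicates replicates per setting.
#' @param n_iter,burn_in Gibbs iterations per fit.
#' @param J,N,alpha generating parameters.
#' @param hyper a [series_hyper] for inference.
#' @param seed base seed; replicate r of setting s uses a distinct stream.
#' @return Long-format data frame: scenario, K, h2, replicate, accuracy01,
#'   certainty, mse.
#' @export
run_scenario_grid <- function(K, h2, scenarios = c("crp", "known", "full"),
                              replicates = 10, n_iter = 2000,
                              burn_in = floor(n_iter / 10), J = 8, N = 400,
                              alpha = 1, hyper = series_hyper(), seed = 1) {
  scenarios <- match.arg(scenarios,
                         c("crp", "tree", "misspecified", "incorrect",
                           "known", "full"), several.ok = TRUE)
  rows <- list()
  grid <- expand.grid(K = K, h2 = h2, rep = seq_len(replicates))
  for (g in seq_len(nrow(grid))) {
    Kg <- grid$K[g]; hg <- grid$h2[g]; r <- grid$rep[g]
    sim <- simulate_qtl(J = J, N = N, K = Kg, h2 = hg, alpha = alpha,
                        seed = seed + 7919L * g)
    for (sc in scenarios) {
      fit <- switch(sc,
        crp = series_fit(sim$y, sim$diplotypes, prior = "crp", hyper = hyper,
                         n_iter = n_iter, burn_in = burn_in, seed = seed + g),
        tree = series_fit(sim$y, sim$diplotypes, prior = "tree",
                          tree = sim$tree, hyper = hyper, n_iter = n_iter,
                          burn_in = burn_in, seed = seed + g),
        misspecified = series_fit(sim$y, sim$diplotypes, prior = "tree",
                                  tree = misspecify_tree(sim$tree, "partial"),
                                  hyper = hyper, n_iter = n_iter,
                                  burn_in = burn_in, seed = seed + g),
        incorrect = series_fit(sim$y, sim$diplotypes, prior = "tree",
                               tree = misspecify_tree(sim$tree, "incorrect"),
                               hyper = hyper, n_iter = n_iter,
                               burn_in = burn_in, seed = seed + g),
        known = series_fit(sim$y, sim$diplotypes, prior = "fixed",
                           fixed_series = sim$series, hyper = hyper,
                           n_iter = n_iter, burn_in = burn_in, seed = seed + g),
        full = series_fit(sim$y, sim$diplotypes, prior = "fixed",
                          fixed_series = seq_len(J) - 1L, hyper = hyper,
                          n_iter = n_iter, burn_in = burn_in, seed = seed + g))
      ev <- evaluate_against_truth(fit, sim$series, sim$bhap)
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = sc, K = Kg, h2 = hg, replicate = r,
                   accuracy01 = ev$accuracy01, certainty = ev$certainty,
                   mse = ev$mse)
    }
  }
  do.call(rbind, rows)
}
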