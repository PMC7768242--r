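test_that("Ewens density matches closed forms and normalizes", {
  expect_equal(exp(crp_log_density(c(0, 0), 1)), 0.5)
  # J = 3, alpha = 1: one-block 1/3, each two-block 1/6, singletons 1/6
  p3 <- vapply(all_series(3), function(s) exp(crp_log_density(s, 1)), numeric(1))
  expect_equal(p3, c(1 / 3, 1 / 6, 1 / 6, 1 / 6, 1 / 6))
  for (J in 2:6) for (a in c(0.1, 1, 5))
    expect_equal(sum(vapply(all_series(J), function(s)
      exp(crp_log_density(s, a)), numeric(1))), 1)
  expect_error(crp_log_density(c(0, 1), 0), "positive")
})

test_that("CRP conditionals are exchangeable and rebuild the density", {
  expect_equal(crp_conditional(integer(0), 2), 1)
  expect_equal(crp_conditional(1L, 1), c(0.5, 0.5))
  # sequential product over any insertion order equals the Ewens density
  set.seed(13)
  alpha <- 0.7
  for (s in all_series(4)) {
    target <- crp_log_density(s, alpha)
    for (rep in 1:5) {
      ord <- sample(4)
      lp <- 0
      a <- rep(NA_integer_, 4)
      for (j in ord) {
        assigned <- a[!is.na(a)]
        lbl <- unique(unclass(s)[!is.na(a)])
        sizes <- tabulate(match(assigned, lbl))
        pr <- crp_conditional(sizes, alpha)
        k <- unclass(s)[j]
        i <- match(k, lbl)
        lp <- lp + log(if (is.na(i)) pr[length(pr)] else pr[i])
        a[j] <- k
      }
      expect_equal(lp, target)
    }
  }
})

test_that("branch mutations imply the expected series", {
  tr <- ape::read.tree(text = "((A:1,D:1):0.5,(B:1,C:1):0.5);")
  n <- 6L
  expect_equal(series_key(partition_from_mutations(tr, rep(0, n))), "0,0,0,0")
  # every terminal branch mutated: all singletons
  cb <- qtlseries:::canonical_branches(tr)
  b <- rep(0, n)
  term <- which(tr$edge[cb$edge, 2] <= 4)
  b[term] <- 1
  expect_equal(attr(partition_from_mutations(tr, b), "K"), 4L)
  # single mutation on the branch subtending (B, C) gives {A,D} | {B,C}
  bc_tips <- sort(match(c("B", "C"), tr$tip.label))
  bc_node <- tr$edge[tr$edge[, 2] %in% bc_tips, 1][1]
  bi <- which(tr$edge[cb$edge, 2] == bc_node)
  b2 <- rep(0, n); b2[bi] <- 1
  expect_equal(series_key(partition_from_mutations(tr, b2)), "0,1,1,0")
  expect_error(partition_from_mutations(tr, rep(0, 4)), "length")
})

test_that("branch configuration prior normalizes and matches closed forms", {
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(branch_config_log_prior(tr2, c(0, 0), 2), -2)
  # zero lengths force the no-mutation configuration
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  expect_equal(branch_config_log_prior(tr0, c(0, 0), 1), 0)
  expect_equal(branch_config_log_prior(tr0, c(1, 0), 1), -Inf)
  # sums to one over all configurations
  set.seed(14)
  tr4 <- sample_coalescent_tree(4)
  cfg <- expand.grid(rep(list(0:1), 6))
  tot <- sum(apply(cfg, 1, function(b) exp(branch_config_log_prior(tr4, b, 1.3))))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("rate-marginalized configuration prior is exact", {
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(exp(branch_config_log_prior_marginal(tr2, c(0, 0), 1, 1)), 0.5)
  # no mutations: single closed-form term
  set.seed(15)
  tr <- sample_coalescent_tree(5)
  L <- sum(tr$edge.length)
  expect_equal(exp(branch_config_log_prior_marginal(tr, rep(0, 8), 1.4, 2)),
               (2 / (2 + 0.5 * L))^1.4)
  # inclusion-exclusion vs adaptive quadrature on random cases, and
  # normalization over all configurations
  for (rep in 1:40) {
    tr4 <- sample_coalescent_tree(4)
    b <- rbinom(6, 1, 0.5)
    got <- exp(branch_config_log_prior_marginal(tr4, b, 1, 1))
    want <- integrate(function(a) vapply(a, function(ai)
      exp(branch_config_log_prior(tr4, b, ai)) * dgamma(ai, 1, 1), numeric(1)),
      0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
    expect_lt(abs(got - want) / want, 1e-8)
  }
  cfg <- expand.grid(rep(list(0:1), 6))
  tr4 <- sample_coalescent_tree(4)
  tot <- sum(apply(cfg, 1, function(b)
    exp(branch_config_log_prior_marginal(tr4, b, 1, 1))))
  expect_equal(tot, 1, tolerance = 1e-8)
})

test_that("tree-informed prior tables are exact and respect the topology", {
  # two leaves, unit branches: only the path between the leaves matters
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  pr2 <- tree_partition_prior(tr2, a_alpha = 1, b_alpha = 1)
  expect_equal(sum(pr2$prob), 1)
  expect_equal(pr2$prob[match("0,0", pr2$keys)], 0.5)
  expect_equal(pr2$prob[match("0,1", pr2$keys)], 0.5)
  # series impossible under the topology get zero mass:
  # {A,D}|{B,C} requires A,D to share mutations, impossible on ((A,B),(C,D))
  trX <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  prX <- tree_partition_prior(trX, a_alpha = 1, b_alpha = 2.33)
  expect_false("0,1,1,0" %in% prX$keys)   # {A,D} | {B,C}
  expect_true("0,0,1,1" %in% prX$keys)    # {A,B} | {C,D}
  expect_equal(sum(prX$prob), 1)
  # a very long terminal branch dominates the non-null mass
  trL <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:50):0.1);")
  prL <- suppressWarnings(tree_partition_prior(trL, a_alpha = 1, b_alpha = 2.33))
  nn <- prL$keys != "0,0,0,0"
  expect_equal(prL$keys[nn][which.max(prL$prob[nn])], "0,0,0,1")
  expect_error(tree_partition_prior(sample_coalescent_tree(13)), "unsupported")
})

test_that("tree prior tables match brute-force config enumeration", {
  # independent route: enumerate every branch configuration explicitly with
  # the scalar prior functions and aggregate by the implied series; exercises
  # zero-length branches (which must carry no mutation mass) as well
  brute_table <- function(tr, alpha = NULL, a = 1, b = 1) {
    n <- nrow(tr$edge)
    cfg <- as.matrix(expand.grid(rep(list(0:1), n)))
    p <- apply(cfg, 1, function(bv) suppressWarnings(
      if (is.null(alpha)) exp(branch_config_log_prior_marginal(tr, bv, a, b))
      else exp(branch_config_log_prior(tr, bv, alpha))))
    keys <- apply(cfg, 1, function(bv)
      suppressWarnings(series_key(partition_from_mutations(tr, bv))))
    agg <- rowsum(p, keys)
    setNames(agg[, 1], rownames(agg))
  }
  trees <- list(ape::read.tree(text = "((A:1,B:0):0.5,(C:1,D:1):0.5);"),
                ape::read.tree(text = "(((A:0.2,B:0.2):0.4,C:0.6):1,D:1.6);"))
  for (tr in trees) {
    for (spec in list(list(alpha = 1.3), list(alpha = NULL))) {
      got <- suppressWarnings(tree_partition_prior(tr, a_alpha = 1, b_alpha = 1,
                                                   alpha = spec$alpha))
      want <- brute_table(tr, alpha = spec$alpha)
      want <- want[want > 0]
      expect_setequal(got$keys, names(want))
      expect_equal(got$prob[match(names(want), got$keys)], unname(want),
                   tolerance = 1e-10)
    }
  }
})

test_that("averaging tree priors over coalescent draws recovers the CRP", {
  # identity between the coalescent-averaged tree prior and the Ewens density
  set.seed(16)
  J <- 4; alpha <- 1; nt <- 3000
  keys <- vapply(all_series(J), series_key, character(1))
  tot <- setNames(numeric(length(keys)), keys)
  for (i in seq_len(nt)) {
    pr <- tree_partition_prior(sample_coalescent_tree(J), alpha = alpha)
    tot[pr$keys] <- tot[pr$keys] + pr$prob
  }
  avg <- tot / nt
  crp <- vapply(all_series(J), function(s) exp(crp_log_density(s, alpha)),
                numeric(1))
  se <- sqrt(pmax(avg * (1 - avg), 1e-6) / nt)
  expect_true(all(abs(avg - crp) < 3.5 * se))
  # single-prior average is the identity; disjoint supports mix evenly
  pr1 <- tree_partition_prior(sample_coalescent_tree(3), a_alpha = 1, b_alpha = 1)
  expect_equal(average_partition_priors(list(pr1))$prob, pr1$prob)
  pa <- qtlseries:::new_partition_prior(c("0,0,0"), 1, 3, "restricted")
  pb <- qtlseries:::new_partition_prior(c("0,1,2"), 1, 3, "restricted")
  mix <- average_partition_priors(list(pa, pb))
  expect_equal(sort(mix$prob), c(0.5, 0.5))
  expect_error(average_partition_priors(list()), "non-empty")
})

test_that("variant restriction keeps exactly the refining series", {
  pr <- crp_partition_prior(3, alpha = 1)
  # one-block variant: unchanged
  expect_equal(sort(restrict_prior(pr, c(0, 0, 0))$keys), sort(pr$keys))
  # variant {A,C}|{B}: survivors are {A,C}|{B} and singletons
  r <- restrict_prior(pr, c(0, 1, 0))
  expect_setequal(r$keys, c("0,1,0", "0,1,2"))
  expect_equal(sum(r$prob), 1)
  # all-singleton variant: only the identity survives
  r2 <- restrict_prior(pr, c(0, 1, 2))
  expect_equal(r2$keys, "0,1,2")
  # support is exactly the refinement set (brute force, J = 5)
  pr5 <- crp_partition_prior(5, alpha = 0.8)
  v <- allelic_series(c(0, 1, 0, 2, 1))
  r5 <- restrict_prior(pr5, v)
  ref <- pr5$keys[vapply(pr5$keys, function(k)
    series_refines(series_from_key(k), v), logical(1))]
  expect_setequal(r5$keys, ref)
})

test_that("prior on the number of alleles and its elicitation are coherent", {
  kd <- prior_k_distribution(crp_partition_prior(3, alpha = 1))
  expect_equal(unname(kd), c(1 / 3, 1 / 2, 1 / 6))
  # point mass on the identity series
  pm <- qtlseries:::new_partition_prior("0,1,2,3", 1, 4, "restricted")
  expect_equal(unname(prior_k_distribution(pm)), c(0, 0, 0, 1))
  # large rate forces the null
  expect_gt(crp_null_mass(8, 1, 1e5), 0.999)
  # Monte-Carlo oracle at J = 2
  set.seed(17)
  a <- rgamma(2e5, 1, 1)
  mc <- mean(1 / (1 + a))
  est <- crp_null_mass(2, 1, 1)
  expect_lt(abs(est - mc), 3 * sd(1 / (1 + a)) / sqrt(2e5))
  # elicitation round trip and monotonicity
  for (t in c(0.3, 0.5, 0.7)) {
    b <- elicit_b_alpha(6, 1, t)
    expect_lt(abs(crp_null_mass(6, 1, b) - t), 1e-5)
  }
  expect_gt(elicit_b_alpha(8, 1, 0.999), elicit_b_alpha(8, 1, 0.5))
})
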