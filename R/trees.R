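#' Validate a coalescent tree of founder haplotypes
#'
#' Checks that `tree` is a rooted, strictly binary `phylo` object with
#' 2J - 2 branches, non-negative branch lengths (in coalescent units), and tip
#' labels matching the founder names exactly once each. Non-binary trees are
#' rejected; resolve polytomies upstream with zero-length branches. A warning
#' is emitted when leaf depths differ by more than 1e-6 relative (coalescent
#' trees are ultrametric; user-supplied trees may not be).
#'
#' @param tree an [ape::phylo] object.
#' @param founders character vector of J founder names (defaults to the sorted
#'   tip labels).
#' @return The tree, invisibly, after validation.
#' @export
validate_series_tree <- function(tree, founders = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' object")
  if (is.null(founders)) founders <- sort(tree$tip.label)
  J <- length(founders)
  if (J < 2L) stop("a tree needs at least two leaves")
  if (length(tree$tip.label) != J || !setequal(tree$tip.label, founders) ||
      anyDuplicated(tree$tip.label))
    stop("tree leaves must match the founder labels exactly once each; ",
         "offending labels: ",
         paste(union(setdiff(tree$tip.label, founders),
                     setdiff(founders, tree$tip.label)), collapse = ", "))
  if (!ape::is.rooted(tree)) stop("'tree' must be rooted")
  if (!ape::is.binary(tree))
    stop("'tree' must be strictly binary; resolve polytomies upstream ",
         "(e.g. with zero-length branches via ape::multi2di)")
  if (is.null(tree$edge.length)) stop("'tree' must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (nrow(tree$edge) != 2L * J - 2L)
    stop("a rooted binary tree over ", J, " leaves must have ", 2L * J - 2L,
         " branches")
  depth <- ape::node.depth.edgelength(tree)[seq_len(J)]
  if (diff(range(depth)) > 1e-6 * max(depth, 1e-12))
    warning("tree is not ultrametric (leaf depths differ); branch lengths ",
            "are used as given, in coalescent units")
  invisible(tree)
}

# Canonical branch ordering: depth-first from the root, children visited in
# order of their clade's smallest founder index. Fixes the alignment of branch
# mutation indicator vectors b. Returns, per canonical branch index 1..2J-2:
# the phylo edge row, its length, and per-leaf root-path bitmasks.
canonical_branches <- function(tree, founders = NULL) {
  if (is.null(founders)) founders <- sort(tree$tip.label)
  validate_series_tree(tree, founders)
  J <- length(founders)
  n_branch <- 2L * J - 2L
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  tip_idx <- match(tree$tip.label, founders)   # node -> founder index (tips)
  # smallest founder index below each node
  min_f <- rep(NA_integer_, max(tree$edge))
  min_f[seq_len(J)] <- tip_idx
  fill <- function(node) {
    if (!is.na(min_f[node])) return(min_f[node])
    m <- min(vapply(tree$edge[kids[[as.character(node)]], 2L], fill, integer(1)))
    min_f[node] <<- m
    m
  }
  fill(root)
  ord <- integer(n_branch)
  paths <- numeric(max(tree$edge))  # bitmask of canonical branches to the root
  cnt <- 0L
  dfs <- function(node, mask) {
    paths[node] <<- mask
    e <- kids[[as.character(node)]]
    if (is.null(e)) return(invisible())
    e <- e[order(min_f[tree$edge[e, 2L]])]
    for (ei in e) {
      cnt <<- cnt + 1L
      ord[cnt] <<- ei
      dfs(tree$edge[ei, 2L], mask + 2^(cnt - 1L))
    }
  }
  dfs(root, 0)
  list(edge = ord, lengths = tree$edge.length[ord],
       leaf_paths = paths[seq_len(J)][order(tip_idx)],  # founder order
       n_branch = n_branch, founders = founders, root = root)
}

#' Allelic series implied by mutated branches on a tree
#'
#' Two founder haplotypes carry the same functional allele exactly when the
#' sets of mutated branches on their root-to-leaf paths coincide
#' (equivalently, when no mutated branch lies on the path between them).
#'
#' @param tree a rooted binary [ape::phylo] with branch lengths.
#' @param b binary vector of branch mutation indicators, length 2J - 2,
#'   aligned to the canonical branch ordering (depth-first from the root,
#'   children in founder-label order).
#' @param founders founder names fixing leaf order (default sorted tip labels).
#' @return An [allelic_series] over the founders.
#' @export
partition_from_mutations <- function(tree, b, founders = NULL) {
  cb <- canonical_branches(tree, founders)
  if (length(b) != cb$n_branch)
    stop("'b' must have length 2J - 2 = ", cb$n_branch)
  if (any(!b %in% c(0, 1))) stop("'b' must be a binary vector")
  mask <- sum(b * 2^(seq_along(b) - 1L))
  sig <- vapply(cb$leaf_paths, function(p) mask_and(mask, p), numeric(1))
  allelic_series(match(sig, unique(sig)) - 1L, cb$founders)
}

# bitwAnd for masks that may exceed .Machine$integer.max is not needed here
# (2J - 2 <= 22 bits), but keep a single choke point for the operation.
mask_and <- function(a, b) bitwAnd(as.integer(a), as.integer(b))

#' Log prior of a branch mutation configuration at fixed rate
#'
#' Functional mutations arrive on each branch as a Poisson process with rate
#' `0.5 * alpha` per coalescent unit, so branch `m` of length `l_m` is mutated
#' with probability `1 - exp(-0.5 * alpha * l_m)`, independently across
#' branches.
#'
#' @inheritParams partition_from_mutations
#' @param alpha functional mutation rate (concentration parameter), > 0.
#' @return Log probability of `b` given the tree and `alpha`.
#' @export
branch_config_log_prior <- function(tree, b, alpha, founders = NULL) {
  if (alpha <= 0) stop("'alpha' must be positive")
  cb <- canonical_branches(tree, founders)
  if (length(b) != cb$n_branch) stop("'b' must have length 2J - 2")
  h <- 0.5 * alpha * cb$lengths
  lq0 <- -h
  lq1 <- ifelse(h > 0, log1p(-exp(-h)), -Inf)
  sum(ifelse(b == 1, lq1, lq0))
}

#' Log prior of a branch configuration with the mutation rate marginalized
#'
#' Exact integral of the fixed-rate branch configuration prior against a
#' Gamma(`a_alpha`, `b_alpha`) prior on the mutation rate, by
#' inclusion-exclusion over the mutated branches:
#' \deqn{p(b|T) = \sum_{S \subseteq mut(b)} (-1)^{|S|}
#'   \left(\frac{b_\alpha}{b_\alpha + 0.5 (L_0 + L_S)}\right)^{a_\alpha},}
#' where \eqn{L_0} is the total length of unmutated branches and \eqn{L_S} the
#' total length of the branches in `S`.
#'
#' @inheritParams branch_config_log_prior
#' @param a_alpha,b_alpha gamma shape and rate for the mutation rate, > 0.
#' @return Log probability of `b` given the tree, with alpha integrated out.
#' @export
branch_config_log_prior_marginal <- function(tree, b, a_alpha, b_alpha,
                                             founders = NULL) {
  if (a_alpha <= 0 || b_alpha <= 0) stop("'a_alpha' and 'b_alpha' must be positive")
  cb <- canonical_branches(tree, founders)
  if (length(b) != cb$n_branch) stop("'b' must have length 2J - 2")
  mut <- which(b == 1)
  if (length(mut) > 24L) stop("too many mutated branches for exact enumeration")
  L0 <- sum(cb$lengths[setdiff(seq_along(b), mut)])
  # alternating sum accumulated in extended precision (compiled kernel)
  log(ie_marginal_cpp(cb$lengths[mut], L0, a_alpha, b_alpha))
}
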