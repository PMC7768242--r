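# File formats: phenotype CSV (`id,value` plus optional covariate columns),
# diplotype probability CSV (`id` plus one column per state, named by the
# state labels `A.A`, `B.B`, ..., `A.B`, ...), Newick trees (one or many,
# branch lengths in coalescent units), partition prior CSV
# (`series,probability`), chain CSV, and JSON manifests.

#' Read a phenotype CSV
#'
#' Expects columns `id` and `value`; any further numeric columns are treated
#' as covariates.
#'
#' @param path CSV file path.
#' @return Data frame with `id`, `value` and covariate columns.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("id", "value") %in% names(d)))
    stop("phenotype file must have 'id' and 'value' columns")
  if (any(!is.finite(d$value))) stop("non-finite phenotype values")
  d$id <- as.character(d$id)
  d
}

#' Read a diplotype probability CSV
#'
#' Expects an `id` column plus `J + J(J-1)/2` probability columns named by
#' the diplotype state labels (homozygotes `A.A` first in founder order, then
#' heterozygotes `A.B`, j < k). Rows within `1e-6` of summing to one are
#' renormalized with a warning; rows further off are rejected.
#'
#' @param path CSV file path.
#' @return A [diplotype_priors] with individual ids as rownames.
#' @export
read_diplotype_priors <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"id" %in% names(d)) stop("diplotype file must have an 'id' column")
  ids <- as.character(d$id)
  probs <- as.matrix(d[, setdiff(names(d), "id"), drop = FALSE])
  S <- ncol(probs)
  J <- round((sqrt(1 + 8 * S) - 1) / 2)  # S = J(J+1)/2
  if (J + (J * (J - 1)) / 2 != S)
    stop("column count ", S, " is not J + J(J-1)/2 for any integer J")
  founders <- sub("\\..*$", "", colnames(probs)[seq_len(J)])
  expected <- diplotype_state_labels(founders)
  if (!identical(colnames(probs), expected))
    stop("diplotype columns must follow the state-label order: ",
         paste(utils::head(expected, 5), collapse = ", "), ", ...")
  rs <- rowSums(probs)
  off <- abs(rs - 1) > 1e-9
  if (any(abs(rs - 1) > 1e-6))
    stop("diplotype rows must sum to 1 within 1e-6; worst deviation ",
         format(max(abs(rs - 1))))
  if (any(off)) {
    warning(sum(off), " diplotype row(s) renormalized (summed to within 1e-6 of 1)")
    probs[off, ] <- probs[off, ] / rs[off]
  }
  diplotype_priors(probs, founders, ids = ids)
}

#' Write diplotype priors to CSV
#' @param dip a [diplotype_priors].
#' @param path output CSV path.
#' @export
write_diplotype_priors <- function(dip, path) {
  d <- data.frame(id = rownames(dip$probs), dip$probs, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
}

#' Read trees from a Newick file
#'
#' Reads one or more rooted binary trees with branch lengths (coalescent
#' units) and validates each against the founder labels. Nexus is not
#' supported; convert upstream.
#'
#' @param path Newick file path.
#' @param founders optional founder labels to validate against.
#' @return A `multiPhylo` (possibly of length one).
#' @export
read_trees <- function(path, founders = NULL) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- structure(list(tr), class = "multiPhylo")
  if (is.null(tr) || length(tr) == 0L) stop("no trees parsed from ", path)
  for (t in tr) validate_series_tree(t, founders)
  tr
}

#' Read and align model inputs
#'
#' Reads a phenotype CSV and a diplotype CSV, aligns them by `id` (dropping,
#' with a warning, individuals missing from either file), and optionally
#' reads trees whose leaves are validated against the founder labels.
#'
#' @param phenotype_path,diplotype_path CSV paths.
#' @param tree_path optional Newick path.
#' @return List with `y`, `diplotypes`, `covariates` (or NULL), `trees`
#'   (or NULL), `ids`.
#' @export
read_series_inputs <- function(phenotype_path, diplotype_path,
                               tree_path = NULL) {
  ph <- read_phenotypes(phenotype_path)
  dip <- read_diplotype_priors(diplotype_path)
  common <- intersect(ph$id, rownames(dip$probs))
  if (length(common) == 0L) stop("no shared individuals between input files")
  dropped <- length(union(ph$id, rownames(dip$probs))) - length(common)
  if (dropped > 0L)
    warning(dropped, " individual(s) missing from one input; dropped")
  ph <- ph[match(common, ph$id), , drop = FALSE]
  probs <- dip$probs[match(common, rownames(dip$probs)), , drop = FALSE]
  covn <- setdiff(names(ph), c("id", "value"))
  trees <- if (!is.null(tree_path)) read_trees(tree_path, dip$founders) else NULL
  list(y = ph$value,
       diplotypes = diplotype_priors(probs, dip$founders, ids = common),
       covariates = if (length(covn)) as.matrix(ph[, covn, drop = FALSE]) else NULL,
       trees = trees, ids = common)
}

#' Write a partition prior as CSV
#' @param prior a [partition_prior].
#' @param path output path (`series,probability` with restricted-growth keys).
#' @export
write_partition_prior <- function(prior, path) {
  utils::write.csv(data.frame(series = prior$keys, probability = prior$prob),
                   path, row.names = FALSE, quote = TRUE)
}

#' Read a partition prior from CSV
#' @param path CSV with `series,probability` columns.
#' @param source source tag for the resulting prior.
#' @export
read_partition_prior <- function(path, source = "restricted") {
  d <- utils::read.csv(path, colClasses = c("character", "numeric"))
  J <- length(series_from_key(d$series[1L]))
  new_partition_prior(d$series, d$probability, J, source)
}

#' Write a fitted chain as CSV
#'
#' One row per iteration: iteration, series key, K, mu, sigma, phi, alpha,
#' and the J haplotype effects.
#'
#' @param fit a [series_fit].
#' @param path output CSV path.
#' @export
write_chain <- function(fit, path) {
  d <- data.frame(iteration = seq_len(fit$n_iter), series = fit$series,
                  K = fit$K, mu = fit$mu, sigma = fit$sigma, phi = fit$phi,
                  alpha = fit$alpha, fit$bhap, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
}

#' Read a chain CSV back into a summarizable fit skeleton
#'
#' Reconstructs the per-iteration records needed by [summary.series_fit()]
#' and [evaluate_against_truth()] from a chain written by [write_chain()].
#'
#' @param path chain CSV path.
#' @param burn_in burn-in to apply when summarizing.
#' @return A `series_fit`-classed object without data or prior components.
#' @export
read_chain <- function(path, burn_in = 0L) {
  d <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(series = "character"))
  founders <- setdiff(names(d), c("iteration", "series", "K", "mu", "sigma",
                                  "phi", "alpha"))
  structure(list(series = d$series, K = d$K, mu = d$mu, sigma = d$sigma,
                 phi = d$phi, alpha = d$alpha,
                 bhap = as.matrix(d[, founders, drop = FALSE]),
                 founders = founders, n_iter = nrow(d),
                 burn_in = as.integer(burn_in), prior_mode = "unknown"),
            class = "series_fit")
}

#' Write a JSON run manifest
#'
#' Captures the configuration needed to reproduce a run bit-for-bit: prior
#' mode, hyperparameters, iteration counts, seed, and package version.
#'
#' @param fit a [series_fit].
#' @param path output JSON path.
#' @export
write_manifest <- function(fit, path) {
  h <- fit$hyper
  jsonlite::write_json(list(
    package = "qtlseries",
    version = as.character(utils::packageVersion("qtlseries")),
    prior_mode = fit$prior_mode,
    fixed_series = if (!is.null(fit$fixed_series)) series_key(fit$fixed_series),
    founders = fit$founders,
    n_individuals = length(fit$y),
    hyper = list(kappa = h$kappa, lambda = h$lambda,
                 tau = if (is.infinite(h$tau)) "Inf" else h$tau,
                 v = h$v, a_alpha = h$a_alpha, b_alpha = h$b_alpha),
    n_iter = fit$n_iter, burn_in = fit$burn_in, seed = fit$seed,
    fix_phi = fit$fix_phi, fix_alpha = fit$fix_alpha),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Diplotype probabilities for a cross of two lines
#'
#' Given the diplotype state probability rows of two (possibly heterozygous)
#' parental lines over possibly different founder sets, enumerates all
#' parental state combinations, lets each parent transmit either of its two
#' haplotypes with probability 1/2, and accumulates offspring state
#' probabilities over the union founder set. Founders shared by both parental
#' populations are merged by name (maternal and paternal copies of a shared
#' founder are treated as identical).
#'
#' @param p1,p2 named numeric probability vectors over each line's diplotype
#'   states (names in `j.k` state-label form; each sums to 1).
#' @param founders1,founders2 founder label vectors of the two lines.
#' @return Named probability vector over the union founder set's states,
#'   summing to 1.
#' @export
cross_diplotype_probs <- function(p1, p2, founders1, founders2) {
  check_row <- function(p, founders, who) {
    if (abs(sum(p) - 1) > 1e-9) stop(who, " probabilities must sum to 1")
    if (!identical(names(p), diplotype_state_labels(founders)))
      stop(who, " names must follow the state-label order for its founders")
  }
  check_row(p1, founders1, "line 1"); check_row(p2, founders2, "line 2")
  founders <- union(founders1, founders2)
  out <- stats::setNames(numeric(length(diplotype_state_labels(founders))),
                         diplotype_state_labels(founders))
  haps_of_state <- function(label) strsplit(label, ".", fixed = TRUE)[[1L]]
  for (s1 in which(p1 > 0)) for (s2 in which(p2 > 0)) {
    h1 <- haps_of_state(names(p1)[s1])
    h2 <- haps_of_state(names(p2)[s2])
    for (a in h1) for (b in h2) {
      pair <- founders[sort(match(c(a, b), founders))]
      label <- if (pair[1L] == pair[2L] || length(pair) == 1L)
        paste(pair[1L], pair[1L], sep = ".")
      else paste(pair[1L], pair[2L], sep = ".")
      out[label] <- out[label] + p1[s1] * p2[s2] * 0.25
    }
  }
  out
}
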