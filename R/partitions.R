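#' Allelic series: a partition of founder haplotypes into functional alleles
#'
#' An allelic series assigns each of the `J` founder haplotypes at a locus to
#' one of `K <= J` functionally distinct alleles. It is stored in canonical
#' restricted-growth form: the first haplotype has allele index 0, and each
#' subsequently appearing allele takes the smallest unused index, so the same
#' partition always has the same labels (e.g. `0,1,0,1,1,0,0,0`).
#'
#' @param assignment integer vector of allele indices, one per haplotype.
#'   Any labelling is accepted and is canonicalized; use 0-based
#'   restricted-growth indices for a stable round trip.
#' @param founders optional character vector of founder haplotype names.
#' @return An object of class `allelic_series`: a 0-based integer vector with
#'   attributes `K` (number of alleles) and optionally `founders`.
#' @examples
#' allelic_series(c(0, 1, 0, 1, 1, 0, 0, 0))
#' @export
allelic_series <- function(assignment, founders = NULL) {
  if (length(assignment) < 1L || anyNA(assignment))
    stop("'assignment' must be a non-empty vector without NAs")
  a <- canonical_assignment(as.integer(round(as.numeric(assignment))))
  if (!is.null(founders)) {
    if (length(founders) != length(a))
      stop("'founders' must have one name per haplotype")
    attr(a, "founders") <- as.character(founders)
  }
  attr(a, "K") <- max(a) + 1L
  class(a) <- "allelic_series"
  a
}

# relabel an arbitrary block labelling into 0-based restricted-growth form
canonical_assignment <- function(x) {
  first <- x[!duplicated(x)]
  match(x, first) - 1L
}

#' @export
print.allelic_series <- function(x, ...) {
  cat("Allelic series:", series_key(x), " (J =", length(x),
      ", K =", attr(x, "K"), ")\n")
  invisible(x)
}

#' Canonical string key of an allelic series
#'
#' @param x an [allelic_series] or plain assignment vector.
#' @return The comma-separated restricted-growth string, e.g. `"0,1,0,1,1,0,0,0"`.
#' @export
series_key <- function(x) {
  if (!inherits(x, "allelic_series")) x <- allelic_series(x)
  paste(unclass(x), collapse = ",")
}

#' Parse a restricted-growth string key into an allelic series
#'
#' @param key string such as `"0,1,0,2"`.
#' @param founders optional founder names.
#' @export
series_from_key <- function(key, founders = NULL) {
  allelic_series(as.integer(strsplit(key, ",", fixed = TRUE)[[1L]]), founders)
}

#' Indicator matrix of an allelic series
#'
#' Returns the J x K matrix `M` with `M[j, k] = 1` when haplotype `j` carries
#' allele `k`.
#'
#' @param x an [allelic_series].
#' @export
series_matrix <- function(x) {
  x <- allelic_series(x)
  K <- attr(x, "K")
  M <- matrix(0, length(x), K)
  M[cbind(seq_along(x), unclass(x) + 1L)] <- 1
  M
}

#' Block sizes of an allelic series
#'
#' @param x an [allelic_series] or assignment vector.
#' @return Integer vector of length K: the number of haplotypes per allele.
#' @export
series_sizes <- function(x) {
  if (!inherits(x, "allelic_series")) x <- allelic_series(x)
  tabulate(unclass(x) + 1L, nbins = attr(x, "K"))
}

#' Enumerate all allelic series for J haplotypes
#'
#' Enumerates every partition of `J` haplotypes in restricted-growth order.
#' There are `bell_number(J)` of them (4140 for J = 8).
#'
#' @param J number of founder haplotypes (J >= 1).
#' @param founders optional founder names attached to each series.
#' @return A list of [allelic_series] objects.
#' @export
all_series <- function(J, founders = NULL) {
  J <- as.integer(J)
  if (J < 1L) stop("'J' must be at least 1")
  if (J > 12L) stop("enumeration of all series is unsupported for J > 12")
  out <- vector("list", bell_number(J))
  a <- integer(J)
  n <- 0L
  rec <- function(i, mx) {
    if (i > J) {
      n <<- n + 1L
      out[[n]] <<- allelic_series(a, founders)
      return(invisible())
    }
    for (k in 0:(mx + 1L)) {
      a[i] <<- k
      rec(i + 1L, max(mx, k))
    }
  }
  a[1L] <- 0L
  rec(2L, 0L)
  if (J == 1L) out[[1L]] <- allelic_series(0L, founders)
  out
}

#' Bell numbers: the number of partitions of n items
#'
#' Computed with the Bell triangle; exact in double precision for n <= 22.
#'
#' @param n non-negative integer (or vector).
#' @return The number of set partitions of `n` items (1, 1, 2, 5, 15, ...).
#' @examples
#' bell_number(8)   # 4140
#' bell_number(15)  # 1382958545
#' @export
bell_number <- function(n) {
  if (length(n) > 1L) return(vapply(n, bell_number, numeric(1)))
  n <- as.integer(n)
  if (n < 0L) stop("'n' must be non-negative")
  if (n > 22L) stop("Bell numbers above n = 22 are not exact in double precision")
  if (n <= 1L) return(1)
  row <- 1
  for (i in seq_len(n - 1L)) row <- cumsum(c(row[length(row)], row))
  row[length(row)]
}

#' Does one allelic series refine another?
#'
#' `x` refines `v` when every pair of haplotypes separated by `v` is also
#' separated by `x` (equivalently, each allele of `x` lies inside a single
#' allele of `v`). Used to restrict priors to series consistent with the
#' functional distinctions implied by a known causal variant.
#'
#' @param x,v allelic series over the same number of haplotypes.
#' @return Logical scalar.
#' @export
series_refines <- function(x, v) {
  x <- allelic_series(x); v <- allelic_series(v)
  if (length(x) != length(v)) stop("series must cover the same haplotypes")
  # x refines v iff v's label is constant given x's label
  !any(duplicated(unique(cbind(unclass(x), unclass(v)))[, 1L]))
}
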