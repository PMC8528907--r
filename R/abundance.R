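#' Construct an abundance vector
#'
#' An abundance vector holds one sample's observed feature counts. Zero-count
#' features are dropped at construction: every estimator in this package is
#' defined on observed features only, so appending zeros never changes a
#' result.
#'
#' @param counts Numeric vector of non-negative integer read counts,
#'   optionally named by feature ID.
#' @param sample_id Optional sample identifier carried through to results.
#' @return An object of class `abundance_vector`: a list with elements
#'   `counts` (positive integer counts, named if names were supplied),
#'   `n` (total reads) and `sample_id`.
#' @examples
#' v <- abundance_vector(c(otu1 = 4, otu2 = 1, otu3 = 0), sample_id = "s1")
#' v$n           # 5
#' singletons(v) # 1
#' @export
abundance_vector <- function(counts, sample_id = NA_character_) {
  if (length(counts) == 0) stop("abundance vector is empty")
  if (anyNA(counts)) stop("abundance vector contains NA counts")
  if (any(counts < 0)) stop("abundance vector contains negative counts")
  if (any(counts != round(counts))) stop("abundance vector contains non-integer counts")
  keep <- counts > 0
  counts <- counts[keep]
  if (length(counts) == 0) stop("abundance vector has no positive counts")
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max
  structure(
    list(counts = counts, n = sum(counts), sample_id = sample_id),
    class = "abundance_vector"
  )
}

#' Abundance-frequency counts
#'
#' `f_k(v, k)` counts the features observed exactly `k` times; `singletons()`
#' is the `k = 1` case used by the Good-Turing coverage estimator.
#'
#' @param v An [abundance_vector()].
#' @param k Positive integer multiplicity.
#' @return Integer count of features with abundance exactly `k`.
#' @export
f_k <- function(v, k) {
  stopifnot(inherits(v, "abundance_vector"), k >= 1)
  sum(v$counts == k)
}

#' @rdname f_k
#' @export
singletons <- function(v) f_k(v, 1)

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf(
    "<abundance_vector> sample=%s  S_obs=%d  n=%s  f1=%d\n",
    x$sample_id, length(x$counts), format(x$n, big.mark = ","),
    sum(x$counts == 1)
  ))
  invisible(x)
}
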