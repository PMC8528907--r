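#' Rarefy a set of samples to a common coverage and compute 2D
#'
#' Implements coverage-based rarefaction at diversity order q = 2: the target
#' coverage `C*` is the smallest coverage attainable across samples at
#' `m = n - 1` (i.e. the dataset with the lowest coverage sets the target,
#' a single global target shared by all groups); every other sample is
#' interpolated down to the smallest size `m` whose expected coverage reaches
#' `C*`, and the inverse Simpson index is computed analytically at that size
#' with [rarefied_inverse_simpson()]. The minimum-coverage sample itself is
#' evaluated at `m = n - 1`.
#'
#' Rarefaction here is analytic interpolation, not random subsampling; the
#' seeded hypergeometric subsampler ([subsample_without_replacement()]) is
#' available as a Monte-Carlo cross-check (`mode = "montecarlo"`), reporting
#' the mean plugin index over `reps` subsamples.
#'
#' @param samples A list of [abundance_vector()]s (at least 2, each with
#'   `n >= 2`).
#' @param mode `"analytic"` (default) or `"montecarlo"`.
#' @param reps,seed Replicate count and RNG seed for the Monte-Carlo mode.
#' @return A list of `diversity_result`s, one per sample, each carrying the
#'   size `m` used and the common target coverage; the target is also
#'   attached as attribute `target_coverage`.
#' @export
rarefy_to_common_coverage <- function(samples, mode = c("analytic", "montecarlo"),
                                      reps = 1000, seed = 1) {
  mode <- match.arg(mode)
  if (length(samples) < 2) stop("coverage-based rarefaction needs at least 2 samples")
  ok <- vapply(samples, inherits, logical(1), "abundance_vector")
  if (!all(ok)) stop("all samples must be abundance_vector objects")
  if (any(vapply(samples, function(v) v$n, numeric(1)) < 2))
    stop("every sample needs n >= 2")
  cmax <- vapply(samples, function(v) expected_coverage_at_size(v, v$n - 1)$value,
                 numeric(1))
  if (any(cmax <= 0)) {
    bad <- vapply(samples[cmax <= 0], function(v) v$sample_id, character(1))
    stop("degenerate sample(s) with zero attainable coverage (all singletons): ",
         paste(bad, collapse = ", "))
  }
  target <- min(cmax)
  at_min <- cmax <= target + 1e-15
  results <- lapply(seq_along(samples), function(i) {
    v <- samples[[i]]
    m <- if (at_min[i]) as.integer(v$n - 1) else size_at_coverage(v, target)
    r <- if (mode == "analytic") {
      rarefied_inverse_simpson(v, m)
    } else {
      monte_carlo_inverse_simpson(v, m, reps = reps, seed = seed + i)
    }
    r$coverage <- target
    r
  })
  attr(results, "target_coverage") <- target
  results
}

#' @noRd
monte_carlo_inverse_simpson <- function(v, m, reps, seed) {
  vals <- vapply(seq_len(reps), function(j) {
    sub <- subsample_without_replacement(v, m, seed = seed * 1000L + j)
    inverse_simpson(sub)$value
  }, numeric(1))
  diversity_result(sample_id = v$sample_id, q = 2, estimator = "rarefied_q2",
                   value = mean(vals), rarefied_to = as.integer(m))
}

#' Seeded hypergeometric subsample of an abundance vector
#'
#' Draws `m` reads without replacement from the observed reads (a
#' multivariate hypergeometric draw over features), via [vegan::rrarefy()].
#' The caller's RNG state is preserved.
#'
#' @param v An [abundance_vector()].
#' @param m Subsample size, `1 <= m <= n`.
#' @param seed Integer seed making the draw reproducible; `NULL` uses (and
#'   advances) the current RNG state.
#' @return An [abundance_vector()] with total count `m`.
#' @export
subsample_without_replacement <- function(v, m, seed = NULL) {
  stopifnot(inherits(v, "abundance_vector"))
  if (length(m) != 1 || m != round(m) || m < 1 || m > v$n)
    stop("m must be an integer in [1, n]; got ", m)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  x <- v$counts
  sub <- drop(vegan::rrarefy(matrix(x, nrow = 1, dimnames = list(NULL, names(x))), m))
  abundance_vector(sub, sample_id = v$sample_id)
}
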