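#' Good-Turing sample coverage
#'
#' Sample coverage is the probability that the next sampled read belongs to an
#' already-observed feature. The Good-Turing estimate is
#' \deqn{\hat{C} = 1 - f_1 / n,}
#' where \eqn{f_1} is the number of singleton features and \eqn{n} the total
#' read count.
#'
#' @param v An [abundance_vector()].
#' @return A `coverage_estimate`: list with `value` (in \[0, 1\]), `method`
#'   (`"good_turing"`) and `at_size` (`"full"`).
#' @examples
#' good_turing_coverage(abundance_vector(c(2, 1, 1)))$value  # 0.5
#' @export
good_turing_coverage <- function(v) {
  stopifnot(inherits(v, "abundance_vector"))
  structure(
    list(value = 1 - sum(v$counts == 1) / v$n,
         method = "good_turing", at_size = "full"),
    class = "coverage_estimate"
  )
}

#' Expected coverage of a rarefied sample
#'
#' Expected Good-Turing coverage of a hypergeometric subsample of size `m`
#' drawn from the observed counts:
#' \deqn{\hat{C}(m) = 1 - \sum_{X_i \ge 1} \frac{X_i}{n}
#'   \frac{\binom{n - X_i}{m}}{\binom{n - 1}{m}}, \qquad 1 \le m \le n - 1.}
#' The binomial-coefficient ratio is evaluated as a difference of log-gamma
#' terms (`lchoose`), exponentiating last, so the formula is overflow-free for
#' read depths up to at least 1e8. At `m = n - 1` it reduces algebraically to
#' the Good-Turing estimate \eqn{1 - f_1/n}.
#'
#' @param v An [abundance_vector()] with `n >= 2`.
#' @param m Subsample size, `1 <= m <= n - 1`.
#' @return A `coverage_estimate` with `method = "chao_jost"` and `at_size = m`.
#' @export
expected_coverage_at_size <- function(v, m) {
  stopifnot(inherits(v, "abundance_vector"))
  n <- v$n
  if (n < 2) stop("coverage interpolation needs n >= 2")
  if (length(m) != 1 || m != round(m) || m < 1 || m > n - 1)
    stop("m must be an integer in [1, n - 1]; got ", m)
  x <- v$counts
  # lchoose(n - x, m) is -Inf when n - x < m, i.e. the term vanishes
  ratio <- exp(lchoose(n - x, m) - lchoose(n - 1, m))
  C <- 1 - sum((x / n) * ratio)
  structure(
    list(value = min(max(C, 0), 1), method = "chao_jost", at_size = m),
    class = "coverage_estimate"
  )
}

#' Smallest subsample size attaining a target coverage
#'
#' Inverts the (non-decreasing) interpolated coverage curve by bisection,
#' returning the smallest `m` in `[1, n - 1]` with
#' \eqn{\hat{C}(m) \ge} `target_C`. Ties resolve to the smallest qualifying
#' `m` — the conservative choice, interpolating least.
#'
#' @param v An [abundance_vector()] with `n >= 2`.
#' @param target_C Target coverage in `[0, 1]`; must not exceed the coverage
#'   attainable at `m = n - 1` (i.e. `1 - f1/n`). Callers wanting the full
#'   sample must clamp to `n - 1` explicitly; this is never done silently.
#' @return Integer subsample size `m`.
#' @export
size_at_coverage <- function(v, target_C) {
  stopifnot(inherits(v, "abundance_vector"))
  n <- v$n
  if (n < 2) stop("coverage inversion needs n >= 2")
  if (target_C < 0 || target_C > 1) stop("target coverage must be in [0, 1]")
  cmax <- expected_coverage_at_size(v, n - 1)$value
  if (target_C > cmax + 1e-12)
    stop(sprintf(paste0(
      "target coverage %.6g exceeds the maximum attainable %.6g for sample ",
      "'%s'; clamp the target to the coverage at m = n - 1 explicitly"),
      target_C, cmax, v$sample_id))
  cov_m <- function(m) expected_coverage_at_size(v, m)$value
  lo <- 1
  if (cov_m(lo) >= target_C) return(1)
  hi <- n - 1
  # invariant: cov(lo) < target_C <= cov(hi)
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (cov_m(mid) >= target_C) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
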