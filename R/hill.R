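#' Hill number of order q
#'
#' The Hill number (effective number of features) of a relative-abundance
#' vector is
#' \deqn{^qD = \left(\sum_i p_i^q\right)^{1/(1-q)},}
#' with the \eqn{q \to 1} limit \eqn{^1D = \exp(-\sum_i p_i \ln p_i)} taken
#' analytically when `|q - 1| < 1e-9`. `q` tunes the sensitivity to rare
#' features: `q = 0` is richness, `q = 1` the exponential of Shannon entropy,
#' `q = 2` the inverse Simpson index.
#'
#' @param p Relative abundances: strictly positive, summing to 1 within 1e-9.
#' @param q Non-negative diversity order.
#' @return The effective number \eqn{^qD}, between 1 and `length(p)`.
#' @examples
#' hill_number(c(0.4, 0.3, 0.2, 0.1), 2)  # 1 / 0.30
#' @export
hill_number <- function(p, q) {
  if (length(p) == 0) stop("empty abundance vector")
  if (any(p <= 0)) stop("relative abundances must be strictly positive")
  if (abs(sum(p) - 1) > 1e-9) stop("relative abundances must sum to 1 (got ", sum(p), ")")
  if (length(q) != 1 || q < 0) stop("q must be a single non-negative number")
  if (abs(q - 1) < 1e-9) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Plugin inverse Simpson index
#'
#' \eqn{^2D = 1/\sum_i (X_i/n)^2 = n^2 / \sum_i X_i^2}: the effective number
#' of dominant features.
#'
#' @param v An [abundance_vector()].
#' @return A `diversity_result` with `estimator = "plugin_hill"`, `q = 2`.
#' @export
inverse_simpson <- function(v) {
  stopifnot(inherits(v, "abundance_vector"))
  diversity_result(
    sample_id = v$sample_id, q = 2, estimator = "plugin_hill",
    value = v$n^2 / sum(v$counts^2)
  )
}

#' Rarefied (interpolated) inverse Simpson index
#'
#' The expected inverse Simpson index of a subsample of size `m`, computed
#' analytically rather than by random subsampling:
#' \deqn{^2D(m) = \left[\frac{1}{m} + \left(1 - \frac{1}{m}\right)
#'   \frac{\sum_i X_i (X_i - 1)}{n (n - 1)}\right]^{-1}.}
#' At `m = n` this reduces algebraically to the plugin [inverse_simpson()].
#'
#' @param v An [abundance_vector()] with `n >= 2`.
#' @param m Subsample size, `1 <= m <= n`.
#' @return A `diversity_result` with `estimator = "rarefied_q2"` and
#'   `rarefied_to = m`.
#' @export
rarefied_inverse_simpson <- function(v, m) {
  stopifnot(inherits(v, "abundance_vector"))
  n <- v$n
  if (n < 2) stop("rarefied inverse Simpson needs n >= 2")
  if (length(m) != 1 || m != round(m) || m < 1 || m > n)
    stop("m must be an integer in [1, n]; got ", m)
  x <- v$counts
  simpson_hat <- sum(x * (x - 1)) / (n * (n - 1))  # unbiased P(two reads share a feature)
  diversity_result(
    sample_id = v$sample_id, q = 2, estimator = "rarefied_q2",
    value = 1 / (1 / m + (1 - 1 / m) * simpson_hat),
    rarefied_to = m
  )
}

#' Chao-Shen effective number of functions
#'
#' Coverage-adjusted, Horvitz-Thompson-corrected Shannon entropy for
#' undersampled assemblages:
#' \deqn{\hat{H}_{CS} = -\sum_{X_i > 0}
#'   \frac{\tilde{p}_i \ln \tilde{p}_i}{1 - (1 - \tilde{p}_i)^n},
#'   \qquad \tilde{p}_i = \hat{C}\, X_i / n,\quad \hat{C} = 1 - f_1/n,}
#' converted to true diversity \eqn{^1D = \exp(\hat{H}_{CS})} — an effective
#' number of equally common functions (here, GO molecular-function terms).
#' Entropy is in nats throughout.
#'
#' Degenerate coverage: when every feature is a singleton (`f1 = n`) the
#' Good-Turing estimate is 0 and the estimator is undefined; the standard
#' practical adjustment `f1 <- n - 1` is applied with a warning.
#'
#' @param v An [abundance_vector()] with `n >= 2`.
#' @return A `diversity_result` with `estimator = "chao_shen_1D"`, `q = 1`,
#'   and the entropy `H` (nats) alongside `value = exp(H)`.
#' @examples
#' chao_shen_effective_functions(abundance_vector(c(4, 3, 2, 1)))$value # ~4.28
#' @export
chao_shen_effective_functions <- function(v) {
  stopifnot(inherits(v, "abundance_vector"))
  n <- v$n
  if (n < 2) stop("Chao-Shen estimator needs n >= 2")
  f1 <- sum(v$counts == 1)
  if (f1 == n) {
    warning("all features are singletons (coverage 0); substituting f1 = n - 1")
    f1 <- n - 1
  }
  C <- 1 - f1 / n
  p_adj <- C * v$counts / n
  H <- -sum(p_adj * log(p_adj) / (1 - (1 - p_adj)^n))
  diversity_result(
    sample_id = v$sample_id, q = 1, estimator = "chao_shen_1D",
    value = exp(H), coverage = C, H = H
  )
}

#' @noRd
diversity_result <- function(sample_id, q, estimator, value,
                             rarefied_to = NA_integer_, coverage = NA_real_,
                             H = NA_real_) {
  structure(
    list(sample_id = sample_id, q = q, estimator = estimator, value = value,
         rarefied_to = rarefied_to, coverage = coverage, H = H),
    class = "diversity_result"
  )
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result> sample=%s  %s (q=%g)  value=%.4f%s\n",
              x$sample_id, x$estimator, x$q, x$value,
              if (!is.na(x$rarefied_to)) sprintf("  m=%d", x$rarefied_to) else ""))
  invisible(x)
}

#' Collect diversity results into a data.frame
#'
#' @param results A list of `diversity_result` objects.
#' @return A data.frame with columns sample_id, estimator, q, m, coverage,
#'   value.
#' @export
diversity_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id, estimator = r$estimator, q = r$q,
               m = r$rarefied_to, coverage = r$coverage, value = r$value,
               stringsAsFactors = FALSE)
  }))
}
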