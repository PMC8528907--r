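test_that("Good-Turing coverage counts singletons", {
  expect_equal(good_turing_coverage(abundance_vector(c(5, 5)))$value, 1)
  expect_equal(good_turing_coverage(abundance_vector(c(2, 1, 1)))$value, 0.5)
  expect_equal(good_turing_coverage(abundance_vector(c(1, 1, 1)))$value, 0)
  expect_error(abundance_vector(numeric(0)), "empty")
})

test_that("interpolated coverage matches hand-derived values and bounds", {
  v <- abundance_vector(c(2, 1))
  expect_equal(expected_coverage_at_size(v, 1)$value, 1 / 3)
  # m = n - 1 identity with Good-Turing, here and on random vectors
  expect_equal(expected_coverage_at_size(abundance_vector(c(3, 1)), 3)$value, 0.75)
  set.seed(42)
  for (i in 1:25) {
    v <- random_vector(S = sample(3:15, 1), n = sample(10:300, 1))
    expect_equal(expected_coverage_at_size(v, v$n - 1)$value,
                 1 - sum(v$counts == 1) / v$n, tolerance = 1e-12)
    # non-decreasing in m
    ms <- sort(sample(seq_len(v$n - 1), min(8, v$n - 1)))
    cs <- vapply(ms, function(m) expected_coverage_at_size(v, m)$value, numeric(1))
    expect_true(all(diff(cs) >= -1e-12))
    expect_true(all(cs >= 0 & cs <= 1))
  }
  expect_error(expected_coverage_at_size(v, v$n), "\\[1, n - 1\\]")
  expect_error(expected_coverage_at_size(v, 0), "\\[1, n - 1\\]")
})

test_that("size_at_coverage inverts the coverage curve conservatively", {
  v <- abundance_vector(c(2, 1), "shallow")
  expect_equal(size_at_coverage(v, 0.5), 2)  # C(1)=1/3, C(2)=2/3
  expect_equal(size_at_coverage(v, 0), 1)
  expect_error(size_at_coverage(v, 0.99), "clamp")
  # smallest qualifying m, checked by enumeration on random vectors
  set.seed(43)
  for (i in 1:10) {
    v <- random_vector(S = sample(3:10, 1), n = sample(10:80, 1))
    target <- runif(1, 0, expected_coverage_at_size(v, v$n - 1)$value)
    m <- size_at_coverage(v, target)
    cs <- vapply(seq_len(v$n - 1),
                 function(k) expected_coverage_at_size(v, k)$value, numeric(1))
    expect_equal(m, min(which(cs >= target)))
  }
})

test_that("Hill numbers match closed forms and are continuous at q = 1", {
  p <- rep(0.1, 10)
  for (q in c(0, 0.5, 1, 2, 3)) expect_equal(hill_number(p, q), 10)
  p <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(hill_number(p, 2), 1 / 0.30)
  expect_equal(hill_number(p, 1), exp(1.2798542), tolerance = 1e-6)
  expect_equal(hill_number(p, 1 - 1e-12), hill_number(p, 1))
  expect_lt(abs(hill_number(p, 1 + 1e-7) - hill_number(p, 1)), 1e-5)
  expect_error(hill_number(c(0.5, 0.4), 1), "sum to 1")
  expect_error(hill_number(c(1.2, -0.2), 1), "positive")
})

test_that("qD is non-increasing in q on random vectors", {
  set.seed(44)
  qs <- c(0, 0.5, 1, 2, 3)
  for (i in 1:50) {
    p <- rexp(sample(2:20, 1)); p <- p / sum(p)
    d <- vapply(qs, function(q) hill_number(p, q), numeric(1))
    expect_true(all(diff(d) <= 1e-10))
    expect_true(all(d >= 1 - 1e-12 & d <= length(p) + 1e-12))
  }
})

test_that("inverse Simpson: plugin, interpolated, and their m = n identity", {
  expect_equal(inverse_simpson(abundance_vector(10))$value, 1)
  expect_equal(inverse_simpson(abundance_vector(c(4, 3, 2, 1)))$value, 100 / 30)
  expect_equal(inverse_simpson(abundance_vector(c(5, 5, 5, 5)))$value, 4)

  v <- abundance_vector(c(4, 3, 2, 1))
  expect_equal(rarefied_inverse_simpson(v, 10)$value, 100 / 30)
  expect_equal(rarefied_inverse_simpson(v, 2)$value, 1 / (0.5 + 0.5 * 20 / 90))
  expect_equal(rarefied_inverse_simpson(abundance_vector(10), 4)$value, 1)
  expect_error(rarefied_inverse_simpson(v, 11), "\\[1, n\\]")

  set.seed(45)
  for (i in 1:25) {
    v <- random_vector(S = sample(2:20, 1), n = sample(10:500, 1))
    expect_equal(rarefied_inverse_simpson(v, v$n)$value,
                 inverse_simpson(v)$value, tolerance = 1e-12)
    # non-decreasing in m
    ms <- sort(sample(seq_len(v$n), min(6, v$n)))
    d <- vapply(ms, function(m) rarefied_inverse_simpson(v, m)$value, numeric(1))
    expect_true(all(diff(d) >= -1e-12))
  }
})

test_that("Chao-Shen effective functions match term-by-term evaluation", {
  expect_equal(chao_shen_effective_functions(abundance_vector(50))$value, 1)
  r <- chao_shen_effective_functions(abundance_vector(c(4, 3, 2, 1)))
  expect_equal(r$H, 1.4542605, tolerance = 1e-6)
  expect_equal(r$value, 4.2813127, tolerance = 1e-6)
  expect_equal(r$value, exp(r$H))
  # large even community: converges to the true richness
  r50 <- chao_shen_effective_functions(abundance_vector(rep(200, 50)))
  expect_equal(r50$value, 50, tolerance = 0.01)
  expect_warning(chao_shen_effective_functions(abundance_vector(c(1, 1, 1))),
                 "singletons")
})

test_that("Chao-Shen dominates plugin Shannon without singletons, converges with n", {
  set.seed(46)
  for (i in 1:10) {
    x <- sample(2:40, sample(3:12, 1), replace = TRUE)  # no singletons
    v <- abundance_vector(x)
    p <- x / sum(x)
    expect_gte(chao_shen_effective_functions(v)$H, -sum(p * log(p)) - 1e-12)
  }
  x <- drop(rmultinom(1, 10000, rep(1 / 40, 40)))
  v <- abundance_vector(x)
  p <- v$counts / v$n
  plugin <- exp(-sum(p * log(p)))
  expect_equal(chao_shen_effective_functions(v)$value, plugin, tolerance = 0.01)
})

test_that("estimators are invariant to feature order and appended zeros", {
  set.seed(47)
  x <- c(7, 5, 3, 1, 1)
  names(x) <- paste0("f", 1:5)
  v <- abundance_vector(x)
  vz <- abundance_vector(c(x, fz1 = 0, fz2 = 0))
  vp <- abundance_vector(sample(x))
  for (f in list(function(v) good_turing_coverage(v)$value,
                 function(v) expected_coverage_at_size(v, 5)$value,
                 function(v) inverse_simpson(v)$value,
                 function(v) rarefied_inverse_simpson(v, 6)$value,
                 function(v) chao_shen_effective_functions(v)$value)) {
    expect_equal(f(vz), f(v))
    expect_equal(f(vp), f(v))
  }
})

test_that("hypergeometric subsampler is seeded, exact at m = n, and unbiased", {
  v <- abundance_vector(c(f1 = 2, f2 = 1))
  expect_equal(sort(subsample_without_replacement(v, 3, seed = 1)$counts),
               sort(v$counts))
  a <- subsample_without_replacement(v, 2, seed = 99)
  b <- subsample_without_replacement(v, 2, seed = 99)
  expect_identical(a$counts, b$counts)
  expect_error(subsample_without_replacement(v, 4, seed = 1), "\\[1, n\\]")
  # P(the drawn read is from feature 1) = 2/3
  hits <- vapply(1:10000, function(s) {
    sub <- subsample_without_replacement(v, 1, seed = s)
    identical(names(sub$counts), "f1")
  }, logical(1))
  expect_equal(mean(hits), 2 / 3, tolerance = 0.03)
})

test_that("interpolated 2D matches subsampling exactly on the concentration scale", {
  # E over hypergeometric subsamples of sum Y(Y-1)/(m(m-1)) equals
  # sum X(X-1)/(n(n-1)); the analytic 2D(m) is the Hill transform of that
  # unbiased concentration, so the Monte-Carlo check is done on the linear
  # scale where the estimator is exactly unbiased.
  set.seed(48)
  for (i in 1:5) {
    v <- random_vector(S = sample(4:10, 1), n = sample(50:200, 1))
    n <- v$n
    m <- sample(2:(n - 1), 1)
    mat <- matrix(rep(v$counts, each = 2000), nrow = 2000)
    sub <- suppressWarnings(vegan::rrarefy(mat, m))
    lam <- rowSums(sub * (sub - 1)) / (m * (m - 1))
    lam0 <- sum(v$counts * (v$counts - 1)) / (n * (n - 1))
    expect_lt(abs(mean(lam) - lam0), 3.5 * sd(lam) / sqrt(2000) + 1e-12)
    expect_equal(rarefied_inverse_simpson(v, m)$value,
                 1 / (1 / m + (1 - 1 / m) * lam0))
  }
})

test_that("common-coverage rarefaction targets the lowest-coverage sample", {
  # two identical samples: both kept at m = n - 1 with identical 2D
  v <- abundance_vector(c(8, 4, 2, 1), "a")
  w <- abundance_vector(c(8, 4, 2, 1), "b")
  res <- rarefy_to_common_coverage(list(v, w))
  expect_equal(res[[1]]$rarefied_to, 14)
  expect_equal(res[[2]]$rarefied_to, 14)
  expect_equal(res[[1]]$value, res[[2]]$value)

  # a deep even sample vs the shallow (2,1) sample: C* = 2/3 set by the
  # shallow one (kept at m = n - 1 = 2), the deep one rarefied down
  deep <- abundance_vector(rep(10, 10), "deep")
  shallow <- abundance_vector(c(2, 1), "shallow")
  res2 <- rarefy_to_common_coverage(list(deep, shallow))
  expect_equal(attr(res2, "target_coverage"), 2 / 3)
  expect_equal(res2[[2]]$rarefied_to, 2)
  expect_lt(res2[[1]]$rarefied_to, deep$n - 1)
  expect_equal(res2[[1]]$rarefied_to, size_at_coverage(deep, 2 / 3))

  # degenerate sample is named
  expect_error(
    rarefy_to_common_coverage(list(deep, abundance_vector(c(1, 1), "bad"))),
    "bad")

  # monte-carlo mode reports a mean near the analytic value at m close to n
  res_mc <- rarefy_to_common_coverage(list(v, w), mode = "montecarlo",
                                      reps = 200, seed = 5)
  expect_equal(res_mc[[1]]$value, res[[1]]$value, tolerance = 0.1)
})
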