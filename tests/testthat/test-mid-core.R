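test_that("area normalization reproduces published percent fractions", {
  m <- normalize_mid(c(9674, 323, 4, 0), analyte = "Ser")
  expect_equal(unname(m$fractions), c(0.9674, 0.0323, 0.0004, 0), tolerance = 1e-4)
  expect_false(m$corrected)
  expect_equal(unname(normalize_mid(c(1, 0, 0, 0))$fractions), c(1, 0, 0, 0))
  set.seed(3)
  expect_equal(sum(normalize_mid(stats::rexp(6))$fractions), 1, tolerance = 1e-12)
  expect_error(normalize_mid(c(0, 0, 0)), "not detected")
})

test_that("the carbon-only binomial reproduces the natural-abundance column", {
  expect_equal(round_half_up(100 * unname(natural_mid(3)$fractions)),
               c(96.74, 3.23, 0.04, 0.00))
  expect_equal(round_half_up(100 * unname(natural_mid(4)$fractions)),
               c(95.67, 4.26, 0.07, 0.00, 0.00))
  expect_equal(round_half_up(100 * unname(natural_mid(5)$fractions)),
               c(94.62, 5.26, 0.12, 0.00, 0.00, 0.00))
  expect_equal(unname(natural_mid(4, p13 = 0)$fractions), c(1, 0, 0, 0, 0))
})

test_that("the natural-abundance matrix is a stochastic lower-triangular map", {
  for (n in c(3, 5)) {
    A <- na_matrix(n)
    expect_true(all(A[upper.tri(A)] == 0))
    expect_equal(colSums(A), rep(1, n + 1L), tolerance = 1e-12)
    expect_lt(kappa(A), 2) # well-conditioned at p = 0.011
  }
})

test_that("forward convolution agrees with per-carbon Bernoulli enumeration", {
  expect_equal(unname(convolve_natural(c(1, 0, 0, 0, 0))$fractions),
               unname(natural_mid(4)$fractions), tolerance = 1e-12)
  expect_equal(unname(convolve_natural(c(0, 0, 0, 1))$fractions),
               c(0, 0, 0, 1)) # fully labeled carbons cannot gain
  set.seed(21)
  for (i in 1:5) {
    x <- rand_simplex(6) # n = 5
    expect_equal(unname(convolve_natural(x)$fractions),
                 oracle_convolve(x, 0.011), tolerance = 1e-12)
  }
})

test_that("correction inverts convolution on the simplex", {
  un <- correct_mid(natural_mid(3))
  expect_equal(unname(un$fractions), c(1, 0, 0, 0), tolerance = 1e-9)
  set.seed(33)
  for (n in 3:5) for (i in 1:20) {
    x <- rand_simplex(n + 1L)
    back <- correct_mid(convolve_natural(x))
    expect_equal(unname(back$fractions), x, tolerance = 1e-8)
    back2 <- correct_mid(convolve_natural(x), method = "inverse")
    expect_equal(unname(back2$fractions), x, tolerance = 1e-8)
  }
})

test_that("NNLS and triangular-inverse oracles agree on the published Ser spectrum", {
  measured <- mid(c(84.99, 13.45, 1.57, 0) / 100, analyte = "Ser", normalize = TRUE)
  by_nnls <- correct_mid(measured, method = "nnls")
  by_inv <- correct_mid(measured, method = "inverse")
  # frozen from two independent solution routes (they differ only in how the
  # small negative M+3 component is removed)
  expect_equal(unname(by_nnls$fractions)[1], 0.8783, tolerance = 2e-4)
  expect_equal(unname(by_inv$fractions)[1], 0.8785, tolerance = 2e-4)
  expect_equal(unname(by_nnls$fractions), unname(by_inv$fractions), tolerance = 5e-4)
  expect_true(attr(by_nnls, "consistent"))
})

test_that("an unphysical spectrum is flagged as inconsistent", {
  # M+1 far below what M+0 alone would generate naturally
  bad <- mid(c(0.90, 0.0, 0.10, 0), normalize = TRUE)
  expect_warning(out <- correct_mid(bad, residual_tol = 1e-4), "inconsistent")
  expect_false(attr(out, "consistent"))
  expect_true(all(out$fractions >= 0))
})

test_that("enrichment is the mean labeled fraction and is monotone", {
  expect_equal(enrichment(c(1, 0, 0, 0)), 0)
  expect_equal(enrichment(c(0, 0, 0, 1)), 1)
  set.seed(9)
  for (i in 1:10) {
    x <- rand_simplex(5)
    k <- sample(which(x[-5] > 0), 1)
    y <- x
    eps <- x[k] / 2
    y[k] <- y[k] - eps; y[k + 1] <- y[k + 1] + eps # shift mass one label up
    expect_gt(enrichment(y), enrichment(x))
  }
})

test_that("mid_table mirrors the published table layout", {
  tab <- mid_table(list(Ser = natural_mid(3)), condition = "natural")
  expect_equal(tab$abundance_percent, c(96.74, 3.23, 0.04, 0.00))
  expect_equal(tab$isotopologue, paste0("M+", 0:3))
})
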