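test_that("log_transform maps unmasked entries and errors on non-positive", {
  m <- matrix(c(1, exp(1), NA, 4), 2, 2)
  lt <- log_transform(list(values = m, mask = is.na(m)))
  expect_equal(lt$values[1, 1], 0)
  expect_equal(lt$values[2, 1], 1)
  expect_true(is.na(lt$values[1, 2]) || lt$mask[1, 2])
  expect_error(log_transform(matrix(c(1, -2), 1)), "non-positive entry")
  # masked non-positive entries are fine
  m2 <- matrix(c(1, -5), 1)
  expect_silent(log_transform(list(values = m2,
                                   mask = matrix(c(FALSE, TRUE), 1))))
})

test_that("fit reproduces hand-computed mean and covariance on a toy cohort", {
  # log-matrix rows (0,0), (1,2), (2,4): mean (1,2); covariance by the
  # explicit 1/(n-1) double sum: [[1,2],[2,4]]
  sch <- vp_schema(vp_variable("a"), vp_variable("b"))
  co <- vp_cohort(data.frame(a = exp(c(0, 1, 2)), b = exp(c(0, 2, 4))), sch)
  m <- vp_fit(co)
  expect_equal(unname(m$mu), c(1, 2), tolerance = 1e-12)
  oracle_sigma <- matrix(0, 2, 2)
  lx <- cbind(c(0, 1, 2), c(0, 2, 4))
  for (i in 1:2) for (j in 1:2)
    oracle_sigma[i, j] <- sum((lx[, i] - mean(lx[, i])) *
                              (lx[, j] - mean(lx[, j]))) / 2
  expect_equal(unname(m$sigma), oracle_sigma, tolerance = 1e-12)
  expect_equal(oracle_sigma, matrix(c(1, 2, 2, 4), 2))

  # alternative mean normalization divides sums by n-1
  m2 <- vp_fit(co, mean_norm = "n-1")
  expect_equal(unname(m2$mu), c(1.5, 3), tolerance = 1e-12)
  # covariance is unaffected by the mean-normalization flag
  expect_equal(m2$sigma, m$sigma)
})

test_that("fit refuses missing cells and undersized cohorts", {
  sch <- vp_schema(vp_variable("a"), vp_variable("b"))
  co <- vp_cohort(data.frame(a = c(1, NA), b = c(2, 3)), sch)
  expect_error(vp_fit(co), "impute first")
  co1 <- vp_cohort(data.frame(a = 1, b = 2), sch)
  expect_error(vp_fit(co1), "at least 2 patients")
})

test_that("identical rows give a zero covariance and zero eigenvalues", {
  sch <- vp_schema(vp_variable("a"), vp_variable("b"))
  co <- vp_cohort(data.frame(a = rep(2, 5), b = rep(3, 5)), sch)
  m <- vp_fit(co)
  expect_equal(unname(m$sigma), matrix(0, 2, 2))
  expect_equal(m$Lambda, c(0, 0))
})

test_that("decomposition reconstructs sigma and matches the p=2 oracle", {
  set.seed(101)
  for (i in 1:20) {
    a <- matrix(rnorm(4), 2)
    s <- a %*% t(a)
    dec <- decompose_covariance(s)
    expect_equal(dec$U %*% diag(dec$Lambda) %*% t(dec$U), s,
                 tolerance = 1e-8)
    orc <- eigen2_oracle(s)
    expect_equal(dec$Lambda, orc$values, tolerance = 1e-8)
    # eigenvectors match up to sign
    for (j in 1:2)
      expect_equal(abs(sum(dec$U[, j] * orc$vectors[, j])), 1,
                   tolerance = 1e-8)
  }
  # trivial cases
  expect_equal(decompose_covariance(diag(3))$Lambda, c(1, 1, 1))
  expect_equal(sort(decompose_covariance(diag(c(2, 0.5)))$Lambda),
               c(0.5, 2))
  expect_error(decompose_covariance(matrix(c(1, 0.5, 0, 1), 2)),
               "symmetric")
})

test_that("tiny negative eigenvalues from rounding are clipped to zero", {
  u <- cbind(c(1, 1) / sqrt(2), c(1, -1) / sqrt(2))
  s <- u %*% diag(c(2, -1e-14)) %*% t(u)
  s <- (s + t(s)) / 2
  dec <- decompose_covariance(s)
  expect_true(all(dec$Lambda >= 0))
  expect_equal(min(dec$Lambda), 0)
})

test_that("both backends satisfy K K' = Sigma, including rank-deficient", {
  truth <- mixed_truth()
  co <- make_cohort(truth, 60, seed = 5)
  for (bk in c("eigen", "cholesky")) {
    m <- vp_fit(co, backend = bk)
    expect_equal(m$K %*% t(m$K), m$sigma, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # a duplicated column makes Sigma singular; reconstruction must still hold
  sch <- vp_schema(vp_variable("a"), vp_variable("b"))
  x <- exp(rnorm(20))
  co2 <- vp_cohort(data.frame(a = x, b = x^2), sch)  # log-b = 2 log-a
  for (bk in c("eigen", "cholesky")) {
    m2 <- vp_fit(co2, backend = bk)
    expect_equal(m2$K %*% t(m2$K), m2$sigma, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("fitting recovers known parameters as the sample grows", {
  truth <- tiny_truth(r = 0.6)
  n <- 10000
  co <- make_cohort(truth, n, seed = 21)
  m <- vp_fit(co)
  bound <- 5 * max(diag(truth$sigma_true)) / sqrt(n)
  expect_lt(max(abs(diag(m$sigma) - diag(truth$sigma_true))), bound)
  expect_lt(max(abs(m$mu - truth$mu_true)), bound)
  # off-diagonals too
  expect_lt(max(abs(m$sigma - truth$sigma_true)), bound)
})

test_that("model JSON serialization round-trips", {
  truth <- mixed_truth()
  co <- make_cohort(truth, 40, seed = 9)
  m <- vp_fit(co)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$mu, m$mu)
  expect_equal(m2$sigma, m$sigma, ignore_attr = TRUE)
  expect_equal(m2$Lambda, m$Lambda)
  expect_equal(m2$K, m$K, ignore_attr = TRUE)
  expect_equal(vapply(m2$schema, `[[`, "", "kind"),
               vapply(m$schema, `[[`, "", "kind"))
  # generation from the deserialized model is identical
  expect_equal(vp_generate(m2, 50, seed = 3)$data,
               vp_generate(m, 50, seed = 3)$data)
})
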