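test_that("proxy interpolation is exact at knots and linear between", {
  s <- data.frame(age_calBP = c(0, 100, 300), value = c(0, 10, 20))
  expect_equal(interpolate_proxy(s, c(0, 100, 300)), c(0, 10, 20))
  expect_equal(interpolate_proxy(s, 50), 5)
  expect_equal(interpolate_proxy(s, 200), 15)
  # outside the support: missing, never extrapolated
  expect_true(all(is.na(interpolate_proxy(s, c(-10, 301)))))
  expect_error(interpolate_proxy(
    data.frame(age_calBP = c(1, 1), value = 1:2), 1), "duplicate")
  # construction oracle: re-interpolating a piecewise-linear truth at its
  # own knots is exact
  set.seed(1)
  knots <- sort(runif(20, 0, 1000))
  vals <- cumsum(rnorm(20))
  s2 <- data.frame(age_calBP = knots, value = vals)
  expect_equal(interpolate_proxy(s2, knots), vals)
})

test_that("standardization centers, scales, and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(50, mean = 7, sd = 3))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5), name = "IP25"), "IP25")
  expect_error(standardize(c(1, NA, NA)), "non-missing")
})

test_that("integrated tables carry standardized proxies and missingness", {
  det <- matrix(c(5, 0, 2, 1, 3, 0), nrow = 3,
                dimnames = list(c("S1", "S2", "S3"), c("seal", "whale")))
  ages <- data.frame(sample_id = c("S1", "S2", "S3"),
                     age_median = c(100, 500, 2000))
  proxies <- list(
    temperature = data.frame(age_calBP = c(0, 1000), value = c(1, 3)),
    ip25 = data.frame(age_calBP = c(0, 3000), value = c(0, 6)))
  tab <- integrate_table(det, ages, proxies)
  expect_equal(mean(tab$ip25), 0, tolerance = 1e-9)
  expect_equal(sd(tab$ip25), 1, tolerance = 1e-9)
  # S3 (2000 BP) is outside the temperature record
  expect_true(is.na(tab$temperature[3]))
  expect_equal(mean(tab$temperature, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(tab$seal, c(5, 0, 2))
})

test_that("Spearman handles monotone, tied and transformed data", {
  x <- 1:10
  m <- spearman_matrix(data.frame(a = x, b = x^3, c = rev(x)))
  expect_equal(m$rs["a", "b"], 1)
  expect_equal(m$rs["a", "c"], -1)
  expect_equal(m$p["a", "b"], 0)
  # brute-force rank oracle with average ranks on tied toy data
  tx <- c(1, 2, 2, 3, 5, 5, 5, 8)
  ty <- c(10, 20, 20, 40, 35, 50, 50, 60)
  rk <- function(v) rank(v, ties.method = "average")
  oracle <- function(a, b) {
    ra <- rk(a); rb <- rk(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  m2 <- spearman_matrix(data.frame(x = tx, y = ty))
  expect_equal(m2$rs["x", "y"], oracle(tx, ty))
  # t-approximation p-value with n - 2 df
  rs <- oracle(tx, ty); n <- 8
  tstat <- rs * sqrt((n - 2) / (1 - rs^2))
  expect_equal(m2$p["x", "y"], 2 * pt(-abs(tstat), n - 2))
  # invariance under monotone transforms
  m3 <- spearman_matrix(data.frame(x = exp(tx), y = ty))
  expect_equal(m3$rs["x", "y"], m2$rs["x", "y"])
  # symmetry + unit diagonal
  expect_equal(m$rs, t(m$rs))
  expect_equal(unname(diag(m$rs)), rep(1, 3))
})

test_that("small pairwise samples are flagged without p-values", {
  d <- data.frame(a = c(1, 2, 3, 4, NA, NA), b = c(2, 1, 4, NA, 5, 6))
  m <- spearman_matrix(d)
  expect_equal(m$n["a", "b"], 3)
  expect_true(is.na(m$p["a", "b"]))
  expect_false(m$table$kept[1])
})

test_that("RDA matches the eigendecomposition oracle and vegan", {
  set.seed(2)
  Y <- matrix(rnorm(40), 10, 4)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("t", "i")))
  fit <- rda(Y, X, n_perm = 99, seed = 1)
  # oracle: eigenvalues of the covariance of lm() fitted values
  Yc <- scale(Y, scale = FALSE)
  fv <- fitted(lm(Yc ~ scale(X)))
  ev_oracle <- eigen(cov(fv), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fit$eigenvalues, ev_oracle[seq_along(fit$eigenvalues)],
               tolerance = 1e-8)
  # independent cross-check against vegan's constrained eigenvalues
  skip_if_not_installed("vegan")
  vfit <- vegan::rda(Y ~ scale(X))
  expect_equal(unname(fit$eigenvalues[1:2]),
               unname(vfit$CCA$eig[1:2]), tolerance = 1e-6)
  expect_equal(fit$constrained_fraction,
               unname(vfit$CCA$tot.chi / vfit$tot.chi), tolerance = 1e-8)
})

test_that("variance fractions partition and permutation p is reproducible", {
  set.seed(3)
  Y <- matrix(rnorm(60), 20, 3)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  f1 <- rda(Y, X, n_perm = 199, seed = 7)
  f2 <- rda(Y, X, n_perm = 199, seed = 7)
  expect_equal(f1$terms$p, f2$terms$p)
  expect_equal(f1$constrained_fraction + f1$residual_fraction, 1,
               tolerance = 1e-9)
  expect_true(all(f1$terms$fraction >= 0 & f1$terms$fraction <= 1))
  expect_true(all(f1$terms$p >= 1 / 200 & f1$terms$p <= 1))
})

test_that("a perfectly constraining term reaches the minimal p", {
  set.seed(4)
  x <- rnorm(15)
  fit <- rda(matrix(x), matrix(x, dimnames = list(NULL, "x")),
             n_perm = 99, seed = 5)
  expect_equal(fit$constrained_fraction, 1, tolerance = 1e-12)
  expect_equal(fit$terms$p, 1 / 100)
})

test_that("collinear explanatory terms are rejected by name", {
  set.seed(5)
  x <- rnorm(12)
  X <- cbind(temp = x, temp2 = 2 * x)
  expect_error(rda(matrix(rnorm(24), 12, 2), X, n_perm = 9),
               "collinear")
})

test_that("a strong simulated driver is detected by the RDA", {
  set.seed(6)
  n <- 30
  temp <- rnorm(n)
  Y <- cbind(3 * temp + rnorm(n), rnorm(n), rnorm(n))
  X <- cbind(temperature = temp, noise = rnorm(n))
  fit <- rda(Y, X, n_perm = 199, seed = 8)
  expect_lt(fit$terms$p[fit$terms$term == "temperature"], 0.05)
  expect_gt(fit$terms$p[fit$terms$term == "noise"], 0.05)
})
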