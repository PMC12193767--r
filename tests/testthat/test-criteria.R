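test_that("determination coefficient and error statistics match closed forms", {
  obs <- c(0, 1, 2, 3)
  calc <- c(0, 1, 2, 2)
  expect_equal(r_squared(obs, calc), stats::cor(obs, calc)^2, tolerance = 1e-12)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, -obs), 1)  # correlation is squared

  expect_identical(rmse(c(1, -1), c(0, 0)), 1)
  expect_identical(mae(c(1, -1), c(0, 0)), 1)
  expect_equal(rmse(c(3, 0, 0, 0), c(0, 0, 0, 0)), 1.5)
  expect_equal(mae(c(3, 0, 0, 0), c(0, 0, 0, 0)), 0.75)
  expect_identical(rmse(1:4, 1:4), 0)

  expect_error(r_squared(rep(1, 4), 1:4), "constant")
})

test_that("Fisher F-ratio follows r2 * (n-2) / (1-r2)", {
  # construct a series of length 77 with r^2 exactly 0.5 is fiddly; verify
  # the closed form through r_squared on random series instead
  s <- random_series(77L, seed = 1L)
  r2 <- r_squared(s$observed, s$calculated)
  expect_equal(f_ratio(s$observed, s$calculated), r2 * 75 / (1 - r2),
               tolerance = 1e-12)
  s3 <- list(observed = c(0, 1, 3), calculated = c(0.1, 0.9, 3.2))
  r2 <- r_squared(s3$observed, s3$calculated)
  expect_equal(f_ratio(s3$observed, s3$calculated), r2 * 1 / (1 - r2),
               tolerance = 1e-12)
  expect_warning(f <- f_ratio(c(0, 1, 3), c(0, 2, 6)), "infinite")
  expect_identical(f, Inf)
})

test_that("concordance penalizes shift and scale, matching its closed form", {
  s <- random_series(20L, seed = 2L)
  x <- s$observed; y <- s$calculated
  n <- length(x)
  cv <- mean((x - mean(x)) * (y - mean(y)))
  want <- 2 * cv / (mean((x - mean(x))^2) + mean((y - mean(y))^2) +
                      (mean(x) - mean(y))^2)
  expect_equal(ccc(x, y), want, tolerance = 1e-12)
  expect_equal(ccc(x, x), 1)
  # location shift costs concordance but not correlation
  expect_lt(ccc(x, x + 1), stats::cor(x, x + 1))
  expect_equal(ccc(rep(2, 5), rep(2, 5)), 1)
  expect_error(ccc(rep(2, 5), rep(3, 5)), "constant")
})

test_that("IIC rewards symmetric residuals and zeroes one-sided fits", {
  calc <- as.numeric(1:10)
  resid <- rep(c(0.5, -0.5), 5)
  obs <- calc + resid
  # symmetric classes: MAE- == MAE+, so IIC equals the plain correlation
  expect_equal(iic(obs, calc), stats::cor(obs, calc), tolerance = 1e-12)
  # constant bias puts every residual in one class
  expect_identical(iic(calc + 1, calc), 0)
  # perfect fit: all residuals land in the >= 0 class
  expect_identical(iic(calc, calc), 0)
  # asymmetric residuals shrink IIC below r
  obs2 <- calc + c(rep(0.8, 5), rep(-0.2, 5))
  expect_lt(iic(obs2, calc), stats::cor(obs2, calc))
})

test_that("CII is 1 for exact collinearity and follows the LOO protest oracle", {
  x <- as.numeric(1:6)
  expect_equal(cii(x, 2 * x + 1), 1)
  withline <- c(1, 2, 3, 4, 5, 20)  # outlier opposes the correlation
  y <- c(1, 2, 3, 4, 5, 6)
  expect_equal(cii(withline, y), oracle_cii(withline, y), tolerance = 1e-10)
  expect_lt(cii(withline, y), 1)
  # duplicating every point dilutes each protest
  s <- random_series(8L, seed = 5L)
  dup <- list(observed = rep(s$observed, 2L), calculated = rep(s$calculated, 2L))
  expect_gte(cii(dup$observed, dup$calculated) -
               cii(s$observed, s$calculated), -1e-10)
})

test_that("CII and CCCP agree with brute-force leave-one-out on random series", {
  for (i in 1:50) {
    n <- 5L + (i %% 11L)
    s <- random_series(n, seed = 100L + i)
    expect_equal(cii(s$observed, s$calculated),
                 oracle_cii(s$observed, s$calculated), tolerance = 1e-10)
    expect_equal(cccp(s$observed, s$calculated),
                 oracle_cccp(s$observed, s$calculated), tolerance = 1e-12)
  }
})

test_that("CCCP balances supporters against opponents", {
  s <- random_series(8L, seed = 9L)
  loo <- oracle_loo_r2(s$observed, s$calculated)
  r2 <- r_squared(s$observed, s$calculated)
  want <- (sum(loo < r2) - sum(loo > r2)) / 8
  expect_equal(cccp(s$observed, s$calculated), want, tolerance = 1e-12)
  expect_lte(abs(cccp(s$observed, s$calculated)), 1)
})

test_that("Q2 matches an explicit leave-one-out loop and never exceeds R2", {
  expect_equal(q2_loo(2 * (1:6) + 3, as.numeric(1:6)), 1)
  for (i in 1:10) {
    s <- random_series(6L + i, seed = 200L + i)
    expect_equal(q2_loo(s$observed, s$calculated),
                 oracle_q2_loo(s$observed, s$calculated), tolerance = 1e-10)
    expect_lte(q2_loo(s$observed, s$calculated),
               r_squared(s$observed, s$calculated) + 1e-12)
  }
  expect_error(q2_loo(1:5, rep(1, 5)), "constant")
})

test_that("correlation-shape statistics are invariant under positive affine maps", {
  s <- random_series(12L, seed = 33L)
  x <- s$observed; y <- s$calculated
  y2 <- 2.5 * y + 7
  expect_equal(r_squared(x, y), r_squared(x, y2), tolerance = 1e-10)
  expect_equal(cii(x, y), cii(x, y2), tolerance = 1e-10)
  expect_equal(cccp(x, y), cccp(x, y2), tolerance = 1e-12)
  # iic is residual-based: invariant when both series shift/scale together
  expect_equal(iic(x, y), iic(x + 3, y + 3), tolerance = 1e-12)
  expect_equal(iic(2 * x, 2 * y), iic(x, y), tolerance = 1e-12)
})

test_that("stat blocks have the reporting shape and respect range invariants", {
  for (i in 1:8) {
    s <- random_series(10L + i, seed = 300L + i)
    sb <- stat_block(s$observed, s$calculated, n_active = 5L)
    expect_identical(names(sb), c("n", "R2", "CCC", "IIC", "CII", "Q2",
                                  "CCCP", "RMSE", "MAE", "F", "N_A"))
    expect_true(sb$R2 >= 0 && sb$R2 <= 1)
    expect_true(abs(sb$CCC) <= 1)
    expect_true(abs(sb$IIC) <= 1)
    expect_lte(sb$CII, 1 + 1e-12)
    expect_true(abs(sb$CCCP) <= 1)
    expect_gte(sb$RMSE, sb$MAE)
    expect_gte(sb$MAE, 0)
  }
})
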