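test_that("log transform applies the half-minimum-non-zero offset rule", {
  no_zero <- log_offset_transform(c(1, 2, 4))
  expect_equal(no_zero$offset, 0)
  expect_equal(no_zero$values, log(c(1, 2, 4)))

  with_zero <- log_offset_transform(c(0, 2, 4))
  expect_equal(with_zero$offset, 1)
  expect_equal(with_zero$values, log(c(1, 3, 5)))

  constant <- log_offset_transform(c(5, 5, 5))
  expect_equal(constant$values, rep(log(5), 3))

  with_na <- log_offset_transform(c(0, NA, 4))
  expect_equal(with_na$offset, 2)
  expect_true(is.na(with_na$values[2]))

  expect_error(log_offset_transform(c(-1, 2)), "negative")
  expect_error(log_offset_transform(c(0, 0)), "non-zero")
})

test_that("log and logit transforms invert exactly, offsets included", {
  set.seed(3)
  x <- c(0, 0, rlnorm(50, 0, 1))
  lt <- log_offset_transform(x)
  expect_equal(inverse_log_offset(lt$values, lt$offset), x, tolerance = 1e-12)

  expect_equal(logit_offset_transform(50)$values, 0)
  expect_equal(logit_offset_transform(c(25, 30))$values[1], log(1 / 3))

  p <- c(0, 100, runif(50, 0.5, 99.5))
  lg <- logit_offset_transform(p)
  expect_true(all(is.finite(lg$values)))
  back <- inverse_logit_offset(lg$values, lg$lower_offset, lg$upper_offset)
  expect_equal(back, p, tolerance = 1e-9)

  expect_error(logit_offset_transform(c(-0.1, 50)), "outside")
  expect_error(logit_offset_transform(c(101, 50)), "outside")
})

test_that("robust_fit interpolates exact linear data and symmetric data", {
  d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  fit <- robust_fit(d, y ~ x)
  expect_equal(unname(coef(fit)["x"]), 2, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)

  sym <- robust_fit(data.frame(y = c(1, 2, 3)), y ~ 1)
  expect_equal(unname(coef(sym)[1]), 2, tolerance = 1e-8)
  expect_equal(robust_mean(c(3, 3, 3)), 3)
  expect_equal(robust_mean(c(1, 2, 3)), 2, tolerance = 1e-8)
})

test_that("robust location matches an independent IRLS oracle under contamination", {
  x <- c(1, 2, 3, 100)
  expect_lt(abs(robust_mean(x) - oracle_huber_mean(x)), 0.5)
  # robust mean sits between the median and the arithmetic mean
  expect_gt(robust_mean(x), median(x))
  expect_lt(robust_mean(x), mean(x))

  set.seed(5)
  y <- c(rnorm(40), rnorm(5, 20))
  expect_lt(abs(robust_mean(y) - oracle_huber_mean(y)), 0.5)
  fit <- robust_fit(data.frame(y = y), y ~ 1)
  expect_equal(unname(coef(fit)[1]), robust_mean(y), tolerance = 1e-6)
})

test_that("robust fit agrees with MASS::rlm as an independent cross-check", {
  skip_if_not_installed("MASS")
  set.seed(8)
  d <- data.frame(x = rnorm(300))
  d$y <- 1 + 0.5 * d$x + rnorm(300, 0, 0.3)
  d$y[1:15] <- d$y[1:15] + 8 # one-sided outliers
  ours <- robust_fit(d, y ~ x)
  theirs <- MASS::rlm(y ~ x, data = d, k = 1.345, maxit = 100)
  # same estimand, independently implemented: slopes agree closely
  expect_equal(unname(coef(ours)["x"]), unname(coef(theirs)["x"]),
               tolerance = 0.02)
})

test_that("with Gaussian noise and no outliers the fit tracks least squares", {
  set.seed(11)
  n <- 1000
  d <- data.frame(x = rnorm(n), g = sample(c("a", "b"), n, replace = TRUE))
  d$y <- 1 + 0.3 * d$x + 0.5 * (d$g == "b") + rnorm(n)
  fit <- robust_fit(d, y ~ x + g)
  ols <- lm(y ~ x + g, data = d)
  se <- summary(ols)$coefficients[, 2]
  expect_lt(abs(coef(fit)["x"] - coef(ols)["x"]), 3 * se["x"])
  expect_lt(abs(coef(fit)["gb"] - coef(ols)["gb"]), 3 * se["gb"])
})

test_that("contaminating 10% of points barely moves the robust mean", {
  set.seed(13)
  x <- rnorm(200)
  x_cont <- x
  x_cont[1:20] <- x_cont[1:20] + 1000
  mean_shift <- mean(x_cont) - mean(x)
  robust_shift <- robust_mean(x_cont) - robust_mean(x)
  expect_lt(abs(robust_shift), 0.2 * abs(mean_shift))
})

test_that("categorical reference is the largest level, ties broken by label", {
  d <- data.frame(g = c("b", "b", "b", "a", "a", "c"), y = rnorm(6))
  fit <- robust_fit(d, y ~ g)
  expect_equal(unname(fit$reference_levels["g"]), "b")
  expect_setequal(setdiff(names(coef(fit)), "(Intercept)"), c("ga", "gc"))

  d2 <- data.frame(g = c("b", "b", "a", "a"), y = rnorm(4))
  fit2 <- robust_fit(d2, y ~ g)
  expect_equal(unname(fit2$reference_levels["g"]), "a")
})

test_that("degenerate terms are dropped with a warning, collinear designs fatal", {
  d <- data.frame(x = rnorm(20), z = 1, y = rnorm(20))
  expect_warning(fit <- robust_fit(d, y ~ x + z), "degenerate")
  expect_false("z" %in% names(coef(fit)))

  d3 <- data.frame(x = rnorm(20))
  d3$x2 <- 2 * d3$x
  d3$y <- rnorm(20)
  expect_error(robust_fit(d3, y ~ x + x2), "collinear")
})

test_that("rows with missing covariates are excluded from fitting but scored", {
  set.seed(21)
  d <- data.frame(x = rnorm(50))
  d$y <- 2 + d$x + rnorm(50, 0, 0.1)
  d$x[1:5] <- NA
  fit <- robust_fit(d, y ~ x)
  expect_equal(fit$nobs, 45)
  # scored through the intercept (centred covariate contribution 0)
  expect_false(anyNA(fit$fitted))
  expect_false(anyNA(fit$residuals))
})
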