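test_that("Cook's-distance filter removes planted influential points", {
  set.seed(101)
  n <- 50
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  sigma <- 0.5
  y <- 1 + 2 * X$x1 - X$x2 + rnorm(n, 0, sigma)
  y[17] <- y[17] + 20 * sigma
  flt <- cooksDistanceFilter(X, y)
  expect_true(17 %in% flt$removed)
  expect_true(all(setdiff(1:n, 17) %in% flt$retained))
  # cutoff is the stated multiple of the mean distance
  expect_equal(flt$cutoff, 10 * mean(flt$cooksDistances))
  # direct recomputation of the distances agrees
  cd <- stats::cooks.distance(stats::lm(y ~ ., cbind(X, y = y)))
  expect_equal(flt$cooksDistances, unname(cd))
  # an infinite multiplier removes nothing
  flt2 <- cooksDistanceFilter(X, y, foldMultiplier = Inf)
  expect_length(flt2$removed, 0L)
  # homogeneous data: nothing removed at this seed (reported property)
  yc <- 1 + 2 * X$x1 + rnorm(n, 0, sigma)
  fltc <- cooksDistanceFilter(X, yc)
  expect_lte(length(fltc$removed), 2L)
})

test_that("log transform of response factors is log10 with input checks", {
  expect_equal(logTransformRrf(c(1, 10, 100)), c(0, 1, 2))
  y <- exp(rnorm(20))
  expect_equal(10^logTransformRrf(y), y, tolerance = 1e-12)
  expect_error(logTransformRrf(c(1, -2, 3)), "observation")
  # a skewed log-normal sample is normal after the transform
  set.seed(11)
  z <- 10^rnorm(200, 0, 0.4)
  expect_gt(stats::shapiro.test(logTransformRrf(z))$p.value, 0.01)
  expect_lt(stats::shapiro.test(z)$p.value, 0.01)
})

test_that("stepwise AIC recovers planted signal predictors", {
  set.seed(42)
  n <- 120
  X <- as.data.frame(matrix(rnorm(n * 20), n, 20,
                            dimnames = list(NULL, paste0("x", 1:20))))
  y <- 2 * X$x3 - X$x7 + rnorm(n, 0, 0.5)
  sel <- stepwiseAicSelect(X, y)
  expect_true(all(c("x3", "x7") %in% sel))
  # deterministic
  expect_identical(sel, stepwiseAicSelect(X, y))

  # pure noise: few predictors survive and the gain over the null is
  # marginal
  y0 <- rnorm(n)
  sel0 <- stepwiseAicSelect(X, y0)
  expect_lte(length(sel0), 6L)

  # a duplicated column changes nothing (aliased columns are dropped)
  X2 <- cbind(X, x3dup = X$x3)
  sel2 <- stepwiseAicSelect(X2, y)
  fit1 <- stats::lm(y ~ ., cbind(X[sel], y = y))
  fit2 <- stats::lm(y ~ ., cbind(X2[sel2], y = y))
  expect_equal(stats::AIC(fit1), stats::AIC(fit2), tolerance = 1e-8)
})

test_that("repeated CV partitions observations and nails the noiseless case", {
  set.seed(3)
  n <- 60
  X <- as.data.frame(matrix(rnorm(n * 4), n, 4,
                            dimnames = list(NULL, paste0("x", 1:4))))
  beta <- c(1.5, -2, 0.5, 3)
  y <- as.matrix(X) %*% beta + 0.7
  m <- fitMlrRepeatedCv(X, as.numeric(y), cvConfig(folds = 10,
                                                   repeats = 5,
                                                   seed = 9))
  expect_lt(mean(m@cvMetrics$rmse), 1e-8)
  expect_equal(unname(m@coefficients[paste0("x", 1:4)]), beta,
               tolerance = 1e-8)
  expect_equal(unname(m@coefficients["(Intercept)"]), 0.7,
               tolerance = 1e-8)
  # every repeat uses each observation exactly once as test material
  agg <- stats::aggregate(nTest ~ repeat_, m@cvMetrics, sum)
  expect_true(all(agg$nTest == n))
  expect_equal(nrow(m@cvMetrics), 50L)
  expect_error(fitMlrRepeatedCv(X[1:5, ], y[1:5],
                                cvConfig(folds = 10, seed = 1)),
               "folds")
})

test_that("held-out error on the default generator sits at the noise floor", {
  fx <- trainedFixture()
  cvMae <- mean(fx$rrtFit$model@cvMetrics$mae)
  floorMae <- fx$spec$sigmaRrt * sqrt(2 / pi)
  expect_gte(cvMae, 0.8 * floorMae)
  expect_lte(cvMae, 1.6 * floorMae)
})

test_that("prediction intervals behave and reach nominal coverage", {
  set.seed(77)
  n <- 120
  X <- as.data.frame(matrix(rnorm(n * 5), n, 5,
                            dimnames = list(NULL, paste0("x", 1:5))))
  y <- 1 + as.matrix(X) %*% c(2, -1, 0.5, 0, 1) + rnorm(n, 0, 0.8)
  m <- fitMlrRepeatedCv(X, as.numeric(y), cvConfig(seed = 5))

  # narrowest interval at the training centroid
  dat <- m@fit$model
  Xtr <- dat[, setdiff(colnames(dat), ".y"), drop = FALSE]
  centroid <- colMeans(Xtr)
  wAt <- function(x) {
    p <- predictWithInterval(m, x)
    p$upper - p$lower
  }
  wc <- wAt(centroid)
  for (i in c(1, 11, 29)) {
    expect_gte(wAt(unlist(Xtr[i, ])) + 1e-12, wc)
  }
  # interval brackets the point estimate
  p <- predictWithInterval(m, centroid)
  expect_lte(p$lower, p$point); expect_gte(p$upper, p$point)
  expect_error(predictWithInterval(m, c(x1 = 1)), "missing predictor")

  # empirical coverage at 95% over 1000 fresh points
  set.seed(991)
  Xnew <- as.data.frame(matrix(rnorm(1000 * 5), 1000, 5,
                               dimnames = list(NULL, paste0("x", 1:5))))
  ynew <- 1 + as.matrix(Xnew) %*% c(2, -1, 0.5, 0, 1) + rnorm(1000, 0, 0.8)
  pi95 <- predictResponse(m, Xnew, interval = TRUE)
  cov <- mean(ynew >= pi95$lwr & ynew <= pi95$upr)
  expect_gte(cov, 0.93); expect_lte(cov, 0.97)

  # intervals shrink as the training size grows (nested subsets of one
  # synthetic draw)
  set.seed(8)
  Xall <- as.data.frame(matrix(rnorm(240 * 3), 240, 3,
                               dimnames = list(NULL, paste0("x", 1:3))))
  yall <- as.matrix(Xall) %*% c(1, 2, -1) + rnorm(240, 0, 0.5)
  widths <- vapply(c(15, 60, 240), function(nn) {
    mn <- fitMlrRepeatedCv(Xall[seq_len(nn), ],
                           as.numeric(yall[seq_len(nn)]),
                           cvConfig(folds = 5, repeats = 2, seed = 2))
    p <- predictWithInterval(mn, c(x1 = 0, x2 = 0, x3 = 0))
    p$upper - p$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  # noiseless data give (numerically) zero-width intervals
  y0 <- as.matrix(X) %*% c(2, -1, 0.5, 0, 1)
  m0 <- fitMlrRepeatedCv(X, as.numeric(y0), cvConfig(seed = 5))
  p0 <- predictWithInterval(m0, centroid)
  expect_lt(p0$upper - p0$lower, 1e-6)
})

test_that("prediction metrics match their direct formulas", {
  x <- c(1, 2, 3, 4)
  m <- evaluatePredictions(x, x, tolerance = 0.1)
  expect_equal(m$RSQ, 1); expect_equal(m$MAE, 0); expect_equal(m$RMSE, 0)
  expect_equal(m$fracWithin, 1)

  m2 <- evaluatePredictions(x + 2, x)
  expect_equal(m2$MAE, 2); expect_equal(m2$RSQ, 1)

  pred <- c(1, 2, 3, 5); meas <- c(1.5, 1.5, 3.5, 4)
  m3 <- evaluatePredictions(pred, meas, tolerance = 0.5)
  err <- pred - meas
  expect_equal(m3$MAE, mean(abs(err)))
  expect_equal(m3$RMSE, sqrt(mean(err^2)))
  expect_equal(m3$RSQ, summary(stats::lm(meas ~ pred))$r.squared)
  expect_equal(m3$fracWithin, mean(abs(err) <= 0.5))
  expect_error(evaluatePredictions(1:3, 1:4), "length")
})
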