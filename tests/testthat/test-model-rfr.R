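makeSignalData <- function(n = 150, p = 12, seed = 31) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p,
                            dimnames = list(NULL, paste0("d", seq_len(p)))))
  y <- 3 * X$d2 - 2.5 * X$d5 + rnorm(n, 0, 0.4)
  list(X = X, y = y)
}

test_that("importance vote finds planted signal descriptors", {
  dat <- makeSignalData()
  sel <- importanceVoteSelection(dat$X, dat$y,
                                 importanceVoteConfig(iterations = 100,
                                                      ntree = 200,
                                                      seed = 13))
  votes <- attr(sel, "votes")
  expect_true(all(c("d2", "d5") %in% sel))
  expect_gt(votes[["d2"]], 90)
  expect_gt(votes[["d5"]], 90)

  # vote threshold zero returns the union of all per-iteration top sets
  sel0 <- importanceVoteSelection(dat$X, dat$y,
                                  importanceVoteConfig(iterations = 10,
                                                       minVotes = 0,
                                                       ntree = 100,
                                                       seed = 13))
  v0 <- attr(sel0, "votes")
  expect_setequal(sel0, names(v0)[v0 > 0])

  # response independent of a wide descriptor pool: no reliable winner
  # (top-6 of 40 descriptors means ~9 expected votes out of 60 under
  # the null, far below the 30-vote threshold)
  set.seed(99)
  Xw <- as.data.frame(matrix(rnorm(120 * 40), 120, 40,
                             dimnames = list(NULL, paste0("d", 1:40))))
  ynull <- rnorm(120)
  got <- tryCatch(
    importanceVoteSelection(Xw, ynull,
                            importanceVoteConfig(iterations = 60,
                                                 minVotes = 30,
                                                 ntree = 100, seed = 4)),
    error = function(e) character(0))
  expect_lte(length(got), 2L)
})

test_that("grid optimization is argmin-consistent over the OOB table", {
  dat <- makeSignalData(n = 80, p = 5, seed = 8)
  g <- gridOptimizeRfr(dat$X, dat$y,
                       gridSearchConfig(ntreeGrid = c(100, 300, 500),
                                        seed = 21))
  tab <- g$rmseTable
  expect_equal(nrow(tab), 3 * ncol(dat$X))
  i <- which(tab$ntree == g$ntree & tab$mtry == g$mtry)
  expect_equal(tab$rmse[i], min(tab$rmse))
  # sanity envelope: OOB RMSE varies by less than 2x across the grid
  expect_lt(max(tab$rmse) / min(tab$rmse), 2)

  g1 <- gridOptimizeRfr(dat$X, dat$y,
                        gridSearchConfig(ntreeGrid = 200,
                                         mtryGrid = 2, seed = 21))
  expect_equal(g1$ntree, 200L); expect_equal(g1$mtry, 2L)
  expect_error(gridOptimizeRfr(dat$X, dat$y,
                               gridSearchConfig(ntreeGrid = 1:100,
                                                maxCells = 50)),
               "maxCells")
})

test_that("final forest is reproducible and respects averaging bounds", {
  dat <- makeSignalData(n = 100, p = 6, seed = 55)
  m <- fitFinalRfr(dat$X, dat$y, ntree = 300, mtry = 2, seed = 17)
  p1 <- predictResponse(m, dat$X)$fit
  expect_gt(summary(stats::lm(dat$y ~ p1))$r.squared, 0.8)
  expect_true(all(p1 >= min(dat$y) & p1 <= max(dat$y)))

  m2 <- fitFinalRfr(dat$X, dat$y, ntree = 300, mtry = 2, seed = 17)
  expect_identical(predictResponse(m2, dat$X)$fit, p1)

  # constant response: constant prediction, zero-width interval
  yc <- rep(2.5, nrow(dat$X))
  mc <- suppressWarnings(  # constant response is intentional here
    fitFinalRfr(dat$X, yc, ntree = 100, mtry = 2, seed = 1))
  pc <- predictResponse(mc, dat$X[1:3, ], interval = TRUE)
  expect_equal(pc$fit, rep(2.5, 3))
  expect_equal(pc$upr - pc$lwr, rep(0, 3))
  # interval contains the point estimate
  pi1 <- predictResponse(m, dat$X[1:5, ], interval = TRUE)
  expect_true(all(pi1$lwr <= pi1$fit & pi1$fit <= pi1$upr))
  expect_error(predictResponse(m, data.frame(d1 = 1)), "missing")
})

test_that("forests lose to linear models on the linear retention fixture", {
  fx <- trainedFixture()
  ts <- fx$ts
  set.seed(23)
  test <- sample(length(ts$structures), 30)
  train <- setdiff(seq_along(ts$structures), test)
  sel <- fx$rrtFit$selected
  Xtr <- ts$descriptors[train, sel, drop = FALSE]
  mlr <- fitMlrRepeatedCv(Xtr, ts$rrt[train],
                          cvConfig(folds = 5, repeats = 2, seed = 3))
  rfr <- fitFinalRfr(Xtr, ts$rrt[train], ntree = 500,
                     mtry = max(1L, length(sel) %/% 3), seed = 3)
  Xte <- ts$descriptors[test, sel, drop = FALSE]
  rmse <- function(p) sqrt(mean((p - ts$rrt[test])^2))
  expect_gte(rmse(predictResponse(rfr, Xte)$fit),
             rmse(predictResponse(mlr, Xte)$fit))
})

test_that("the loss-50 model learns the ortho fragmentation contrast", {
  fx <- trainedFixture()
  m50 <- fx$rrfModels[["50"]]
  expect_true("substOrtho" %in% m50@predictors)
  desc <- fx$ts$descriptors
  ortho <- fx$ts$groundTruth$orthoIndicator == 1
  p50 <- predictResponse(m50, desc)$fit
  expect_gt(mean(p50[ortho]), mean(p50[!ortho]))
})
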