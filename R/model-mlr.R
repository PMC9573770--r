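# Multiple linear regression training protocol: Cook's-distance outlier
# screen, log-transform of response factors, stepwise-AIC predictor
# selection, repeated 10-fold cross-validation, 95% prediction intervals.

#' Cross-validation configuration
#'
#' @param folds number of folds (default 10).
#' @param repeats number of independent repeats of the fold assignment
#'   (default 5), guarding against bias from any single random grouping.
#' @param seed integer seed controlling the fold assignment.
#' @return list with class \code{"cvConfig"}.
#' @export
cvConfig <- function(folds = 10L, repeats = 5L, seed = 1L) {
  folds <- as.integer(folds); repeats <- as.integer(repeats)
  if (folds < 2L) stop("'folds' must be at least 2")
  if (repeats < 1L) stop("'repeats' must be at least 1")
  structure(list(folds = folds, repeats = repeats, seed = as.integer(seed)),
            class = "cvConfig")
}

#' Cook's-distance outlier filter
#'
#' Fits a linear model of the response on the given predictors and removes
#' observations whose Cook's distance reaches \code{foldMultiplier} times
#' the mean Cook's distance (the keep condition is
#' \code{CD < foldMultiplier * mean(CD)}), the cutoff used to screen
#' influential standards out of the training sets.
#'
#' @param X data.frame of descriptors.
#' @param y numeric response.
#' @param foldMultiplier cutoff multiple of the mean Cook's distance
#'   (default 10).
#' @param predictors optional character vector restricting the screening
#'   fit (e.g. the stepwise-AIC selection); default all columns of
#'   \code{X}.
#' @return list with elements \code{retained}, \code{removed} (integer
#'   indices), \code{cooksDistances} and \code{cutoff}.
#' @export
cooksDistanceFilter <- function(X, y, foldMultiplier = 10,
                                predictors = NULL) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (!is.null(predictors)) X <- X[, predictors, drop = FALSE]
  if (nrow(X) <= ncol(X) + 1L)
    stop("too few observations for the screening fit; ",
         "pre-reduce the predictors (e.g. with stepwiseAicSelect)")
  fit <- stats::lm(y ~ ., data = cbind(X, y = y))
  if (anyNA(stats::coef(fit)))
    stop("singular screening design; pre-reduce the predictors")
  cd <- stats::cooks.distance(fit)
  cd[!is.finite(cd)] <- 0
  cutoff <- foldMultiplier * mean(cd)
  removed <- which(cd >= cutoff)
  list(retained = setdiff(seq_along(y), removed),
       removed = as.integer(removed),
       cooksDistances = unname(cd), cutoff = cutoff)
}

#' Log-transform response factors
#'
#' Relative response factors are modelled on the log10 scale, which
#' normalizes their strongly right-skewed distribution; all RRF model
#' errors in this package are therefore reported in log10 units.
#'
#' @param y positive numeric vector of RRFs.
#' @return log10 of \code{y}.
#' @export
logTransformRrf <- function(y) {
  bad <- which(!is.finite(y) | y <= 0)
  if (length(bad))
    stop("nonpositive response factor(s) at observation(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  log10(y)
}

#' Stepwise AIC predictor selection
#'
#' Bidirectional stepwise selection by the Akaike information criterion,
#' starting from the full cleaned descriptor set and stopping at a local
#' AIC minimum.  Aliased (perfectly collinear) columns are dropped from
#' the starting model first, so the search is well defined; when the
#' descriptor pool is not smaller than the observation count, it is first
#' screened to the \code{floor(n / 2)} descriptors most correlated with
#' the response so the starting fit has residual degrees of freedom.  The
#' result is deterministic for given inputs.
#'
#' @param X cleaned descriptor data.frame.
#' @param y numeric response.
#' @return character vector of selected descriptor names (possibly after
#'   removing none; at least the best single move set).
#' @export
stepwiseAicSelect <- function(X, y) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (nrow(X) <= 2L) stop("too few observations for selection")
  if (ncol(X) >= nrow(X) - 2L) {
    r <- abs(vapply(X, function(col)
      suppressWarnings(stats::cor(col, y)), numeric(1)))
    r[is.na(r)] <- 0
    keep <- names(sort(r, decreasing = TRUE))[seq_len(nrow(X) %/% 2L)]
    X <- X[, keep, drop = FALSE]
  }
  dat <- cbind(X, .y = y)
  full <- stats::lm(.y ~ ., data = dat)
  co <- stats::coef(full)
  aliased <- names(co)[is.na(co)]
  if (length(aliased)) {
    keep <- setdiff(colnames(X), aliased)
    dat <- cbind(X[, keep, drop = FALSE], .y = y)
    full <- stats::lm(.y ~ ., data = dat)
  }
  sel <- stats::step(full, direction = "both", trace = 0,
                     scope = list(lower = .y ~ 1))
  vars <- attr(stats::terms(sel), "term.labels")
  if (length(vars) == 0L) vars <- character(0)
  vars
}

#' Fit an MLR model with repeated k-fold cross-validation
#'
#' Observations are partitioned into \code{cv$folds} random groups; each
#' group serves once per repeat as the held-out test set, and the whole
#' grouping is redrawn \code{cv$repeats} times.  The reported coefficient
#' set is the one attained by the fold fit with the least held-out RMSE,
#' and the across-fold standard deviations of the coefficients are kept as
#' their deviations.  The fold fit with least RMSE also backs the
#' prediction-interval machinery.
#'
#' @param X descriptor data.frame restricted to the selected predictors.
#' @param y numeric response (RRT, or log10 RRF).
#' @param cv a \code{\link{cvConfig}}.
#' @param response label stored with the model (e.g. \code{"rrt"}).
#' @return an \code{\linkS4class{MLRModel}}; slot \code{cvMetrics} holds
#'   per-fold held-out RMSE and MAE.
#' @export
fitMlrRepeatedCv <- function(X, y, cv = cvConfig(), response = "response") {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (n != length(y)) stop("X and y sizes differ")
  if (n < cv$folds) stop("need at least as many observations as folds")
  set.seed(cv$seed)
  metrics <- NULL
  coefList <- list()
  best <- list(rmse = Inf, fit = NULL)
  for (r in seq_len(cv$repeats)) {
    foldId <- sample(rep_len(seq_len(cv$folds), n))
    for (k in seq_len(cv$folds)) {
      test <- which(foldId == k)
      if (length(test) == 0L) stop("empty test fold; reduce 'folds'")
      train <- setdiff(seq_len(n), test)
      dat <- cbind(X[train, , drop = FALSE], .y = y[train])
      fit <- stats::lm(.y ~ ., data = dat)
      pred <- stats::predict(fit, newdata = X[test, , drop = FALSE])
      err <- pred - y[test]
      rmse <- sqrt(mean(err^2)); mae <- mean(abs(err))
      metrics <- rbind(metrics,
                       data.frame(repeat_ = r, fold = k, rmse = rmse,
                                  mae = mae, nTest = length(test)))
      coefList[[length(coefList) + 1L]] <- stats::coef(fit)
    }
  }
  if (best$rmse == Inf) {
    # choose the fold fit with smallest held-out RMSE (refit it)
    i <- which.min(metrics$rmse)
    r <- metrics$repeat_[i]; k <- metrics$fold[i]
    set.seed(cv$seed)
    for (rr in seq_len(r)) foldId <- sample(rep_len(seq_len(cv$folds), n))
    train <- which(foldId != k)
    dat <- cbind(X[train, , drop = FALSE], .y = y[train])
    best$fit <- stats::lm(.y ~ ., data = dat)
  }
  cmat <- do.call(rbind, coefList)
  dev <- apply(cmat, 2, stats::sd)
  new("MLRModel", predictors = colnames(X),
      coefficients = stats::coef(best$fit), coefDev = dev,
      fit = best$fit, cvMetrics = metrics, response = response)
}

#' @describeIn predictResponse linear predictor with optional prediction
#'   interval from the linear-model predictive distribution.
#' @export
setMethod("predictResponse", "MLRModel",
          function(object, newdata, interval = FALSE, level = 0.95) {
  newdata <- .coerceNewdata(newdata, object@predictors)
  if (interval) {
    p <- stats::predict(object@fit, newdata = newdata,
                        interval = "prediction", level = level)
    data.frame(fit = p[, "fit"], lwr = p[, "lwr"], upr = p[, "upr"])
  } else {
    data.frame(fit = as.numeric(stats::predict(object@fit,
                                               newdata = newdata)))
  }
})

.coerceNewdata <- function(newdata, predictors) {
  if (is.numeric(newdata) && !is.null(names(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  newdata <- as.data.frame(newdata)
  missing <- setdiff(predictors, colnames(newdata))
  if (length(missing))
    stop("missing predictor(s): ", paste(missing, collapse = ", "))
  newdata[, predictors, drop = FALSE]
}

#' Prediction with interval for a single descriptor vector
#'
#' Convenience wrapper around \code{\link{predictResponse}} returning the
#' point estimate and the bounds of the prediction interval at the stated
#' confidence level.
#'
#' @param model a trained \code{\linkS4class{MLRModel}} or
#'   \code{\linkS4class{RFRModel}}.
#' @param x named numeric vector (or one-row data.frame) of descriptors.
#' @param confidence confidence level, default 0.95.
#' @return list with \code{point}, \code{lower}, \code{upper},
#'   \code{confidence}.
#' @export
predictWithInterval <- function(model, x, confidence = 0.95) {
  p <- predictResponse(model, x, interval = TRUE, level = confidence)
  list(point = p$fit[1], lower = p$lwr[1], upper = p$upr[1],
       confidence = confidence)
}

#' Prediction performance metrics
#'
#' \code{RSQ} is the squared correlation from the linear regression of
#' measured on predicted values; \code{MAE} and \code{RMSE} are the usual
#' absolute and quadratic means of the errors; \code{fracWithin} is the
#' fraction of observations whose absolute error is at most
#' \code{tolerance} (reported only when a tolerance is given).
#'
#' @param predicted,measured equal-length numeric vectors.
#' @param tolerance optional absolute-error tolerance.
#' @return list with \code{RSQ}, \code{MAE}, \code{RMSE} and optionally
#'   \code{fracWithin}.
#' @export
evaluatePredictions <- function(predicted, measured, tolerance = NULL) {
  if (length(predicted) != length(measured))
    stop("prediction and measurement vectors differ in length")
  if (length(predicted) < 2L) stop("need at least two observations")
  err <- predicted - measured
  rsq <- if (stats::sd(predicted) == 0 || stats::sd(measured) == 0) {
    if (all(err == err[1])) 1 else 0
  } else suppressWarnings(
    # an exact fit is a legitimate input here (noiseless references)
    summary(stats::lm(measured ~ predicted))$r.squared)
  out <- list(RSQ = rsq, MAE = mean(abs(err)), RMSE = sqrt(mean(err^2)))
  if (!is.null(tolerance))
    out$fracWithin <- mean(abs(err) <= tolerance)
  out
}

setMethod("show", "MLRModel", function(object) {
  cat("MLRModel for", object@response, "with",
      length(object@predictors), "predictors\n")
  cat("  CV RMSE (mean over folds):",
      signif(mean(object@cvMetrics$rmse), 4), "\n")
  invisible(object)
})
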