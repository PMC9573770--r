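# Random forest regression protocol: importance-vote descriptor
# selection, ntree/mtry grid optimization on out-of-bag error, final fit
# with per-tree predictions for interval estimation.

#' Importance-vote selection configuration
#'
#' @param iterations number of random train/test splits (default 100).
#' @param trainFraction fraction of observations used to fit each forest
#'   (default 2/3).
#' @param topK number of top-importance descriptors recorded per
#'   iteration (default 6).
#' @param minVotes strict vote threshold: descriptors appearing more than
#'   \code{minVotes} times are selected (default 50).
#' @param ntree trees per voting forest (default 500).
#' @param seed integer seed.
#' @export
importanceVoteConfig <- function(iterations = 100L, trainFraction = 2 / 3,
                                 topK = 6L, minVotes = 50L, ntree = 500L,
                                 seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("'trainFraction' must lie strictly between 0 and 1")
  if (minVotes > iterations) stop("'minVotes' cannot exceed 'iterations'")
  structure(list(iterations = as.integer(iterations),
                 trainFraction = trainFraction, topK = as.integer(topK),
                 minVotes = as.integer(minVotes), ntree = as.integer(ntree),
                 seed = as.integer(seed)),
            class = "importanceVoteConfig")
}

#' Grid-search configuration for ntree and mtry
#'
#' @param ntreeGrid candidate tree counts (default 100, 200, ..., 1000).
#' @param mtryGrid candidate numbers of descriptors sampled per split;
#'   default 1 up to the number of predictors (resolved at fit time).
#' @param maxCells guard against accidental huge grids.
#' @param seed integer seed.
#' @export
gridSearchConfig <- function(ntreeGrid = seq(100L, 1000L, by = 100L),
                             mtryGrid = NULL, maxCells = 500L, seed = 1L) {
  if (length(ntreeGrid) == 0L) stop("'ntreeGrid' must be non-empty")
  structure(list(ntreeGrid = as.integer(sort(ntreeGrid)),
                 mtryGrid = if (is.null(mtryGrid)) NULL
                            else as.integer(sort(mtryGrid)),
                 maxCells = as.integer(maxCells), seed = as.integer(seed)),
            class = "gridSearchConfig")
}

#' Importance-vote descriptor selection
#'
#' For each of \code{cfg$iterations} random splits, a forest is fitted on
#' the training part with all descriptors and the \code{cfg$topK}
#' descriptors by permutation importance (mean decrease in accuracy) are
#' recorded; descriptors voted for more than \code{cfg$minVotes} times are
#' selected.
#'
#' @param X descriptor data.frame.
#' @param y numeric response.
#' @param cfg an \code{\link{importanceVoteConfig}}.
#' @return character vector of selected descriptor names; attribute
#'   \code{votes} carries the full vote count table.
#' @export
importanceVoteSelection <- function(X, y, cfg = importanceVoteConfig()) {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 observations")
  if (n != length(y)) stop("X and y sizes differ")
  set.seed(cfg$seed)
  votes <- integer(ncol(X))
  names(votes) <- colnames(X)
  nTrain <- max(2L, round(cfg$trainFraction * n))
  for (i in seq_len(cfg$iterations)) {
    idx <- sample(n, nTrain)
    rf <- randomForest::randomForest(
      x = X[idx, , drop = FALSE], y = y[idx], ntree = cfg$ntree,
      importance = TRUE)
    imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
    top <- names(sort(imp, decreasing = TRUE))[seq_len(min(cfg$topK,
                                                           length(imp)))]
    votes[top] <- votes[top] + 1L
  }
  sel <- names(votes)[votes > cfg$minVotes]
  if (length(sel) == 0L)
    stop("no descriptor exceeded the vote threshold; lower 'minVotes'")
  structure(sel, votes = votes)
}

#' Grid optimization of ntree and mtry
#'
#' Evaluates every combination of the tree-count and split-sample grids by
#' out-of-bag RMSE (one forest per \code{mtry} at the maximal tree count
#' supplies the exact out-of-bag error at each smaller tree count) and
#' returns the argmin pair, ties broken towards the smaller \code{ntree}
#' then the smaller \code{mtry}.
#'
#' @param X descriptor data.frame restricted to the selected descriptors.
#' @param y numeric response.
#' @param cfg a \code{\link{gridSearchConfig}}.
#' @return list with \code{ntree}, \code{mtry} and \code{rmseTable}
#'   (data.frame ntree, mtry, rmse).
#' @export
gridOptimizeRfr <- function(X, y, cfg = gridSearchConfig()) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  mtryGrid <- cfg$mtryGrid %||% seq_len(ncol(X))
  if (any(mtryGrid > ncol(X)))
    stop("'mtryGrid' exceeds the number of predictors")
  nCells <- length(mtryGrid) * length(cfg$ntreeGrid)
  if (nCells > cfg$maxCells)
    stop("grid of ", nCells, " cells exceeds maxCells = ", cfg$maxCells)
  maxTree <- max(cfg$ntreeGrid)
  tab <- NULL
  for (m in mtryGrid) {
    set.seed(cfg$seed)
    rf <- randomForest::randomForest(x = X, y = y, ntree = maxTree,
                                     mtry = m)
    rmse <- sqrt(rf$mse[cfg$ntreeGrid])
    tab <- rbind(tab, data.frame(ntree = cfg$ntreeGrid, mtry = m,
                                 rmse = rmse))
  }
  tab <- tab[order(tab$ntree, tab$mtry), ]
  rownames(tab) <- NULL
  i <- which.min(tab$rmse)  # first minimum: smallest ntree, then mtry
  list(ntree = tab$ntree[i], mtry = tab$mtry[i], rmseTable = tab)
}

#' Fit the final random forest model
#'
#' @param X descriptor data.frame restricted to the selected descriptors.
#' @param y numeric response.
#' @param selected selected descriptor names (defaults to all columns).
#' @param ntree,mtry tuned parameters from \code{\link{gridOptimizeRfr}}.
#' @param seed integer seed; refitting with the same seed reproduces the
#'   ensemble and all predictions exactly.
#' @param response label stored with the model.
#' @param rmseTable optional grid table to retain in the model object.
#' @return an \code{\linkS4class{RFRModel}}.
#' @export
fitFinalRfr <- function(X, y, selected = colnames(X), ntree = 500L,
                        mtry = max(1L, floor(length(selected) / 3)),
                        seed = 1L, response = "response",
                        rmseTable = data.frame()) {
  X <- as.data.frame(X)[, selected, drop = FALSE]
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = as.integer(ntree),
                                   mtry = as.integer(mtry),
                                   keep.forest = TRUE)
  rf$trainX <- X  # training snapshot for the portable artifact dump
  rf$trainY <- y
  new("RFRModel", predictors = selected, ntree = as.integer(ntree),
      mtry = as.integer(mtry), forest = rf, rmseTable = rmseTable,
      seed = as.integer(seed), response = response)
}

#' @describeIn predictResponse ensemble-mean prediction; the optional
#'   interval spans the 2.5% and 97.5% quantiles of the per-tree
#'   predictions (at \code{level = 0.95}), clamped to contain the point
#'   estimate.
#' @export
setMethod("predictResponse", "RFRModel",
          function(object, newdata, interval = FALSE, level = 0.95) {
  newdata <- .coerceNewdata(newdata, object@predictors)
  if (!interval) {
    p <- stats::predict(object@forest, newdata = newdata)
    return(data.frame(fit = as.numeric(p)))
  }
  p <- stats::predict(object@forest, newdata = newdata,
                      predict.all = TRUE)
  fit <- as.numeric(p$aggregate)
  alpha <- (1 - level) / 2
  qs <- t(apply(p$individual, 1, stats::quantile,
                probs = c(alpha, 1 - alpha)))
  data.frame(fit = fit, lwr = pmin(qs[, 1], fit), upr = pmax(qs[, 2], fit))
})

setMethod("show", "RFRModel", function(object) {
  cat("RFRModel for", object@response, "with",
      length(object@predictors), "predictors (ntree =", object@ntree,
      ", mtry =", object@mtry, ")\n")
  invisible(object)
})
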