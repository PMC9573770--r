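# Model artifacts as structured text (JSON): predictor names,
# coefficients and deviations plus the training snapshot needed to
# reconstruct the backing fit exactly (linear models are refit on the
# stored design; forests are regrown from the stored seed, which
# reproduces the ensemble bit for bit).

#' Serialize a trained model to a structured text artifact
#'
#' @param model an \code{\linkS4class{MLRModel}} or
#'   \code{\linkS4class{RFRModel}}.
#' @param file output path (JSON).
#' @export
writeModelArtifact <- function(model, file) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("model artifacts require the 'jsonlite' package")
  if (is(model, "MLRModel")) {
    dat <- model@fit$model
    obj <- list(type = "MLR", response = model@response,
                registryVersion = .REGISTRY_VERSION,
                predictors = model@predictors,
                coefficients = as.list(model@coefficients),
                coefDev = as.list(model@coefDev),
                trainX = dat[, setdiff(colnames(dat), ".y"),
                             drop = FALSE],
                trainY = dat$.y,
                cvMetrics = model@cvMetrics)
  } else if (is(model, "RFRModel")) {
    obj <- list(type = "RFR", response = model@response,
                registryVersion = .REGISTRY_VERSION,
                predictors = model@predictors,
                ntree = model@ntree, mtry = model@mtry,
                seed = model@seed,
                trainX = as.data.frame(model@forest$trainX),
                trainY = model@forest$trainY,
                rmseTable = model@rmseTable)
  } else stop("unsupported model class")
  # I(17) significant digits: doubles survive the text round trip
  # exactly, so regrown forests split identically
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = I(17))
  invisible(file)
}

#' Load a model artifact
#'
#' @param file path written by \code{\link{writeModelArtifact}}.
#' @return the reconstructed model object.
#' @export
readModelArtifact <- function(file) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("model artifacts require the 'jsonlite' package")
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  X <- as.data.frame(obj$trainX)
  y <- as.numeric(obj$trainY)
  if (identical(obj$type, "MLR")) {
    fit <- stats::lm(.y ~ ., data = cbind(X, .y = y))
    new("MLRModel", predictors = obj$predictors,
        coefficients = unlist(obj$coefficients),
        coefDev = unlist(obj$coefDev), fit = fit,
        cvMetrics = as.data.frame(obj$cvMetrics),
        response = obj$response)
  } else if (identical(obj$type, "RFR")) {
    m <- fitFinalRfr(X, y, selected = obj$predictors,
                     ntree = obj$ntree, mtry = obj$mtry, seed = obj$seed,
                     response = obj$response,
                     rmseTable = as.data.frame(obj$rmseTable))
    m
  } else stop("unknown model artifact type in ", file)
}
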