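#' @export
setGeneric("bzNumber", function(x) standardGeneric("bzNumber"))

#' @export
setGeneric("canonicalName", function(x) standardGeneric("canonicalName"))

#' @export
setGeneric("toSmiles", function(x, asMethylEther = FALSE)
  standardGeneric("toSmiles"))

#' @export
setGeneric("chlorineCount", function(x) standardGeneric("chlorineCount"))

#' @export
setGeneric("chlorinePositions", function(x)
  standardGeneric("chlorinePositions"))

#' @export
setGeneric("substituentCount", function(x)
  standardGeneric("substituentCount"))

#' @export
setGeneric("substituentPositions", function(x)
  standardGeneric("substituentPositions"))

#' @export
setGeneric("substituentKinds", function(x)
  standardGeneric("substituentKinds"))

#' @export
setGeneric("positionClasses", function(x)
  standardGeneric("positionClasses"))

#' Predict a response from a trained model
#'
#' Unified prediction interface for \code{\linkS4class{MLRModel}} and
#' \code{\linkS4class{RFRModel}}.  Point predictions come from the linear
#' predictor or the ensemble mean; intervals from the linear-model
#' predictive distribution or from per-tree prediction quantiles.
#'
#' @param object a trained model.
#' @param newdata data.frame (or named vector) of descriptor values
#'   covering the model's selected predictors.
#' @param interval return lower/upper interval bounds as well.
#' @param level interval confidence level (default 0.95).
#' @return data.frame with column \code{fit}, plus \code{lwr}/\code{upr}
#'   when \code{interval} is \code{TRUE}.
#' @export
setGeneric("predictResponse",
  function(object, newdata, interval = FALSE, level = 0.95)
    standardGeneric("predictResponse"))
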