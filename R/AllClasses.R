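#' Substituted biphenyl structure
#'
#' The universal structure record of the package: a chlorination pattern on
#' the ten substitutable biphenyl ring positions plus zero, one or two
#' oxygen substituents (hydroxy or methoxy).  A plain PCB congener is the
#' special case with no substituent.  Objects are stored in a canonical
#' orientation under the biphenyl numbering symmetry (ring exchange and
#' 180-degree rotation of either ring), so two equivalent descriptions of
#' the same molecule compare identical slot by slot.
#'
#' @slot chlorines integer vector of slot codes (1-10) carrying chlorine.
#' @slot substPos integer vector of slot codes carrying the oxygen
#'   substituents (length 0, 1 or 2).
#' @slot substKind character vector parallel to \code{substPos}, each
#'   \code{"hydroxy"} or \code{"methoxy"}.
#'
#' @seealso \code{\link{biphenylStructure}}, \code{\link{canonicalName}},
#'   \code{\link{toSmiles}}
#' @export
setClass("BiphenylStructure",
  representation(chlorines = "integer", substPos = "integer",
                 substKind = "character"))

setValidity("BiphenylStructure", function(object) {
  msg <- character(0)
  cl <- object@chlorines; sp <- object@substPos; sk <- object@substKind
  if (length(cl) && (anyNA(cl) || any(cl < 1L | cl > 10L)))
    msg <- c(msg, "chlorine slots must lie in 1..10")
  if (length(sp) && (anyNA(sp) || any(sp < 1L | sp > 10L)))
    msg <- c(msg, "substituent slots must lie in 1..10")
  if (length(sp) > 2L)
    msg <- c(msg, "at most two oxygen substituents are supported")
  if (length(sp) != length(sk))
    msg <- c(msg, "substituent kinds must parallel substituent positions")
  if (length(sk) && !all(sk %in% c("hydroxy", "methoxy")))
    msg <- c(msg, "substituent kind must be 'hydroxy' or 'methoxy'")
  if (anyDuplicated(cl)) msg <- c(msg, "duplicated chlorine positions")
  if (anyDuplicated(sp)) msg <- c(msg, "duplicated substituent positions")
  if (length(intersect(cl, sp)))
    msg <- c(msg, "substituent positions must be free of chlorine")
  if (length(msg)) msg else TRUE
})

#' Construct a substituted biphenyl
#'
#' @param chlorines ring positions carrying chlorine, as labels drawn from
#'   \code{2,3,4,5,6,2',3',4',5',6'} (character) or slot codes 1-10
#'   (integer).
#' @param substituents named character vector mapping ring-position labels
#'   to substituent kinds (\code{"hydroxy"} or \code{"methoxy"}), e.g.
#'   \code{c("4'" = "hydroxy")}.  May be empty for a plain congener.
#'
#' @return a \code{\linkS4class{BiphenylStructure}} in canonical
#'   orientation.
#' @examples
#' # 4'-OH metabolite of PCB 95 (2,2',3,5',6-pentachlorobiphenyl)
#' s <- biphenylStructure(c("2", "2'", "3", "5'", "6"),
#'                        c("4'" = "hydroxy"))
#' canonicalName(s)
#' @export
biphenylStructure <- function(chlorines = character(0),
                              substituents = character(0)) {
  clSlots <- if (is.numeric(chlorines)) as.integer(chlorines)
             else .matchPositions(chlorines)
  if (length(substituents)) {
    if (is.null(names(substituents)))
      stop("'substituents' must be named by ring position")
    sSlots <- .matchPositions(names(substituents))
    sKind <- as.character(substituents)
  } else {
    sSlots <- integer(0); sKind <- character(0)
  }
  can <- .canonStructureSlots(clSlots, sSlots, sKind)
  if (is.null(can))
    can <- list(chlorines = sort(clSlots), substPos = sSlots,
                substKind = sKind)
  new("BiphenylStructure", chlorines = can$chlorines,
      substPos = can$substPos, substKind = can$substKind)
}

#' Candidate set of metabolite structures for one parent congener
#'
#' @slot parent the parent \code{\linkS4class{BiphenylStructure}} (a plain
#'   congener).
#' @slot members list of candidate structures.
#' @slot provenance character vector parallel to \code{members}; one of
#'   \code{"direct"}, \code{"shift_1_2"}, \code{"di_oh"}.
#' @export
setClass("CandidateSet",
  representation(parent = "BiphenylStructure", members = "list",
                 provenance = "character"))

setValidity("CandidateSet", function(object) {
  if (length(object@members) != length(object@provenance))
    return("provenance must parallel members")
  if (!all(vapply(object@members, is, logical(1), "BiphenylStructure")))
    return("members must be BiphenylStructure objects")
  keys <- vapply(object@members, function(s)
    .structureKey(s@chlorines, s@substPos, s@substKind), character(1))
  if (anyDuplicated(keys))
    return("members must be pairwise distinct after canonicalization")
  TRUE
})

#' Five-transition MS/MS profile
#'
#' Relative response factors of the five monitored neutral-loss MRM
#' transitions (losses 15, 30, 43, 50 and 66 Da) for one MeO-PCB.
#'
#' @slot rrf named nonnegative numeric vector with names
#'   \code{"15","30","43","50","66"}.
#' @slot normalized logical; \code{TRUE} when the entries sum to one.
#' @export
setClass("MSMSProfile",
  representation(rrf = "numeric", normalized = "logical"))

setValidity("MSMSProfile", function(object) {
  if (!identical(names(object@rrf), as.character(NEUTRAL_LOSSES)))
    return("profile must be named by the five neutral losses 15,30,43,50,66")
  if (anyNA(object@rrf) || any(object@rrf < 0))
    return("relative response factors must be nonnegative")
  if (all(object@rrf == 0))
    return("profile must have at least one positive entry")
  if (object@normalized && abs(sum(object@rrf) - 1) > 1e-8)
    return("normalized profile must sum to 1")
  TRUE
})

#' @param rrf numeric vector of five transition responses, in neutral-loss
#'   order 15, 30, 43, 50, 66 (names optional).
#' @param normalize scale the entries to sum to one.
#' @rdname MSMSProfile-class
#' @export
msmsProfile <- function(rrf, normalize = FALSE) {
  rrf <- as.numeric(rrf)
  if (length(rrf) != 5L)
    stop("an MS/MS profile has exactly five transition entries")
  names(rrf) <- as.character(NEUTRAL_LOSSES)
  if (normalize) {
    tot <- sum(rrf)
    if (tot <= 0) stop("cannot normalize an all-zero profile")
    rrf <- rrf / tot
  }
  new("MSMSProfile", rrf = rrf, normalized = isTRUE(normalize))
}

#' Multiple linear regression model with cross-validation summary
#'
#' Holds the predictor subset chosen by stepwise AIC, the coefficient set
#' attained at the least held-out RMSE across the repeated 10-fold
#' cross-validation, the across-fold coefficient deviations, and the fitted
#' \code{lm} object that backs prediction intervals.
#'
#' @slot predictors selected descriptor names.
#' @slot coefficients named coefficient vector (includes
#'   \code{"(Intercept)"}).
#' @slot coefDev across-fold standard deviations of the coefficients.
#' @slot fit the backing \code{lm} fit (training design snapshot included).
#' @slot cvMetrics data.frame of per-fold held-out RMSE and MAE.
#' @slot response name of the modelled response.
#' @export
setClass("MLRModel",
  representation(predictors = "character", coefficients = "numeric",
                 coefDev = "numeric", fit = "ANY", cvMetrics = "data.frame",
                 response = "character"))

#' Random forest regression model
#'
#' @slot predictors descriptor names retained by the importance vote.
#' @slot ntree,mtry tuned forest parameters (from the search grid).
#' @slot forest the backing \code{randomForest} ensemble.
#' @slot rmseTable out-of-bag RMSE over the full parameter grid.
#' @slot seed integer seed that makes the ensemble reproducible.
#' @slot response name of the modelled response.
#' @export
setClass("RFRModel",
  representation(predictors = "character", ntree = "integer",
                 mtry = "integer", forest = "ANY", rmseTable = "data.frame",
                 seed = "integer", response = "character"))
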