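# Quantification with predicted relative response factors.

#' Internal standard record
#'
#' @param name standard name.
#' @param retentionTime retention time in minutes.
#' @param response integrated area of the standard.
#' @param concentration concentration, in ng/mL (solutions) or ng/g
#'   (tissue); units pass through to the quantification report.
#' @param units unit string, default \code{"ng/mL"}.
#' @return list with class \code{"internalStandard"}.
#' @export
internalStandard <- function(name, retentionTime, response, concentration,
                             units = "ng/mL") {
  if (retentionTime <= 0) stop("retention time must be positive")
  if (response <= 0) stop("response must be positive")
  if (concentration <= 0) stop("concentration must be positive")
  structure(list(name = name, retentionTime = retentionTime,
                 response = response, concentration = concentration,
                 units = units),
            class = "internalStandard")
}

#' Relative retention time
#'
#' RRT of an analyte relative to one reference internal standard:
#' \code{rt / reference rt}.  Minute-scale errors are recovered exactly as
#' \code{|delta RRT| * reference rt}.
#'
#' @param rt analyte retention time in minutes.
#' @param reference an \code{\link{internalStandard}} record.
#' @return dimensionless RRT.
#' @export
computeRrt <- function(rt, reference) {
  if (any(rt <= 0)) stop("retention time must be positive")
  rt / reference$retentionTime
}

#' Relative response factor
#'
#' Standard internal-standard convention:
#' \code{(analyte response / IS response) / (analyte conc / IS conc)}.
#'
#' @param analyteResponse integrated area of the analyte transition.
#' @param analyteConc known analyte concentration.
#' @param isRecord an \code{\link{internalStandard}} record.
#' @return dimensionless RRF.
#' @export
computeRrf <- function(analyteResponse, analyteConc, isRecord) {
  if (any(analyteResponse <= 0) || any(analyteConc <= 0))
    stop("responses and concentrations must be positive")
  (analyteResponse / isRecord$response) /
    (analyteConc / isRecord$concentration)
}

#' Select the quantification transition for a structure
#'
#' Ortho-methoxylated PCBs are quantified on the loss-50 ([CH3 + Cl])
#' transition and meta/para-methoxylated PCBs on the loss-43
#' ([CH3 + CO]) transition; di-methoxy structures mixing one ortho and
#' one meta/para group are excluded from quantification.
#'
#' @param s a \code{\linkS4class{BiphenylStructure}} with at least one
#'   oxygen substituent.
#' @return \code{50}, \code{43}, or \code{NA} (excluded), with attribute
#'   \code{flag} one of \code{"ok"}/\code{"excluded"}.
#' @export
selectQuantTransition <- function(s) {
  stopifnot(is(s, "BiphenylStructure"))
  if (length(s@substPos) == 0L)
    stop("structure has no oxygen substituent")
  classes <- positionClasses(s)
  if (all(classes == "ortho"))
    return(structure(50L, flag = "ok"))
  if (all(classes %in% c("meta", "para")))
    return(structure(43L, flag = "ok"))
  structure(NA_integer_, flag = "excluded")
}

#' Quantify an identified peak
#'
#' Converts the integrated area of the selected quantification transition
#' into a concentration through the predicted relative response factor:
#' \code{conc = (area / IS response) / RRF * IS conc}, where the RRF of
#' the selected transition is the predicted total response factor scaled
#' by that transition's share of the predicted profile.
#'
#' @param peak one-row data.frame or named list with transition areas
#'   \code{area_loss15} .. \code{area_loss66} and a \code{peak_id}.
#' @param structure the identified \code{\linkS4class{BiphenylStructure}}.
#' @param predictedProfile normalized \code{\linkS4class{MSMSProfile}} of
#'   the structure.
#' @param predictedTotalRrf predicted summed response factor over the five
#'   transitions.
#' @param isRecord an \code{\link{internalStandard}} record.
#' @return data.frame row: peak_id, name, transition_used, rrf_used,
#'   concentration, units, flag.  Excluded structures (mixed ortho +
#'   meta/para di-methoxy) carry flag \code{"excluded"} and no
#'   concentration.
#' @export
quantifyPeak <- function(peak, structure, predictedProfile,
                         predictedTotalRrf, isRecord) {
  peak <- as.list(peak)
  loss <- selectQuantTransition(structure)
  base <- data.frame(peak_id = peak$peak_id %||% NA_character_,
                     name = canonicalName(structure),
                     stringsAsFactors = FALSE)
  if (is.na(loss)) {
    return(cbind(base, data.frame(transition_used = NA_integer_,
                                  rrf_used = NA_real_,
                                  concentration = NA_real_,
                                  units = isRecord$units,
                                  flag = "excluded")))
  }
  prof <- if (inherits(predictedProfile, "MSMSProfile"))
    predictedProfile@rrf else as.numeric(predictedProfile)
  share <- prof[as.character(loss)] / sum(prof)
  rrf <- predictedTotalRrf * share
  if (!is.finite(rrf) || rrf <= 0)
    stop("nonpositive predicted response factor for the selected ",
         "transition")
  area <- as.numeric(peak[[paste0("area_loss", loss)]])
  conc <- (area / isRecord$response) / rrf * isRecord$concentration
  cbind(base, data.frame(transition_used = as.integer(loss),
                         rrf_used = unname(rrf),
                         concentration = unname(conc),
                         units = isRecord$units, flag = "ok"))
}

#' Fold-difference accuracy statistics
#'
#' Per pair, the fold difference is \code{max(e/a, a/e)}; reported are the
#' fractions of pairs within 2-fold and 3-fold and the maximum fold
#' difference, the accuracy summary used for response-factor-based
#' quantification.
#'
#' @param estimated,actual positive numeric vectors of equal length.
#' @return list with \code{fractionWithin2x}, \code{fractionWithin3x},
#'   \code{maxFold}.
#' @export
foldDifferenceStats <- function(estimated, actual) {
  if (length(estimated) != length(actual))
    stop("vectors differ in length")
  if (any(estimated <= 0) || any(actual <= 0))
    stop("fold differences require positive values")
  fold <- pmax(estimated / actual, actual / estimated)
  list(fractionWithin2x = mean(fold <= 2),
       fractionWithin3x = mean(fold <= 3),
       maxFold = max(fold))
}
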