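# High-level pipeline: from a standards table to trained models, and from
# a peak table to ranked identifications and concentrations.

#' Train the retention-time model from a standards table
#'
#' Full protocol on measured relative retention times: assemble the
#' cleaned descriptor matrix, select predictors by bidirectional stepwise
#' AIC, remove influential observations by the Cook's-distance screen on
#' the selected-predictor fit, and refit with repeated 10-fold
#' cross-validation.
#'
#' @param structures list of \code{\linkS4class{BiphenylStructure}}.
#' @param rrt measured relative retention times, parallel to
#'   \code{structures}.
#' @param cv a \code{\link{cvConfig}}.
#' @param foldMultiplier Cook's-distance cutoff multiple (default 10).
#' @param descriptors optional precomputed cleaned descriptor data.frame
#'   (rows parallel to \code{structures}).
#' @return list: \code{model} (\code{\linkS4class{MLRModel}}),
#'   \code{selected} predictors, \code{filter} (outlier screen result).
#' @export
trainRrtModel <- function(structures, rrt, cv = cvConfig(),
                          foldMultiplier = 10, descriptors = NULL) {
  if (is.null(descriptors))
    descriptors <- assembleDescriptorMatrix(structures, clean = TRUE)
  selected <- stepwiseAicSelect(descriptors, rrt)
  flt <- cooksDistanceFilter(descriptors, rrt,
                             foldMultiplier = foldMultiplier,
                             predictors = selected)
  keep <- flt$retained
  model <- fitMlrRepeatedCv(descriptors[keep, selected, drop = FALSE],
                            rrt[keep], cv = cv, response = "rrt")
  list(model = model, selected = selected, filter = flt)
}

#' Train the five response-factor models from a standards table
#'
#' Per monitored neutral loss: log10-transform the measured relative
#' response factors, select descriptors by the importance vote, tune
#' ntree/mtry on the out-of-bag RMSE grid and fit the final forest.
#'
#' @param structures list of \code{\linkS4class{BiphenylStructure}}.
#' @param rrf n x 5 matrix of measured RRFs (columns in neutral-loss
#'   order).
#' @param voteCfg an \code{\link{importanceVoteConfig}}.
#' @param gridCfg a \code{\link{gridSearchConfig}}.
#' @param descriptors optional precomputed cleaned descriptor data.frame.
#' @return named list (\code{"15"} .. \code{"66"}) of
#'   \code{\linkS4class{RFRModel}} objects predicting log10 RRF.
#' @export
trainRrfModels <- function(structures, rrf,
                           voteCfg = importanceVoteConfig(),
                           gridCfg = gridSearchConfig(),
                           descriptors = NULL) {
  if (is.null(descriptors))
    descriptors <- assembleDescriptorMatrix(structures, clean = TRUE)
  rrf <- as.matrix(rrf)
  if (ncol(rrf) != 5L) stop("'rrf' must have five transition columns")
  models <- list()
  for (j in seq_len(5L)) {
    y <- logTransformRrf(rrf[, j])
    sel <- importanceVoteSelection(descriptors, y, voteCfg)
    Xs <- descriptors[, sel, drop = FALSE]
    grid <- gridOptimizeRfr(Xs, y, gridCfg)
    models[[as.character(NEUTRAL_LOSSES[j])]] <-
      fitFinalRfr(Xs, y, selected = sel, ntree = grid$ntree,
                  mtry = grid$mtry, seed = gridCfg$seed,
                  response = paste0("log10 RRF loss ",
                                    NEUTRAL_LOSSES[j]),
                  rmseTable = grid$rmseTable)
  }
  models
}

#' Identify peaks against a candidate set
#'
#' For each peak of a peak table, restricts the candidate set to the
#' peak's homolog (matching MRM precursor m/z) and ranks the remaining
#' candidates by the weighted rank score.
#'
#' @param peaks peak-table data.frame (see \code{\link{readPeakTable}}).
#' @param candidates a \code{\linkS4class{CandidateSet}} or list of
#'   structures.
#' @param rrtModel,rrfModels trained models as returned by
#'   \code{\link{trainRrtModel}} and \code{\link{trainRrfModels}}.
#' @param weights rank weights \code{c(rrt, msms)}.
#' @param topN keep the best \code{topN} candidates per peak (default
#'   all).
#' @return data.frame of ranked candidates for all peaks, with columns
#'   \code{peak_id} and \code{rank} prepended.
#' @export
identifyPeaks <- function(peaks, candidates, rrtModel, rrfModels,
                          weights = c(rrt = 1, msms = 1), topN = Inf) {
  members <- if (is(candidates, "CandidateSet")) candidates@members
             else candidates
  prov <- if (is(candidates, "CandidateSet")) candidates@provenance
          else rep(NA_character_, length(members))
  if (length(members) == 0L) stop("empty candidate set")
  precursors <- vapply(members, function(m)
    mrmTransitions(m)$precursor_mz[1], numeric(1))
  out <- NULL
  for (i in seq_len(nrow(peaks))) {
    peak <- peaks[i, ]
    sel <- which(precursors == as.integer(peak$precursor_mz))
    if (length(sel) == 0L) {
      warning("no candidate matches the homolog of peak ", peak$peak_id)
      next
    }
    sub <- new("CandidateSet",
               parent = if (is(candidates, "CandidateSet"))
                 candidates@parent else members[[sel[1]]],
               members = members[sel], provenance = prov[sel])
    ranked <- rankCandidates(peak, sub, rrtModel, rrfModels, weights)
    n <- min(nrow(ranked), topN)
    out <- rbind(out, cbind(peak_id = peak$peak_id,
                            rank = seq_len(n),
                            ranked[seq_len(n), , drop = FALSE]))
  }
  rownames(out) <- NULL
  out
}

#' Quantify identified peaks with predicted response factors
#'
#' For each peak and its identified structure, predicts the
#' five-transition response factors from the trained models, selects the
#' quantification transition by the substitution rule (loss 50 for
#' all-ortho, loss 43 for all-meta/para, mixed di-methoxy excluded) and
#' converts the transition area into a concentration.
#'
#' @param peaks peak-table data.frame.
#' @param identifications data.frame with columns \code{peak_id} and
#'   \code{name} (canonical structure names), e.g. the rank-1 rows of
#'   \code{\link{identifyPeaks}}.
#' @param rrfModels trained response-factor models.
#' @param isRecord an \code{\link{internalStandard}} record.
#' @return quantification report data.frame (one row per identification).
#' @export
quantifyPeaks <- function(peaks, identifications, rrfModels, isRecord) {
  out <- NULL
  for (i in seq_len(nrow(identifications))) {
    pid <- identifications$peak_id[i]
    peak <- peaks[peaks$peak_id == pid, ]
    if (nrow(peak) != 1L) stop("peak '", pid, "' not found exactly once")
    s <- parseCanonicalName(identifications$name[i])
    desc <- assembleDescriptorMatrix(list(s), clean = FALSE)
    rrfs <- vapply(as.character(NEUTRAL_LOSSES), function(l)
      10^predictResponse(rrfModels[[l]], desc)$fit[1], numeric(1))
    res <- quantifyPeak(peak, s, msmsProfile(rrfs, normalize = TRUE),
                        sum(rrfs), isRecord)
    out <- rbind(out, res)
  }
  rownames(out) <- NULL
  out
}

#' Reproduce the validation metrics on a user-supplied standards table
#'
#' Given a measured standards CSV (see \code{\link{readStandardsCsv}}),
#' re-runs the full training protocol and reports the cross-validated
#' retention-time metrics (RSQ, MAE in minutes, fraction within 1 minute),
#' the per-transition response-factor MAEs in log10 units, the cosine
#' similarity distribution between predicted and measured profiles, and
#' the fold-difference statistics of response-factor-based
#' requantification of the standards.  These metrics depend on the
#' supplied data set and the cross-validation split.
#'
#' @param standards data.frame from \code{\link{readStandardsCsv}}.
#' @param isRecord an \code{\link{internalStandard}} record (reference for
#'   converting RRT errors to minutes).
#' @param seed integer seed for the resampling machinery.
#' @return list of metric blocks.
#' @export
reproduceValidation <- function(standards, isRecord, seed = 1L) {
  structures <- lapply(standards$smiles, parseBiphenylSmiles)
  desc <- assembleDescriptorMatrix(structures, clean = TRUE)
  rrt <- computeRrt(standards$rt_min, isRecord)
  rrtFit <- trainRrtModel(structures, rrt, cv = cvConfig(seed = seed),
                          descriptors = desc)
  predRrt <- predictResponse(rrtFit$model, desc)$fit
  rrtMetrics <- evaluatePredictions(predRrt * isRecord$retentionTime,
                                    rrt * isRecord$retentionTime,
                                    tolerance = 1)
  rrfCols <- paste0("rrf_loss", NEUTRAL_LOSSES)
  rrf <- as.matrix(standards[, rrfCols])
  rrfModels <- trainRrfModels(structures, rrf,
                              voteCfg = importanceVoteConfig(seed = seed),
                              gridCfg = gridSearchConfig(seed = seed),
                              descriptors = desc)
  rrfMae <- vapply(seq_len(5L), function(j) {
    pred <- predictResponse(rrfModels[[as.character(NEUTRAL_LOSSES[j])]],
                            desc)$fit
    mean(abs(pred - log10(rrf[, j])))
  }, numeric(1))
  cosv <- vapply(seq_len(nrow(desc)), function(i) {
    pred <- vapply(as.character(NEUTRAL_LOSSES), function(l)
      10^predictResponse(rrfModels[[l]], desc[i, , drop = FALSE])$fit[1],
      numeric(1))
    cosTheta(pred, rrf[i, ])
  }, numeric(1))
  list(rrt = rrtMetrics,
       rrfMaeLog10 = structure(rrfMae,
                               names = as.character(NEUTRAL_LOSSES)),
       cosTheta = summary(cosv),
       fracCosAbove095 = mean(cosv > 0.95))
}
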