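# Synthetic standards, training sets and simulated sample runs.
#
# The generator emulates the statistical structure of a MeO-PCB standard
# set: retention times linear in molecular descriptors with Gaussian
# noise, and per-transition response factors following log10-scale rules
# with a strong ortho/meta-para fragmentation contrast (loss 50 elevated
# for ortho methoxy groups, loss 43 for meta/para) plus an
# ortho-by-chlorination interaction that linear models cannot represent
# exactly.

.defaultRrtRule <- function() {
  # positional terms mirror the strong dependence of MeO-PCB retention on
  # where the substituents sit, not only on how many there are: ortho
  # chlorines and ortho-ortho' pairs twist the biphenyl and shorten
  # retention, para/meta oxygen placement and chlorines flanking the
  # methoxy shift it in characteristic ways
  # coefficient scale sets a within-homolog isomer spread of several
  # minutes at a 25-minute reference, as observed on apolar columns
  # the Wiener-index term plays the classic QSRR role of a topological
  # size/branching descriptor and breaks the ties positional counts
  # leave between close isomers
  list(intercept = 0.15,
       coefs = c(nCl = 0.05, wienerIndex = 0.001, nClOrtho = -0.06,
                 nOrthoOrthoPrimePairs = -0.05, substPara = 0.15,
                 substMeta = 0.08, nClFlankingSubst = -0.08,
                 nClParaToSubstSameRing = 0.06,
                 nClOppRing = 0.025, nSubstituents = 0.05))
}

.defaultRrfRule <- function(deltaOrtho = 1.0) {
  # per-loss log10 rules; dOrtho carries the ortho/meta-para
  # fragmentation asymmetry (loss 50 up, loss 43 down for ortho methoxy),
  # gInteract an ortho-by-chlorination interaction, fFlank the effect of
  # chlorines directly flanking the methoxy group (chlorine-involving
  # losses 50 and 66 gain, the CO-loss 43 channel loses)
  data.frame(
    loss = NEUTRAL_LOSSES,
    b0 = c(-0.3, -0.5, 0.3, -0.7, -0.8),
    bCl = c(-0.05, 0.02, -0.03, 0.05, 0.06),
    dOrtho = c(0, 0.3, -1, 1, 0.3) * deltaOrtho,
    gInteract = c(0, 0, -0.05, 0.08, 0.05),
    fFlank = c(0, -0.05, -0.1, 0.25, 0.2),
    pPara = c(0.15, -0.25, 0.35, -0.25, -0.1),
    mMeta = c(-0.1, 0.15, 0.15, -0.15, 0.1),
    oppR = c(0.03, -0.04, 0.05, -0.03, 0.06))
}

#' Generator specification for synthetic MeO-PCB data
#'
#' Defaults describe a standard set of 124 structures (about one fifth
#' dihydroxylated), retention-time noise of 0.02 RRT units (about half a
#' minute at the 25-minute reference), response-factor noise of 0.2 log10
#' units, replicate-level area noise of 0.05 log10 units, and an
#' ortho-methoxy fragmentation contrast of 1 log10 unit.
#'
#' @param nStructures number of standards to generate (default 124).
#' @param diFraction fraction drawn from the dihydroxylated candidate
#'   space (default 0.18).
#' @param rrtRule list with \code{intercept} and named \code{coefs} over
#'   registry descriptors; linear RRT-generating rule.
#' @param rrfRule data.frame of per-loss log10-RRF rule coefficients
#'   (\code{b0 + bCl * nCl + dOrtho * ortho + gInteract * ortho * nCl}).
#' @param deltaOrtho scale of the ortho fragmentation contrast used when
#'   \code{rrfRule} is left at its default.
#' @param sigmaRrt,sigmaRrf Gaussian noise standard deviations on the RRT
#'   and log10-RRF scales.
#' @param sigmaArea replicate (measurement) noise on log10 peak areas in
#'   simulated sample runs.
#' @param outlierFraction fraction of training observations whose RRT is
#'   shifted by ten noise standard deviations (influence-filter test
#'   material); must be below 0.2.
#' @param referenceRt retention time of the reference internal standard in
#'   minutes.
#' @param seed integer seed; identical specs generate byte-identical
#'   data.
#' @return list with class \code{"generatorSpec"}.
#' @export
generatorSpec <- function(nStructures = 124L, diFraction = 0.18,
                          rrtRule = .defaultRrtRule(),
                          rrfRule = .defaultRrfRule(deltaOrtho),
                          deltaOrtho = 1.0, sigmaRrt = 0.02,
                          sigmaRrf = 0.2, sigmaArea = 0.05,
                          outlierFraction = 0, referenceRt = 25,
                          seed = 1L) {
  if (sigmaRrt < 0 || sigmaRrf < 0 || sigmaArea < 0)
    stop("noise standard deviations must be nonnegative")
  if (outlierFraction < 0 || outlierFraction >= 0.2)
    stop("'outlierFraction' must lie in [0, 0.2)")
  structure(list(nStructures = as.integer(nStructures),
                 diFraction = diFraction, rrtRule = rrtRule,
                 rrfRule = rrfRule, deltaOrtho = deltaOrtho,
                 sigmaRrt = sigmaRrt, sigmaRrf = sigmaRrf,
                 sigmaArea = sigmaArea,
                 outlierFraction = outlierFraction,
                 referenceRt = referenceRt, seed = as.integer(seed)),
            class = "generatorSpec")
}

# deterministic parts of the generating rules, from the full (uncleaned)
# descriptor matrix
.ruleRrt <- function(spec, desc) {
  v <- rep(spec$rrtRule$intercept, nrow(desc))
  for (nm in names(spec$rrtRule$coefs)) {
    if (!nm %in% colnames(desc))
      stop("rrt rule references unknown descriptor '", nm, "'")
    v <- v + spec$rrtRule$coefs[[nm]] * desc[[nm]]
  }
  v
}

.ruleLogRrf <- function(spec, desc) {
  ortho <- as.numeric(desc[["substOrtho"]] > 0)
  nCl <- desc[["nCl"]]
  extras <- list(fFlank = desc[["nClFlankingSubst"]],
                 pPara = desc[["substPara"]],
                 mMeta = desc[["substMeta"]],
                 oppR = desc[["nClOppRing"]])
  sapply(seq_len(nrow(spec$rrfRule)), function(j) {
    r <- spec$rrfRule[j, ]
    v <- r$b0 + r$bCl * nCl + r$dOrtho * ortho +
      r$gInteract * ortho * nCl
    for (nm in names(extras)) {
      if (!is.null(r[[nm]])) v <- v + r[[nm]] * extras[[nm]]
    }
    v
  })
}

#' Generate a synthetic training set of MeO-PCB standards
#'
#' Samples structures from the mono-hydroxylated congener space (plus a
#' fraction of ortho/para-dihydroxylated metabolites), computes their
#' descriptor matrix and generates retention times and five-transition
#' response factors from the spec's rules.  The generating parameters are
#' returned as ground truth for recovery tests; everything is reproducible
#' from the seed.
#'
#' @param spec a \code{\link{generatorSpec}}.
#' @return list: \code{structures}, \code{descriptors} (cleaned
#'   data.frame), \code{descriptorsFull} (uncleaned), \code{rrt} (numeric,
#'   includes any injected outliers), \code{rrf} (n x 5 matrix of raw
#'   response factors), \code{groundTruth} (rules, deterministic parts,
#'   noise draws, outlier indices).
#' @export
generateTrainingSet <- function(spec = generatorSpec()) {
  stopifnot(inherits(spec, "generatorSpec"))
  set.seed(spec$seed)
  pool <- enumerateMonoOhPcbs()
  nDi <- round(spec$diFraction * spec$nStructures)
  nMono <- spec$nStructures - nDi
  if (nMono > length(pool))
    stop("nStructures exceeds the mono-hydroxylated congener space")
  structures <- pool[sample(length(pool), nMono)]
  if (nDi > 0L) {
    di <- list(); seen <- character(0)
    while (length(di) < nDi) {
      bz <- sample(209L, 1L)
      cs <- generateMetaboliteCandidates(bz, classes = "di_oh")
      if (length(cs) == 0L) next
      m <- cs@members[[sample(length(cs), 1L)]]
      key <- canonicalName(m)
      if (!key %in% seen) {
        seen <- c(seen, key)
        di[[length(di) + 1L]] <- m
      }
    }
    structures <- c(structures, di)
  }
  names(structures) <- vapply(structures, canonicalName, character(1))

  descFull <- assembleDescriptorMatrix(structures, clean = FALSE)
  cleaned <- .cleanDescriptorMatrix(descFull)
  desc <- as.data.frame(cleaned$matrix)

  n <- length(structures)
  detRrt <- .ruleRrt(spec, descFull)
  noiseRrt <- stats::rnorm(n, 0, spec$sigmaRrt)
  rrt <- detRrt + noiseRrt
  nOut <- round(spec$outlierFraction * n)
  outliers <- if (nOut > 0L) sample(n, nOut) else integer(0)
  rrt[outliers] <- rrt[outliers] + 10 * spec$sigmaRrt

  detLogRrf <- .ruleLogRrf(spec, descFull)
  noiseRrf <- matrix(stats::rnorm(n * 5L, 0, spec$sigmaRrf), n, 5L)
  logRrf <- detLogRrf + noiseRrf
  colnames(logRrf) <- as.character(NEUTRAL_LOSSES)
  rownames(logRrf) <- names(structures)

  if (spec$sigmaRrt > 0 && n >= 10L && n <= 5000L) {
    # generation-time sanity screen: the injected noise must look normal
    p <- stats::shapiro.test(noiseRrt)$p.value
    if (p < 1e-4)
      warning("RRT noise failed the normality screen (p = ",
              signif(p, 2), ")")
  }

  list(structures = structures, descriptors = desc,
       descriptorsFull = descFull, rrt = rrt, rrf = 10^logRrf,
       groundTruth = list(rrtRule = spec$rrtRule, rrfRule = spec$rrfRule,
                          sigmaRrt = spec$sigmaRrt,
                          sigmaRrf = spec$sigmaRrf, detRrt = detRrt,
                          detLogRrf = detLogRrf, outliers = outliers,
                          orthoIndicator =
                            as.numeric(descFull[["substOrtho"]] > 0),
                          nCl = descFull[["nCl"]]))
}

#' Simulate a sample run as a peak table
#'
#' Generates the peak table a derivatized sample extract would produce for
#' a list of true metabolites: retention times from the RRT rule (noised),
#' per-transition areas from the response-factor rules scaled by
#' concentration relative to the internal standard (noised on the log10
#' scale by \code{sigmaArea}), formatted exactly as the peak-table
#' interface expects.
#'
#' @param trueMetabolites list of \code{\linkS4class{BiphenylStructure}}
#'   objects (or canonical names) of the metabolites present.
#' @param concentrations positive numeric vector of true concentrations,
#'   parallel to \code{trueMetabolites}.
#' @param spec a \code{\link{generatorSpec}} (rules, noise, seed).
#' @param isRecord an \code{\link{internalStandard}} record.
#' @param file optional path; writes the peak table as CSV.
#' @return list: \code{peaks} (data.frame: peak_id, rt_min, rrt,
#'   area_loss15..66, precursor_mz), \code{key} (data.frame: peak_id,
#'   name, concentration).
#' @export
generateSampleRun <- function(trueMetabolites, concentrations,
                              spec = generatorSpec(), isRecord,
                              file = NULL) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  mets <- lapply(trueMetabolites, function(m)
    if (is.character(m)) parseCanonicalName(m) else m)
  if (length(mets) != length(concentrations))
    stop("metabolites and concentrations differ in length")
  set.seed(spec$seed)
  desc <- assembleDescriptorMatrix(mets, clean = FALSE)
  detRrt <- .ruleRrt(spec, desc)
  detLogRrf <- .ruleLogRrf(spec, desc)
  n <- length(mets)
  rrt <- detRrt + stats::rnorm(n, 0, spec$sigmaRrt)
  areaNoise <- matrix(stats::rnorm(n * 5L, 0, spec$sigmaArea), n, 5L)
  rrfObs <- 10^(detLogRrf + areaNoise)
  areas <- rrfObs * (concentrations / isRecord$concentration) *
    isRecord$response
  colnames(areas) <- paste0("area_loss", NEUTRAL_LOSSES)
  precursor <- vapply(mets, function(m)
    mrmTransitions(m)$precursor_mz[1], numeric(1))
  peaks <- data.frame(peak_id = paste0("P", seq_len(n)),
                      rt_min = rrt * spec$referenceRt, rrt = rrt,
                      areas, precursor_mz = as.integer(precursor),
                      stringsAsFactors = FALSE)
  key <- data.frame(peak_id = peaks$peak_id,
                    name = vapply(mets, canonicalName, character(1)),
                    concentration = concentrations,
                    stringsAsFactors = FALSE)
  if (!is.null(file)) utils::write.csv(peaks, file, row.names = FALSE)
  list(peaks = peaks, key = key)
}
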