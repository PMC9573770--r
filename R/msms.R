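# MRM transitions, MS/MS profiles, cosine similarity, candidate ranking.

#' The five monitored neutral losses
#'
#' Nominal neutral-loss masses of the five MRM transitions monitored for
#' methylated OH-PCBs, with the fragment identities: 15 = [CH3],
#' 30 = [CH2O], 43 = [CH3 + CO], 50 = [CH3 + Cl], 66 = [CH3O + Cl].
#'
#' @export
NEUTRAL_LOSSES <- c(15L, 30L, 43L, 50L, 66L)

#' @rdname NEUTRAL_LOSSES
#' @export
NEUTRAL_LOSS_IDENTITIES <- c(`15` = "[CH3]", `30` = "[CH2O]",
                             `43` = "[CH3+CO]", `50` = "[CH3+Cl]",
                             `66` = "[CH3O+Cl]")

.CL35 <- 0.7576  # natural abundance of 35Cl; 37Cl = 0.2424

# Nominal (integer) molecular mass of the all-35Cl isotopologue of the
# methylated derivative: formula C(12+k) H(10-n+2k) Cl(n) O(k) for k
# methoxy groups and n chlorines.
.nominalBaseMass <- function(nCl, nMeO) {
  12L * (12L + nMeO) + (10L - nCl + 2L * nMeO) + 35L * nCl + 16L * nMeO
}

# number of 37Cl atoms in the most abundant isotopologue (ties -> fewer,
# i.e. the lower m/z)
.mostAbundant37 <- function(nCl) {
  p <- stats::dbinom(0:nCl, nCl, 1 - .CL35)
  which(p == max(p))[1] - 1L
}

#' MRM transitions of a methylated OH-PCB
#'
#' The precursor is the nominal m/z of the most abundant chlorine
#' isotopologue of the molecular ion of the methyl-ether derivative
#' (chlorine isotope cluster from the binomial 35Cl/37Cl natural
#' abundances 0.7576/0.2424; ties resolved to the lower m/z); the five
#' products are the precursor minus the neutral losses 15, 30, 43, 50 and
#' 66.  For pentachlorinated mono-methoxy structures this gives the
#' monitored 356 -> 313 (loss 43) transition; 286 -> 243 for
#' trichlorinated mono-methoxy and 386 -> 343 for pentachlorinated
#' di-methoxy structures.
#'
#' @param s a \code{\linkS4class{BiphenylStructure}} with at least one
#'   oxygen substituent (treated as methoxy).
#' @return data.frame with columns \code{neutral_loss}, \code{loss_identity},
#'   \code{precursor_mz}, \code{product_mz}.
#' @examples
#' s <- parseCanonicalName("4'-95")
#' mrmTransitions(s)  # precursor 356, loss-43 product 313
#' @export
mrmTransitions <- function(s) {
  stopifnot(is(s, "BiphenylStructure"))
  k <- length(s@substPos)
  if (k == 0L)
    stop("structure has no oxygen substituent: not a MeO-PCB")
  n <- length(s@chlorines)
  precursor <- .nominalBaseMass(n, k) + 2L * .mostAbundant37(n)
  data.frame(neutral_loss = NEUTRAL_LOSSES,
             loss_identity = unname(NEUTRAL_LOSS_IDENTITIES),
             precursor_mz = precursor,
             product_mz = precursor - NEUTRAL_LOSSES)
}

#' Normalize a raw transition-intensity map into an MS/MS profile
#'
#' @param raw numeric vector of five intensities in neutral-loss order
#'   (15, 30, 43, 50, 66); at least one must be positive.
#' @return a normalized \code{\linkS4class{MSMSProfile}} (entries sum to
#'   one).
#' @export
normalizeProfile <- function(raw) {
  if (inherits(raw, "MSMSProfile")) raw <- raw@rrf
  msmsProfile(raw, normalize = TRUE)
}

#' Cosine similarity between two MS/MS profiles
#'
#' Inner product of the two five-transition vectors divided by the product
#' of their Euclidean norms: 1 for profiles of identical shape, 0 for
#' profiles with disjoint transitions.  Scale invariant, so normalized and
#' raw profiles compare identically.
#'
#' @param a,b \code{\linkS4class{MSMSProfile}} objects or numeric
#'   5-vectors in neutral-loss order.
#' @return cosine similarity in [0, 1].
#' @examples
#' cosTheta(c(1, 0, 1, 0, 0), c(1, 1, 0, 0, 0))  # 0.5
#' @export
cosTheta <- function(a, b) {
  va <- if (inherits(a, "MSMSProfile")) a@rrf else as.numeric(a)
  vb <- if (inherits(b, "MSMSProfile")) b@rrf else as.numeric(b)
  if (length(va) != 5L || length(vb) != 5L)
    stop("profiles must have five transition entries")
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("zero-norm profile")
  v <- min(1, max(0, sum(va * vb) / (na * nb)))
  # snap floating-point dust so the identity and orthogonality limits
  # are exact
  if (abs(v - 1) < 1e-12) v <- 1
  if (v < 1e-15) v <- 0
  v
}

#' Classify the methoxy position class from an MS/MS profile
#'
#' Ortho-methoxylated PCBs fragment preferentially with the loss of 50
#' ([CH3 + Cl]) while meta/para-methoxylated PCBs favour the loss of 43
#' ([CH3 + CO]); the classifier compares the two transitions and returns
#' \code{"ortho"} when loss 50 dominates, otherwise \code{"meta_para"}.
#' An exact tie is resolved to \code{"meta_para"} with a warning.
#'
#' @param profile an \code{\linkS4class{MSMSProfile}} or numeric 5-vector.
#' @return \code{"ortho"} or \code{"meta_para"}.
#' @export
classifyMethoxyPosition <- function(profile) {
  v <- if (inherits(profile, "MSMSProfile")) profile@rrf
       else as.numeric(profile)
  if (length(v) != 5L) stop("profile must have five transition entries")
  r50 <- v[4]; r43 <- v[3]
  if (r50 == r43) {
    warning("loss-50 and loss-43 responses tie; classifying as meta_para")
    return("meta_para")
  }
  if (r50 > r43) "ortho" else "meta_para"
}

# predicted five-transition profile of one structure from the per-loss
# response-factor models (models predict log10 RRF)
.predictProfile <- function(structure, rrfModels, descriptors = NULL) {
  if (is.null(descriptors)) {
    descriptors <- assembleDescriptorMatrix(list(structure), clean = FALSE)
  }
  rrf <- vapply(as.character(NEUTRAL_LOSSES), function(l)
    10^predictResponse(rrfModels[[l]], descriptors)$fit[1], numeric(1))
  msmsProfile(rrf, normalize = TRUE)
}

#' Rank candidate structures for an unknown peak
#'
#' For every candidate, the relative retention time and the
#' five-transition MS/MS profile are predicted from the trained models;
#' candidates are ranked by ascending absolute RRT deviation from the
#' measured peak and by descending cosine similarity between measured and
#' predicted profiles, and the two ranks are combined into the weighted
#' rank score \code{wRrt * rankRrt + wMsms * rankMsms}.  Lower scores are
#' better; ties are broken by higher cosine similarity, then by smaller
#' RRT deviation.
#'
#' @param peak a one-row data.frame or named list with at least
#'   \code{rrt} and the five measured areas \code{area_loss15} ..
#'   \code{area_loss66}; optional \code{precursor_mz} is checked against
#'   the candidates' homolog transition.
#' @param candidates a \code{\linkS4class{CandidateSet}} or list of
#'   structures; all members must share the peak's homolog (chlorine and
#'   substituent count).
#' @param rrtModel trained model for RRT.
#' @param rrfModels named list of trained models (names \code{"15"},
#'   \code{"30"}, \code{"43"}, \code{"50"}, \code{"66"}) for log10 RRF.
#' @param weights numeric \code{c(rrt, msms)} rank weights, default
#'   \code{c(1, 1)}.
#' @return data.frame sorted by weighted score: name, provenance,
#'   predicted RRT, RRT deviation, cosine similarity, per-criterion ranks
#'   and weighted score.
#' @export
rankCandidates <- function(peak, candidates, rrtModel, rrfModels,
                           weights = c(rrt = 1, msms = 1)) {
  if (is(candidates, "CandidateSet")) {
    members <- candidates@members
    prov <- candidates@provenance
  } else {
    members <- candidates
    prov <- rep(NA_character_, length(members))
  }
  if (length(members) == 0L) stop("empty candidate set")
  peak <- as.list(peak)
  if (is.null(peak$rrt)) stop("peak must provide 'rrt'")

  nCl <- vapply(members, chlorineCount, integer(1))
  nSub <- vapply(members, substituentCount, integer(1))
  if (length(unique(nCl)) > 1L || length(unique(nSub)) > 1L)
    stop("candidates span more than one homolog")
  if (!is.null(peak$precursor_mz)) {
    expected <- mrmTransitions(members[[1]])$precursor_mz[1]
    if (as.integer(peak$precursor_mz) != expected)
      stop("peak precursor m/z ", peak$precursor_mz,
           " does not match the candidate homolog (expected ", expected,
           ")")
  }

  areas <- vapply(as.character(NEUTRAL_LOSSES), function(l)
    as.numeric(peak[[paste0("area_loss", l)]] %||% 0), numeric(1))
  if (all(areas == 0)) stop("peak has no positive transition area")
  measured <- msmsProfile(areas, normalize = TRUE)

  desc <- assembleDescriptorMatrix(members, clean = FALSE)
  predRrt <- predictResponse(rrtModel, desc)$fit
  cosv <- numeric(length(members))
  profiles <- vector("list", length(members))
  for (i in seq_along(members)) {
    profiles[[i]] <- .predictProfile(members[[i]], rrfModels,
                                     desc[i, , drop = FALSE])
    cosv[i] <- cosTheta(measured, profiles[[i]])
  }
  dev <- abs(predRrt - peak$rrt)
  rankRrt <- rank(dev, ties.method = "min")
  rankMsms <- rank(1 - cosv, ties.method = "min")
  score <- weights[1] * rankRrt + weights[2] * rankMsms
  ord <- order(score, -cosv, dev)
  out <- data.frame(
    name = vapply(members, canonicalName, character(1)),
    provenance = prov,
    predicted_rrt = predRrt,
    rrt_deviation = dev,
    cos_theta = cosv,
    rank_rrt = as.integer(rankRrt),
    rank_msms = as.integer(rankMsms),
    weighted_score = as.numeric(score),
    stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  attr(out, "profiles") <- profiles[ord]
  out
}
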