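# Molecular descriptor registry.
#
# Two descriptor families feed the models: chemoinformatic descriptors
# computed from the molecular graph parsed out of a SMILES string
# (constitutional counts, topological indices, autocorrelations, additive
# property sums), and substitution-pattern descriptors computed directly
# from the biphenyl structure record (position indicators and relational
# chlorine counts around the oxygen substituents).  The registry is frozen:
# descriptor names and definitions only change with the package version.

.REGISTRY_VERSION <- "ohpcb-registry-1"

.ATOM_MASS <- c(C = 12.000, H = 1.00783, O = 15.9949, Cl = 34.96885)
.ATOM_ENEG <- c(C = 2.55, H = 2.20, O = 3.44, Cl = 3.16)
.ATOM_POLARIZ <- c(C = 1.76, H = 0.67, O = 0.80, Cl = 2.18)
.ATOM_VDW <- c(C = 1.70, H = 1.20, O = 1.52, Cl = 1.75)
.ATOM_MR <- c(C = 2.42, H = 1.03, O = 1.64, Cl = 5.97)

# ---- chemoinformatic descriptors ----------------------------------------

# g: molecular graph as produced by .molGraphsFromSmiles
.chemDescriptorsFromGraph <- function(g) {
  el <- g$elements
  nH <- sum(g$implicitH) + sum(el == "H")
  heavy <- which(el != "H")
  nHeavy <- length(heavy)
  counts <- c(C = sum(el == "C"), O = sum(el == "O"), Cl = sum(el == "Cl"))
  mw <- sum(.ATOM_MASS[el]) + sum(g$implicitH) * .ATOM_MASS[["H"]]

  gr <- igraph::graph_from_edgelist(g$bonds, directed = FALSE)
  if (igraph::vcount(gr) < length(el))
    gr <- igraph::add_vertices(gr, length(el) - igraph::vcount(gr))
  D <- igraph::distances(gr, v = heavy, to = heavy)
  deg <- igraph::degree(gr)[heavy]
  nb <- nHeavy  # vertices in the heavy-atom graph
  nE <- nrow(g$bonds)
  core <- igraph::coreness(gr)
  inRing <- core >= 2L

  # rotatable: acyclic single bonds between heavy atoms of degree >= 2
  rot <- 0L
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds[k, 1]; b <- g$bonds[k, 2]
    if (g$order[k] == 1L && el[a] != "H" && el[b] != "H" &&
        igraph::degree(gr, a) >= 2L && igraph::degree(gr, b) >= 2L &&
        !(inRing[a] && inRing[b]))
      rot <- rot + 1L
  }
  cyclomatic <- nE - length(el) + igraph::components(gr)$no

  # distance-based indices on the heavy-atom graph
  ut <- upper.tri(D)
  wiener <- sum(D[ut])
  harary <- sum(1 / D[ut])
  ecc <- apply(D, 1, max)
  radius <- min(ecc); diameter <- max(ecc)

  # adjacency among heavy atoms
  heavyIdx <- match(seq_along(el), heavy)
  adj <- vector("list", nHeavy)
  for (k in seq_len(nrow(g$bonds))) {
    a <- heavyIdx[g$bonds[k, 1]]; b <- heavyIdx[g$bonds[k, 2]]
    if (!is.na(a) && !is.na(b)) {
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  dH <- vapply(adj, length, integer(1))  # heavy-atom degree
  zagreb1 <- sum(dH^2)
  zagreb2 <- sum(vapply(seq_len(nHeavy), function(i)
    sum(dH[adj[[i]]][adj[[i]] > i] * dH[i]), numeric(1)))
  platt <- sum(dH * (dH - 1L))

  # Kier-Hall valence delta for heavy atoms
  hOn <- g$implicitH[heavy]
  dV <- ifelse(el[heavy] == "C", 4 - hOn,
        ifelse(el[heavy] == "O", 6 - hOn, 7 / 9))

  # simple and valence connectivity indices over paths of length 0..3
  chi0 <- sum(1 / sqrt(dH)); chi0v <- sum(1 / sqrt(dV))
  edges <- which(D == 1 & upper.tri(D), arr.ind = TRUE)
  chi1 <- sum(1 / sqrt(dH[edges[, 1]] * dH[edges[, 2]]))
  chi1v <- sum(1 / sqrt(dV[edges[, 1]] * dV[edges[, 2]]))
  paths2 <- 0L; chi2 <- 0; chi2v <- 0
  for (m in seq_len(nHeavy)) {
    nbm <- adj[[m]]
    if (length(nbm) >= 2L) {
      prs <- utils::combn(nbm, 2L)
      for (j in seq_len(ncol(prs))) {
        a <- prs[1, j]; b <- prs[2, j]
        paths2 <- paths2 + 1L
        chi2 <- chi2 + 1 / sqrt(dH[a] * dH[m] * dH[b])
        chi2v <- chi2v + 1 / sqrt(dV[a] * dV[m] * dV[b])
      }
    }
  }
  paths3 <- 0L; chi3 <- 0; chi3v <- 0
  for (k in seq_len(nrow(edges))) {
    b <- edges[k, 1]; c0 <- edges[k, 2]
    for (a in setdiff(adj[[b]], c0)) for (d in setdiff(adj[[c0]], c(a, b))) {
      paths3 <- paths3 + 1L
      chi3 <- chi3 + 1 / sqrt(dH[a] * dH[b] * dH[c0] * dH[d])
      chi3v <- chi3v + 1 / sqrt(dV[a] * dV[b] * dV[c0] * dV[d])
    }
  }
  paths3 <- paths3 / 2L; chi3 <- chi3 / 2; chi3v <- chi3v / 2

  nEdgesH <- nrow(edges)
  balaban <- if (cyclomatic + 1 > 0 && nEdgesH > 0) {
    s <- rowSums(D)
    nEdgesH / (cyclomatic + 1) *
      sum(1 / sqrt(s[edges[, 1]] * s[edges[, 2]]))
  } else 0
  schultz <- sum((dH + rowSums(D)) * dH)  # degree-distance flavour
  wienerPolarity <- sum(D[ut] == 3)
  eccConn <- sum(ecc * dH)
  petitjean <- if (radius > 0) (diameter - radius) / radius else 0

  A <- nHeavy
  kappa1 <- if (nEdgesH > 0) A * (A - 1)^2 / nEdgesH^2 else 0
  kappa2 <- if (paths2 > 0) (A - 1) * (A - 2)^2 / paths2^2 else 0
  kappa3 <- if (paths3 > 0) {
    if (A %% 2 == 1) (A - 1) * (A - 3)^2 / paths3^2
    else (A - 3) * (A - 2)^2 / paths3^2
  } else 0
  kierFlex <- kappa1 * kappa2 / A

  # Moreau-Broto autocorrelations (lags 0..5) and Moran I (lags 1..3)
  wts <- list(m = .ATOM_MASS[el[heavy]], e = .ATOM_ENEG[el[heavy]],
              p = .ATOM_POLARIZ[el[heavy]], v = .ATOM_VDW[el[heavy]])
  ats <- numeric(0)
  for (wn in names(wts)) {
    w <- wts[[wn]]
    for (d in 0:5) {
      val <- if (d == 0) sum(w^2) else {
        sel <- which(D == d & upper.tri(D), arr.ind = TRUE)
        if (nrow(sel)) sum(w[sel[, 1]] * w[sel[, 2]]) else 0
      }
      ats[paste0("ats", d, wn)] <- val
    }
  }
  moran <- numeric(0)
  for (wn in c("m", "e")) {
    w <- wts[[wn]]; wc <- w - mean(w); denom <- sum(wc^2) / nHeavy
    for (d in 1:3) {
      sel <- which(D == d, arr.ind = TRUE)
      val <- if (nrow(sel) && denom > 0)
        (sum(wc[sel[, 1]] * wc[sel[, 2]]) / nrow(sel)) / denom else 0
      moran[paste0("moran", d, wn)] <- val
    }
  }

  # additive property sums (implicit hydrogens included where physical)
  elAll <- c(el, rep("H", sum(g$implicitH)))
  sumPolar <- sum(.ATOM_POLARIZ[elAll])
  sumEneg <- sum(.ATOM_ENEG[elAll])
  mr <- sum(.ATOM_MR[elAll])
  # oxygens: ether vs hydroxyl by implicit hydrogen count
  oIdx <- which(el == "O")
  nOH <- sum(g$implicitH[oIdx] > 0L)
  nEther <- length(oIdx) - nOH
  tpsa <- 20.23 * nOH + 9.23 * nEther
  # crude additive hydrophobicity: fixed per-fragment contributions
  nArC <- sum(el == "C" & inRing)
  nAlC <- counts[["C"]] - nArC
  logp <- 0.294 * nArC + 0.130 * nAlC + 0.633 * counts[["Cl"]] -
    0.203 * nEther - 0.643 * nOH + 0.123 * (nH - nOH) - 0.2 * nOH

  c(molecularWeight = mw,
    nAtomsHeavy = nHeavy,
    nAtomsTotal = nHeavy + nH,
    nCarbon = counts[["C"]],
    nHydrogen = nH,
    nChlorine = counts[["Cl"]],
    nOxygen = counts[["O"]],
    nBondsHeavy = nEdgesH,
    fractionChlorine = counts[["Cl"]] / nHeavy,
    fractionHetero = (counts[["Cl"]] + counts[["O"]]) / nHeavy,
    meanAtomicMass = mw / (nHeavy + nH),
    halogenMassFraction = counts[["Cl"]] * .ATOM_MASS[["Cl"]] / mw,
    nRotatableBonds = rot,
    cyclomaticRings = cyclomatic,
    wienerIndex = wiener,
    wienerMean = wiener / max(1, sum(ut)),
    hararyIndex = harary,
    zagrebM1 = zagreb1,
    zagrebM2 = zagreb2,
    plattIndex = platt,
    chi0 = chi0, chi1 = chi1, chi2 = chi2, chi3 = chi3,
    chi0v = chi0v, chi1v = chi1v, chi2v = chi2v, chi3v = chi3v,
    balabanJ = balaban,
    graphRadius = radius,
    graphDiameter = diameter,
    petitjeanIndex = petitjean,
    eccentricConnectivity = eccConn,
    schultzMTI = schultz,
    wienerPolarity = wienerPolarity,
    kierKappa1 = kappa1, kierKappa2 = kappa2, kierKappa3 = kappa3,
    kierFlexibility = kierFlex,
    ats,
    moran,
    sumPolarizability = sumPolar,
    sumElectronegativity = sumEneg,
    tpsa = tpsa,
    approxLogP = unname(logp),
    molarRefractivity = mr,
    hBondAcceptors = counts[["O"]],
    hBondDonors = nOH,
    aromaticFraction = nArC / nHeavy)
}

#' Chemoinformatic descriptors from SMILES
#'
#' Computes the frozen registry of graph-based molecular descriptors for
#' one or more SMILES strings: constitutional counts, topological indices
#' (Wiener, Zagreb, Platt, Balaban J, connectivity chi, Kier kappa and
#' flexibility, eccentricity-based indices), Moreau-Broto and Moran
#' autocorrelations over atomic mass/electronegativity/polarizability/van
#' der Waals radius, and additive property sums (polar surface area,
#' additive hydrophobicity and molar refractivity).  SMILES parsing is
#' delegated to OpenBabel via \pkg{ChemmineOB}; descriptor values depend
#' only on the molecular graph, so any two SMILES of the same molecule
#' yield identical vectors.
#'
#' @param smiles character vector of SMILES strings.
#' @return numeric matrix, one row per input, columns the descriptor
#'   registry; attribute \code{registryVersion} records the registry id.
#' @examples
#' \donttest{
#' computeChemDescriptors("c1ccccc1-c2ccccc2")[, "molecularWeight"]
#' }
#' @export
computeChemDescriptors <- function(smiles) {
  graphs <- .molGraphsFromSmiles(smiles)
  rows <- lapply(graphs, .chemDescriptorsFromGraph)
  m <- do.call(rbind, rows)
  rownames(m) <- names(smiles) %||% smiles
  attr(m, "registryVersion") <- .REGISTRY_VERSION
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- substitution-pattern descriptors ------------------------------------

# cycle distance between two substitutable positions of the same ring
# (benzene positions 2..6): 1 = ortho, 2 = meta, 3 = para
.ringRelation <- function(a, b) {
  ia <- (a - 1L) %% 5L + 2L  # benzene position number 2..6
  ib <- (b - 1L) %% 5L + 2L
  d <- min(abs(ia - ib), 6L - abs(ia - ib))
  c("ortho", "meta", "para")[d]
}

#' Substitution-pattern descriptors
#'
#' Positional features computed from the structure record in its canonical
#' orientation: per-position chlorine indicators, chlorine counts (total,
#' per ring, per ortho/meta/para class), relational counts of chlorines
#' ortho/meta/para to the oxygen substituents on the same ring and
#' class-resolved counts on the opposite ring, substituent position-class
#' indicators, flanking-chlorine count, chlorine-chlorine adjacency
#' features and the ortho-ortho' pair count that drives the biphenyl
#' twist.
#'
#' @param s a \code{\linkS4class{BiphenylStructure}}.
#' @return named numeric vector (part of the frozen descriptor registry).
#' @export
computeSubstitutionDescriptors <- function(s) {
  stopifnot(is(s, "BiphenylStructure"))
  cl <- s@chlorines; sp <- s@substPos
  ind <- as.numeric(1:10 %in% cl)
  names(ind) <- paste0("clPos", sub("'", "p", .POS_LABELS))
  clClass <- .POS_CLASS[cl]

  relSame <- c(ortho = 0, meta = 0, para = 0)
  oppClass <- c(ortho = 0, meta = 0, para = 0)
  nOpp <- 0
  flank <- integer(0)
  for (p in sp) {
    same <- cl[.slotRing(cl) == .slotRing(p)]
    opp <- cl[.slotRing(cl) != .slotRing(p)]
    for (c0 in same) {
      rel <- .ringRelation(p, c0)
      relSame[rel] <- relSame[rel] + 1
    }
    flank <- union(flank, intersect(.adjacentSlots(p), cl))
    nOpp <- nOpp + length(opp)
    for (c0 in opp) oppClass[.POS_CLASS[c0]] <- oppClass[.POS_CLASS[c0]] + 1
  }
  substClass <- c(ortho = 0, meta = 0, para = 0)
  for (p in sp) substClass[.POS_CLASS[p]] <- substClass[.POS_CLASS[p]] + 1

  clAdj <- 0L
  for (c0 in cl) clAdj <- clAdj + sum(.adjacentSlots(c0) %in% cl)
  clAdj <- clAdj / 2L
  runLen <- function(ringSlots) {
    pos <- sort((ringSlots - 1L) %% 5L + 1L)
    if (!length(pos)) return(0L)
    best <- 1L; cur <- 1L
    for (i in seq_along(pos)[-1]) {
      cur <- if (pos[i] == pos[i - 1L] + 1L) cur + 1L else 1L
      best <- max(best, cur)
    }
    best
  }
  orthoA <- intersect(c(1L, 5L), cl); orthoB <- intersect(c(6L, 10L), cl)

  c(ind,
    nCl = length(cl),
    nClRingA = sum(cl <= 5L),
    nClRingB = sum(cl > 5L),
    nClOrtho = sum(clClass == "ortho"),
    nClMeta = sum(clClass == "meta"),
    nClPara = sum(clClass == "para"),
    nClOrthoToSubstSameRing = unname(relSame["ortho"]),
    nClMetaToSubstSameRing = unname(relSame["meta"]),
    nClParaToSubstSameRing = unname(relSame["para"]),
    nClOppRing = nOpp,
    nClOrthoOppRing = unname(oppClass["ortho"]),
    nClMetaOppRing = unname(oppClass["meta"]),
    nClParaOppRing = unname(oppClass["para"]),
    substOrtho = unname(substClass["ortho"]),
    substMeta = unname(substClass["meta"]),
    substPara = unname(substClass["para"]),
    nClFlankingSubst = length(flank),
    nSubstituents = length(sp),
    nClClAdjacentPairs = clAdj,
    maxClRun = max(runLen(cl[cl <= 5L]), runLen(cl[cl > 5L])),
    nOrthoOrthoPrimePairs = length(orthoA) * length(orthoB))
}

# ---- assembly ------------------------------------------------------------

#' Assemble the model descriptor matrix
#'
#' Concatenates chemoinformatic descriptors (computed from the methylated
#' or free SMILES of each structure) with substitution-pattern
#' descriptors.  With \code{clean = TRUE} the matrix is cleaned
#' deterministically: columns with any missing value, zero variance (when
#' more than one row is present) or exact duplication of an earlier column
#' are dropped, and the dropped-column log is attached.
#'
#' @param structures list of \code{\linkS4class{BiphenylStructure}}.
#' @param clean apply the cleaning pass.
#' @param asMethylEther compute chemoinformatic descriptors on the
#'   methylated derivatives (the analysed species); default \code{TRUE}.
#' @return data.frame of descriptors with rows named by
#'   \code{\link{canonicalName}} and attributes \code{registryVersion} and
#'   \code{dropped} (named character vector: column, reason).
#' @export
assembleDescriptorMatrix <- function(structures, clean = TRUE,
                                     asMethylEther = TRUE) {
  if (length(structures) == 0L) stop("no structures supplied")
  smiles <- vapply(structures, toSmiles, character(1),
                   asMethylEther = asMethylEther)
  chem <- computeChemDescriptors(smiles)
  subst <- do.call(rbind, lapply(structures,
                                 computeSubstitutionDescriptors))
  m <- cbind(chem, subst)
  rownames(m) <- vapply(structures, canonicalName, character(1))
  dropped <- character(0)
  if (clean) {
    cleaned <- .cleanDescriptorMatrix(m)
    m <- cleaned$matrix
    dropped <- cleaned$dropped
  }
  out <- as.data.frame(m)
  attr(out, "registryVersion") <- .REGISTRY_VERSION
  attr(out, "dropped") <- dropped
  out
}

# deterministic cleaning pass: drop NA columns, zero-variance columns
# (skipped with a warning for a single row) and exact duplicates of
# earlier columns; returns the cleaned matrix plus a named drop log
.cleanDescriptorMatrix <- function(m) {
  m <- as.matrix(m)
  dropped <- character(0)
  nas <- colnames(m)[apply(m, 2, anyNA)]
  dropped[nas] <- "missing values"
  m <- m[, setdiff(colnames(m), nas), drop = FALSE]
  if (nrow(m) > 1L) {
    vars <- apply(m, 2, stats::var)
    zv <- colnames(m)[vars == 0]
    dropped[zv] <- "zero variance"
    m <- m[, vars > 0, drop = FALSE]
    dup <- colnames(m)[duplicated(t(m))]
    dropped[dup] <- "duplicate column"
    m <- m[, setdiff(colnames(m), dup), drop = FALSE]
  } else {
    warning("single-row matrix: zero-variance filter skipped")
  }
  if (ncol(m) == 0L)
    stop("cleaning removed every descriptor column")
  list(matrix = m, dropped = dropped)
}

#' Registry manifest
#'
#' Names of all descriptors in the frozen registry (before cleaning),
#' with their family, plus the registry version.
#'
#' @return data.frame with columns \code{descriptor} and \code{family}.
#' @export
descriptorRegistry <- function() {
  bip <- biphenylStructure("2", c("4'" = "hydroxy"))
  chem <- colnames(computeChemDescriptors(toSmiles(bip, TRUE)))
  subst <- names(computeSubstitutionDescriptors(bip))
  out <- data.frame(
    descriptor = c(chem, subst),
    family = c(rep("chemoinformatic", length(chem)),
               rep("substitution", length(subst))),
    stringsAsFactors = FALSE)
  attr(out, "registryVersion") <- .REGISTRY_VERSION
  out
}
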