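# Shared fixtures, built once per test run.

.fixtureEnv <- new.env(parent = emptyenv())

# Default-condition training set (seed 1) plus models trained with
# reduced-but-documented resampling sizes (30 voting iterations, two-point
# tree grid) so the whole suite trains a single time.
trainedFixture <- function() {
  if (!is.null(.fixtureEnv$fx)) return(.fixtureEnv$fx)
  spec <- generatorSpec(seed = 1)
  ts <- generateTrainingSet(spec)
  rrtFit <- trainRrtModel(ts$structures, ts$rrt, cv = cvConfig(seed = 2),
                          descriptors = ts$descriptors)
  rrfModels <- trainRrfModels(
    ts$structures, ts$rrf,
    voteCfg = importanceVoteConfig(iterations = 30, minVotes = 15,
                                   seed = 2),
    gridCfg = gridSearchConfig(ntreeGrid = c(200, 500), seed = 2),
    descriptors = ts$descriptors)
  .fixtureEnv$fx <- list(
    spec = spec, ts = ts, rrtFit = rrtFit, rrfModels = rrfModels,
    isRec = internalStandard("IS", spec$referenceRt, 1e6, 100))
  .fixtureEnv$fx
}

# ---- independent symmetry oracle ----------------------------------------
# Brute-force canonicalization written from first principles: a labelled
# structure is a character vector over the ten positions in the order
# 2,3,4,5,6,2',3',4',5',6'; the eight numbering symmetries are generated
# by composing ring flips (2<->6, 3<->5 within a ring) and the ring swap,
# and the canonical form is the lexicographically smallest label string.
oracleSymmetryImages <- function(lab) {
  flipRing <- function(v) v[c(5, 4, 3, 2, 1)]
  ringA <- lab[1:5]; ringB <- lab[6:10]
  out <- list()
  for (a in list(ringA, flipRing(ringA)))
    for (b in list(ringB, flipRing(ringB))) {
      out[[length(out) + 1]] <- c(a, b)
      out[[length(out) + 1]] <- c(b, a)
    }
  out
}

oracleCanonical <- function(lab) {
  strs <- vapply(oracleSymmetryImages(lab), paste, "", collapse = "")
  strs[order(strs)][1]
}

# count symmetry-distinct structures over all chlorine subsets of the
# free positions, with fixed extra labels (e.g. one hydroxyl) placed at
# every possible position
oracleCountMonoOh <- function() {
  seen <- new.env(parent = emptyenv())
  count <- 0L
  for (oh in 1:10) {
    free <- setdiff(1:10, oh)
    for (n in 1:9) {
      cmb <- utils::combn(free, n)
      for (j in seq_len(ncol(cmb))) {
        lab <- rep("h", 10)
        lab[oh] <- "o"
        lab[cmb[, j]] <- "c"
        key <- oracleCanonical(lab)
        if (is.null(seen[[key]])) {
          assign(key, TRUE, envir = seen)
          count <- count + 1L
        }
      }
    }
  }
  count
}

oracleCountCongeners <- function() {
  seen <- new.env(parent = emptyenv())
  perHomolog <- integer(10)
  for (n in 1:10) {
    cmb <- utils::combn(10, n)
    for (j in seq_len(ncol(cmb))) {
      lab <- rep("h", 10)
      lab[cmb[, j]] <- "c"
      key <- oracleCanonical(lab)
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        perHomolog[n] <- perHomolog[n] + 1L
      }
    }
  }
  perHomolog
}

# independent molecular-formula oracle: atom counts of a SMILES via the
# OpenBabel-parsed atom block plus implicit hydrogens from valences
oracleFormulaCounts <- function(smiles) {
  sdfstr <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, " x\n"))
  sdf <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    strsplit(sdfstr, "\n", fixed = TRUE)[[1]]))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  el <- sub("_.*$", "", rownames(ab))
  val <- c(C = 4, O = 2, Cl = 1)
  bsum <- numeric(length(el))
  for (k in seq_len(nrow(bb))) {
    bsum[bb[k, 1]] <- bsum[bb[k, 1]] + bb[k, 3]
    bsum[bb[k, 2]] <- bsum[bb[k, 2]] + bb[k, 3]
  }
  counts <- table(el)
  c(C = unname(counts["C"]), Cl = unname(counts["Cl"]),
    O = unname(counts["O"]), H = sum(val[el] - bsum))
}

# independent nominal-mass oracle from the molecular formula and the
# chlorine isotope distribution
oraclePrecursor <- function(smiles) {
  f <- oracleFormulaCounts(smiles)
  base <- 12 * f[["C"]] + f[["H"]] + 35 * f[["Cl"]] + 16 * f[["O"]]
  probs <- stats::dbinom(0:f[["Cl"]], f[["Cl"]], 0.2424)
  base + 2 * (which(probs == max(probs))[1] - 1)
}
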