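test_that("MRM transitions reproduce the monitored m/z values", {
  pentaMono <- parseCanonicalName("4'-95")
  t1 <- mrmTransitions(pentaMono)
  expect_equal(unique(t1$precursor_mz), 356)
  expect_equal(t1$product_mz[t1$neutral_loss == 43], 313)

  triMono <- parseCanonicalName("4-22")
  t2 <- mrmTransitions(triMono)
  expect_equal(unique(t2$precursor_mz), 286)
  expect_equal(t2$product_mz[t2$neutral_loss == 43], 243)

  pentaDi <- parseCanonicalName("4,5-95")
  t3 <- mrmTransitions(pentaDi)
  expect_equal(unique(t3$precursor_mz), 386)
  expect_equal(t3$product_mz[t3$neutral_loss == 43], 343)

  expect_error(mrmTransitions(congenerFromBz(95)), "not a MeO-PCB")
})

test_that("transition masses agree with the formula/isotope oracle", {
  set.seed(19)
  oh <- enumerateMonoOhPcbs()
  some <- c(oh[sample(length(oh), 10)],
            candidateMembers(generateMetaboliteCandidates(95,
                                                          "di_oh")))
  for (s in some) {
    tr <- mrmTransitions(s)
    expect_equal(unique(tr$precursor_mz),
                 unname(oraclePrecursor(toSmiles(s, TRUE))),
                 label = canonicalName(s))
    expect_equal(tr$precursor_mz - tr$product_mz, c(15, 30, 43, 50, 66))
  }
})

test_that("profile normalization scales to unit sum and is idempotent", {
  p <- normalizeProfile(c(0, 0, 2, 2, 0))
  expect_equal(unname(p@rrf), c(0, 0, 0.5, 0.5, 0))
  expect_equal(sum(p@rrf), 1)
  p2 <- normalizeProfile(c(0, 0, 2, 2, 0) * 17)
  expect_equal(p2@rrf, p@rrf)
  expect_equal(normalizeProfile(p)@rrf, p@rrf)
  expect_error(normalizeProfile(rep(0, 5)), "zero")
})

test_that("cosine similarity has its exact limits and hand value", {
  prof <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  expect_equal(cosTheta(prof, prof), 1)
  expect_equal(cosTheta(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 1)), 0)
  expect_equal(cosTheta(c(1, 0, 1, 0, 0), c(1, 1, 0, 0, 0)), 0.5)
  expect_error(cosTheta(rep(0, 5), prof), "zero-norm")

  # symmetry, scale invariance and boundedness on random profiles
  set.seed(6)
  for (i in 1:50) {
    a <- stats::runif(5); b <- stats::runif(5)
    expect_equal(cosTheta(a, b), cosTheta(b, a), tolerance = 1e-12)
    expect_equal(cosTheta(a * 7, b), cosTheta(a, b), tolerance = 1e-12)
    v <- cosTheta(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("methoxy position classification follows the loss-50/43 contrast", {
  expect_identical(classifyMethoxyPosition(c(0.1, 0.1, 0.1, 0.6, 0.1)),
                   "ortho")
  expect_identical(classifyMethoxyPosition(c(0.1, 0.1, 0.6, 0.1, 0.1)),
                   "meta_para")
  expect_warning(
    cls <- classifyMethoxyPosition(c(0.1, 0.1, 0.35, 0.35, 0.1)),
    "tie")
  expect_identical(cls, "meta_para")
})

test_that("candidate ranking is dominance-consistent and order invariant", {
  fx <- trainedFixture()
  cand <- generateMetaboliteCandidates(95)
  members <- candidateMembers(cand)
  mono <- members[vapply(members, substituentCount, integer(1)) == 1L]

  # synthesize a peak exactly at one candidate's predicted values: that
  # candidate is best on both criteria and must rank first
  target <- mono[[3]]
  desc <- assembleDescriptorMatrix(list(target), clean = FALSE)
  suppressWarnings(rrtStar <- predictResponse(fx$rrtFit$model, desc)$fit)
  rrfStar <- vapply(as.character(NEUTRAL_LOSSES), function(l)
    10^predictResponse(fx$rrfModels[[l]], desc)$fit[1], numeric(1))
  peak <- c(list(peak_id = "T1", rrt = rrtStar),
            as.list(setNames(rrfStar * 1e5,
                             paste0("area_loss", NEUTRAL_LOSSES))))
  ranked <- rankCandidates(peak, mono, fx$rrtFit$model, fx$rrfModels)
  expect_identical(ranked$name[1], canonicalName(target))
  expect_equal(ranked$rank_rrt[1], 1L)
  expect_equal(ranked$rank_msms[1], 1L)
  # weighted score is the stated combination of the two ranks
  expect_equal(ranked$weighted_score,
               ranked$rank_rrt + ranked$rank_msms)

  # input order does not matter
  ranked2 <- rankCandidates(peak, rev(mono), fx$rrtFit$model,
                            fx$rrfModels)
  expect_identical(ranked2$name, ranked$name)

  # with zero MS/MS weight the ordering is pure RRT-deviation ranking
  ranked3 <- rankCandidates(peak, mono, fx$rrtFit$model, fx$rrfModels,
                            weights = c(rrt = 1, msms = 0))
  expect_identical(ranked3$name,
                   ranked$name[order(ranked$rrt_deviation)])

  expect_error(rankCandidates(peak, list(), fx$rrtFit$model,
                              fx$rrfModels),
               "empty")
  expect_error(rankCandidates(peak, members, fx$rrtFit$model,
                              fx$rrfModels),
               "homolog")
})
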