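isFix <- internalStandard("CB-209", 20, 5e5, 50)

test_that("relative retention times are ratios with exact minute algebra", {
  expect_equal(computeRrt(20, isFix), 1.0)
  expect_equal(computeRrt(30, isFix), 1.5)
  expect_error(computeRrt(-1, isFix), "positive")
  # minute-scale error reconstruction is exact
  set.seed(14)
  for (i in 1:25) {
    rt1 <- runif(1, 5, 45); rt2 <- runif(1, 5, 45)
    dRrt <- abs(computeRrt(rt1, isFix) - computeRrt(rt2, isFix))
    expect_equal(dRrt * isFix$retentionTime, abs(rt1 - rt2),
                 tolerance = 1e-12)
  }
})

test_that("response factors follow the internal-standard convention", {
  expect_equal(computeRrf(5e5, 50, isFix), 1.0)
  expect_equal(computeRrf(1e6, 50, isFix), 2.0)  # doubled response
  expect_error(computeRrf(-5, 50, isFix), "positive")

  # quantification is exactly inverse to RRF computation
  set.seed(15)
  for (i in 1:25) {
    conc <- runif(1, 1, 1000); area <- runif(1, 1e3, 1e7)
    rrf <- computeRrf(area, conc, isFix)
    back <- (area / isFix$response) / rrf * isFix$concentration
    expect_equal(back, conc, tolerance = 1e-9)
  }
})

test_that("the quantification transition follows the substitution rule", {
  expect_equal(as.integer(selectQuantTransition(
    parseCanonicalName("4'-95", kind = "methoxy"))), 43L)
  orthoS <- biphenylStructure("4", c(`2` = "methoxy"))
  expect_equal(as.integer(selectQuantTransition(orthoS)), 50L)
  mixed <- biphenylStructure("5", c(`2` = "methoxy", `4` = "methoxy"))
  sel <- selectQuantTransition(mixed)
  expect_true(is.na(sel))
  expect_identical(attr(sel, "flag"), "excluded")
  expect_error(selectQuantTransition(congenerFromBz(3)), "substituent")
})

test_that("transition selection agrees with profile classification on noiseless profiles", {
  spec <- generatorSpec(seed = 1)
  oh <- enumerateMonoOhPcbs()
  set.seed(20)
  some <- oh[sample(length(oh), 20)]
  desc <- assembleDescriptorMatrix(some, clean = FALSE)
  detLog <- ohpcb:::.ruleLogRrf(spec, desc)
  for (i in seq_along(some)) {
    cls <- classifyMethoxyPosition(10^detLog[i, ])
    sel <- selectQuantTransition(some[[i]])
    expect_identical(cls == "ortho", as.integer(sel) == 50L,
                     label = canonicalName(some[[i]]))
  }
})

test_that("peak quantification scales as expected and flags exclusions", {
  prof <- msmsProfile(c(0.05, 0.1, 0.6, 0.15, 0.1), normalize = TRUE)
  s <- parseCanonicalName("4'-95", kind = "methoxy")
  # RRF 1 on the selected transition and area equal to the reference
  # response returns the reference concentration
  peak <- list(peak_id = "p", area_loss43 = isFix$response)
  res <- quantifyPeak(peak, s, prof, 1 / unname(prof@rrf["43"]), isFix)
  expect_equal(res$concentration, isFix$concentration)
  expect_equal(res$transition_used, 43L)
  expect_identical(res$flag, "ok")

  # halving the response factor doubles the concentration
  res2 <- quantifyPeak(peak, s, prof, 0.5 / unname(prof@rrf["43"]),
                       isFix)
  expect_equal(res2$concentration, 2 * isFix$concentration)

  mixed <- biphenylStructure("5", c(`2` = "methoxy", `4` = "methoxy"))
  resx <- quantifyPeak(peak, mixed, prof, 1, isFix)
  expect_identical(resx$flag, "excluded")
  expect_true(is.na(resx$concentration))
})

test_that("fold-difference statistics are symmetric and match hand values", {
  f <- foldDifferenceStats(c(1, 1, 1), c(1, 1, 1))
  expect_equal(f$fractionWithin2x, 1)
  expect_equal(f$maxFold, 1)

  expect_equal(foldDifferenceStats(10, 5)$maxFold, 2)
  expect_equal(foldDifferenceStats(5, 10)$maxFold, 2)

  f3 <- foldDifferenceStats(c(1, 3, 1), c(1, 1, 2.5))
  expect_equal(f3$fractionWithin2x, 1 / 3)
  expect_equal(f3$fractionWithin3x, 1)
  expect_equal(f3$maxFold, 3)

  set.seed(16)
  e <- runif(20, 1, 100); a <- runif(20, 1, 100)
  expect_equal(foldDifferenceStats(e, a), foldDifferenceStats(a, e))
  expect_error(foldDifferenceStats(c(1, -1), c(1, 1)), "positive")
})
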