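test_that("congener enumeration reproduces the known congener space", {
  cong <- enumeratePcbCongeners()
  expect_length(cong, 209L)
  homolog <- table(vapply(cong, chlorineCount, integer(1)))
  expect_equal(unname(as.integer(homolog)),
               c(3L, 12L, 24L, 42L, 46L, 42L, 24L, 12L, 3L, 1L))
  # ordering is deterministic: BZ number equals list position
  expect_identical(names(cong), paste("PCB", 1:209))
  expect_equal(vapply(cong, bzNumber, integer(1)), setNames(1:209,
               names(cong)))
})

test_that("BZ numbering matches accepted assignments for known congeners", {
  known <- list(`1` = "2", `3` = "4", `11` = "3,3'", `15` = "4,4'",
                `22` = "2,3,4'", `25` = "2,3',4", `28` = "2,4,4'",
                `52` = "2,2',5,5'", `95` = "2,2',3,5',6",
                `101` = "2,2',4,5,5'", `103` = "2,2',4,5',6",
                `107` = "2,3,3',4',5", `108` = "2,3,3',4,5'",
                `109` = "2,3,3',4,6", `118` = "2,3',4,4',5",
                `126` = "3,3',4,4',5", `153` = "2,2',4,4',5,5'",
                `180` = "2,2',3,4,4',5,5'", `199` = "2,2',3,3',4,5,5',6'",
                `209` = "2,2',3,3',4,4',5,5',6,6'")
  for (bz in names(known)) {
    got <- paste(chlorinePositions(congenerFromBz(as.integer(bz))),
                 collapse = ",")
    expect_identical(got, known[[bz]], label = paste("PCB", bz))
  }
})

test_that("canonicalization is idempotent and symmetry invariant", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(1:9, 1)
    cl <- sample(10, n)
    free <- setdiff(1:10, cl)
    oh <- free[sample(length(free), 1)]
    labels <- c("2", "3", "4", "5", "6", "2'", "3'", "4'", "5'", "6'")
    s <- biphenylStructure(labels[cl], setNames("hydroxy", labels[oh]))
    # rebuilding from the canonical form is a fixed point
    s2 <- biphenylStructure(chlorinePositions(s),
                            setNames(substituentKinds(s),
                                     substituentPositions(s)))
    expect_identical(canonicalName(s2), canonicalName(s))
    # ring swap of the input description maps to the same object
    swapLab <- function(v) ifelse(grepl("'", v), sub("'", "", v),
                                  paste0(v, "'"))
    s3 <- biphenylStructure(swapLab(labels[cl]),
                            setNames("hydroxy", swapLab(labels[oh])))
    expect_identical(canonicalName(s3), canonicalName(s))
  }
})

test_that("mono-hydroxylated enumeration matches its size and the brute-force oracle", {
  oh <- enumerateMonoOhPcbs()
  expect_length(oh, 837L)
  expect_true(all(vapply(oh, substituentCount, integer(1)) == 1L))
  expect_true(all(vapply(oh, chlorineCount, integer(1)) %in% 1:9))
  # no duplicates after canonicalization
  expect_false(anyDuplicated(vapply(oh, canonicalName, character(1))) > 0)
  # independent exhaustive oracle over all (OH position x Cl subset) pairs
  expect_identical(oracleCountMonoOh(), 837L)
  perHomolog <- oracleCountCongeners()
  expect_identical(sum(perHomolog), 209L)
  expect_identical(perHomolog,
                   c(3L, 12L, 24L, 42L, 46L, 42L, 24L, 12L, 3L, 1L))
})

test_that("metabolite candidate generation reproduces the named products", {
  shift95 <- generateMetaboliteCandidates(95, classes = "shift_1_2")
  nm95 <- vapply(candidateMembers(shift95), canonicalName, character(1))
  expect_true("3-103" %in% nm95)

  shift28 <- generateMetaboliteCandidates(28, classes = "shift_1_2")
  nm28 <- vapply(candidateMembers(shift28), canonicalName, character(1))
  expect_true(all(c("4-22", "4'-25") %in% nm28))

  di95 <- generateMetaboliteCandidates(95, classes = "di_oh")
  expect_true("4,5-95" %in%
                vapply(candidateMembers(di95), canonicalName,
                       character(1)))

  # chlorine count is preserved in every class
  all95 <- generateMetaboliteCandidates(95)
  expect_true(all(vapply(candidateMembers(all95), chlorineCount,
                         integer(1)) == 5L))
  # provenance parallels members and members are unique
  expect_length(candidateProvenance(all95), length(all95))

  expect_error(generateMetaboliteCandidates(95, classes = character(0)),
               "at least one")
  # full di-OH enumeration is a superset of the ortho/para default
  full <- generateMetaboliteCandidates(95, classes = "di_oh",
                                       fullDiOh = TRUE)
  expect_gte(length(full), length(di95))
})

test_that("SMILES export is canonical, valid and round-trips", {
  bip <- biphenylStructure()
  smi <- toSmiles(bip)
  counts <- oracleFormulaCounts(smi)
  expect_equal(counts[["C"]], 12)
  expect_equal(counts[["H"]], 10)

  s <- parseCanonicalName("4'-95")
  # molecular formula of the methylated derivative: C13H7Cl5O
  f <- oracleFormulaCounts(toSmiles(s, asMethylEther = TRUE))
  expect_equal(unname(f[c("C", "H", "Cl", "O")]), c(13, 7, 5, 1))

  # round trip through an externally parsed SMILES
  set.seed(7)
  oh <- enumerateMonoOhPcbs()
  for (s0 in oh[sample(length(oh), 12)]) {
    back <- parseBiphenylSmiles(toSmiles(s0, asMethylEther = TRUE))
    expect_identical(canonicalName(back), canonicalName(s0))
    expect_identical(substituentKinds(back), "methoxy")
  }
  # byte-stable across calls
  expect_identical(toSmiles(s, TRUE), toSmiles(s, TRUE))
})

test_that("canonical names parse back to the same structure", {
  for (nm in c("4'-95", "4,5-95", "3-103", "4-22", "PCB 28")) {
    s <- parseCanonicalName(nm)
    expect_identical(canonicalName(s), nm)
  }
  # typographic primes and dashes are accepted
  expect_identical(canonicalName(parseCanonicalName("4′–95")),
                   "4'-95")
  expect_error(parseCanonicalName("not-a-name"), "cannot parse")
})
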