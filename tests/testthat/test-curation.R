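test_that("pK conversion matches the negative log molar definition", {
  expect_equal(toPK(10, "uM"), 5.0)
  expect_equal(toPK(1, "M"), 0.0)
  expect_equal(toPK(100, "nM"), 7.0)
  expect_equal(toPK(c(1, 1), c("mM", "nM")), c(3, 9))
  expect_error(toPK(-1, "uM"), "positive")
  expect_error(toPK(10, "pM"), "unknown unit")
})

test_that("censored records are excluded, order preserved", {
  rec <- data.frame(relation = c("=", ">", "=", "<"), value = 1:4)
  out <- filterCensored(rec)
  expect_equal(out$value, c(1, 3))
  expect_equal(nrow(filterCensored(rec[rec$relation != "=", ])), 0)
  expect_equal(nrow(filterCensored(rec[0, ])), 0)
})

test_that("binder labelling threshold is inclusive on the binder side", {
  expect_equal(labelCompound(c(5.0, 4.99, 7.2)), c("binder", "non-binder", "binder"))
  expect_equal(labelCompound(5.5, threshold = 6), "non-binder")
  expect_error(labelCompound(NA_real_), "finite")
})

test_that("duplicate aggregation is the median, bounded and permutation-invariant", {
  expect_equal(aggregateDuplicates(c(4, 5, 6))$pK, 5)
  expect_equal(aggregateDuplicates(c(4, 6))$pK, 5)
  expect_equal(aggregateDuplicates(7.3), list(pK = 7.3, n_measurements = 1L))
  expect_error(aggregateDuplicates(numeric(0)), "empty")
  set.seed(1)
  for (i in 1:20) {
    g <- stats::rnorm(sample(2:9, 1), 5, 1)
    m <- aggregateDuplicates(g)$pK
    expect_equal(m, aggregateDuplicates(sample(g, length(g)))$pK)
    expect_gte(m, min(g)); expect_lte(m, max(g))
  }
})

test_that("structure standardization strips salts, neutralizes and canonicalizes", {
  out <- standardizeStructure(c("OC(=O)c1ccccc1.[Na+]", "C[NH+]1CCCCC1"))
  expect_false(any(grepl("\\.", out)))              # counter-ion gone
  expect_false(any(grepl("\\+|\\-", out)))          # neutralized
  # neutral acid equals the standardized free acid
  expect_identical(out[1], standardizeStructure("OC(=O)c1ccccc1"))
  # idempotence
  expect_identical(standardizeStructure(out), out)
})

test_that("alternative spellings of one molecule canonicalize identically", {
  pairs <- list(
    c("c1ccccc1C", "Cc1ccccc1"),
    c("OCC", "CCO"),
    c("C1CCCCC1N", "NC1CCCCC1"),
    c("c1ccncc1", "c1ccc(cn1)"),
    c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"),
    c("N1CCNCC1", "C1CNCCN1"),
    c("FC(F)(F)c1ccccc1", "c1ccccc1C(F)(F)F"),
    c("CCN(CC)CC", "N(CC)(CC)CC"),
    c("O=C(N)c1ccccc1", "NC(=O)c1ccccc1"),
    c("c1ccc2ccccc2c1", "c1ccc2c(c1)cccc2"))
  for (p in pairs) {
    out <- standardizeStructure(p)
    expect_identical(out[1], out[2])
  }
  # distinct molecules stay distinct
  distinct <- standardizeStructure(c("CCO", "CCN", "CCC", "c1ccccc1"))
  expect_equal(anyDuplicated(distinct), 0)
})

test_that("unparseable structures are flagged NA with a warning", {
  expect_warning(out <- standardizeStructure(c("CCO", "C1CC", "not-a-smiles")),
                 "could not be parsed")
  expect_false(is.na(out[1]))
  expect_true(all(is.na(out[2:3])))
})

test_that("full curation yields one labelled record per unique structure", {
  rec <- data.frame(
    compound_id = c("a", "a", "b", "c", "d"),
    smiles = c("Cc1ccccc1CN(C)C", "CN(C)Cc1ccccc1C",    # same molecule, two spellings
               "CCCCN1CCCCC1", "CCCCN1CCCCC1.[Cl-]",    # same after salt removal
               "OC(=O)CCc1ccccc1"),
    endpoint = c("IC50", "Ki", "IC50", "EC50", "Kd"),
    relation = "=",
    value = c(1, 100, 0.01, 1, 50),
    unit = c("uM", "uM", "uM", "uM", "uM"),
    stringsAsFactors = FALSE)
  cur <- curateActivities(rec)
  expect_equal(nrow(cur), 3)
  expect_equal(anyDuplicated(cur$canonical_smiles), 0)
  tol <- cur[cur$n_measurements == 2 & cur$label == "binder" & cur$pK < 6, ]
  expect_equal(tol$pK, median(c(6, 4)))              # two spellings pooled
  expect_setequal(cur$label, c("binder", "non-binder"))
})

test_that("curation drops censored-only compounds and respects the endpoint vocabulary", {
  rec <- data.frame(compound_id = c("a", "b", "c"),
                    smiles = c("CCO", "CCN", "CCC"),
                    endpoint = c("IC50", "IC50", "AC50"),
                    relation = c(">", "=", "="),
                    value = 10, unit = "uM", stringsAsFactors = FALSE)
  cur <- curateActivities(rec)
  expect_equal(nrow(cur), 1)
  expect_equal(nrow(curateActivities(rec[0, ])), 0)
})

test_that("curating a noise-free synthetic cohort recovers the generated labels", {
  co <- generateCohort(generatorConfig(nCompounds = 80, pkNoiseSd = 0, seed = 13),
                       poses = FALSE)
  cur <- curateActivities(co@activities)
  std <- standardizeStructure(co@compounds$smiles)
  m <- match(std, cur$canonical_smiles)
  expect_false(anyNA(m))
  expect_identical(cur$label[m], co@compounds$label)
  expect_equal(cur$pK[m], co@compounds$pK, tolerance = 1e-9)
})

test_that("activity tables round-trip through delimited text", {
  co <- generateCohort(generatorConfig(nCompounds = 10, seed = 2), poses = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeActivityTable(co@activities, f)
  back <- readActivityTable(f)
  expect_equal(back$compound_id, co@activities$compound_id)
  expect_equal(back$value, co@activities$value, tolerance = 1e-9)
})
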