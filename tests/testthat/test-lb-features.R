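test_that("the ligand-based block has exactly 2059 features with provenance tags", {
  fm <- computeLBFeatures(c(mol1 = "c1ccccc1", mol2 = "CCN1CCCCC1"))
  expect_equal(ncol(fm), 2059)
  expect_equal(lbFeatureSchema()$total, 2059)
  pr <- provenance(fm)
  expect_equal(sum(pr == "lb_physchem"), 11)
  expect_equal(sum(pr == "lb_fp"), 2048)
  expect_true(all(featureValues(fm)[, pr == "lb_fp"] %in% c(0, 1)))
})

test_that("physicochemical descriptors hit known values on simple molecules", {
  fm <- featureValues(computeLBFeatures(c(benzene = "c1ccccc1", ethane = "CC")))
  expect_equal(fm["benzene", "HBondDonors"], 0)
  expect_equal(fm["benzene", "Stereocenters"], 0)
  expect_equal(fm["benzene", "FractionCsp3"], 0)
  expect_equal(fm["benzene", "HeavyAtoms"], 6)
  expect_equal(fm["ethane", "HeavyAtoms"], 2)
  expect_equal(fm["ethane", "RotatableBonds"], 0)
  expect_equal(fm["ethane", "TPSA"], 0)
  expect_equal(fm["ethane", "Atoms"], 8)            # C2H6
  expect_equal(fm["ethane", "FractionCsp3"], 1)
})

test_that("unparseable structures are skipped with a message", {
  expect_message(fm <- computeLBFeatures(c(a = "CCO", b = "][")), "skipping")
  expect_equal(rownames(featureValues(fm)), "a")
})

test_that("tanimoto matches its set definition and conventions", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)       # featureless pair convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "equal length")
  set.seed(4)
  for (i in 1:25) {
    a <- stats::rbinom(64, 1, 0.3); b <- stats::rbinom(64, 1, 0.3)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
    if (sum(a) > 0) expect_equal(tanimoto(a, a), 1)
  }
})

test_that("fingerprints are invariant to how the (standardized) molecule is written", {
  spellings <- standardizeStructure(c("Cc1ccccc1CCN1CCCCC1", "C(c1ccccc1C)CN1CCCCC1"))
  expect_identical(spellings[1], spellings[2])
  fm <- featureValues(computeLBFeatures(spellings[1], ids = "x"))
  fm2 <- featureValues(computeLBFeatures(spellings[2], ids = "x"))
  expect_identical(fm, fm2)
})

test_that("feature computation is order-independent", {
  smiles <- c(a = "CCO", b = "c1ccccc1", c = "CCN1CCCCC1")
  f1 <- featureValues(computeLBFeatures(smiles))
  f2 <- featureValues(computeLBFeatures(rev(smiles)))
  expect_equal(f1, f2[rownames(f1), ])
})

test_that("Murcko frameworks group side-chain variants and rank by frequency", {
  smiles <- c("Cc1ccccc1",                 # toluene        -> benzene
              "c1ccccc1",                  # benzene        -> benzene
              "CCc1ccccc1",                # ethylbenzene   -> benzene
              "OCc1ccccc1",                # benzyl alcohol -> benzene
              "CC1CCNCC1", "C1CCNCC1",     # piperidines    -> piperidine
              "CCC1CCNCC1",
              "c1ccc2ccccc2c1", "Cc1ccc2ccccc2c1",  # naphthalenes
              "CCCC")                      # acyclic        -> no-scaffold
  pk <- c(5, 6, 7, 4, 5, 5, 5, 8, 6, 3)
  tab <- murckoScaffoldSummary(smiles, pk)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$count, c(4, 3, 2, 1))   # sorted by descending frequency
  expect_true("no-scaffold" %in% tab$scaffold)
  # benzene group statistics from hand enumeration
  benz <- tab[tab$count == 4, ]
  expect_equal(benz$mean_pK, mean(c(5, 6, 7, 4)))
  expect_equal(benz$sd_pK, sd(c(5, 6, 7, 4)))
  # singleton group reports sd 0
  expect_equal(tab$sd_pK[tab$count == 1], 0)
})

test_that("toluene and benzene share one scaffold row", {
  tab <- murckoScaffoldSummary(c("Cc1ccccc1", "c1ccccc1"), c(5, 6))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$count, 2)
})

test_that("chemical-space PCA matches a direct eigen-decomposition on a toy", {
  x <- cbind(d1 = c(2.0, 1.0, 0.0, -1.0, -2.0),
             d2 = c(1.5, 0.5, 0.5, -0.5, -2.0))
  p <- chemspacePCA(x)
  xs <- scale(x)
  eig <- eigen(stats::cov(xs))
  expect_equal(abs(p$loadings[, 1]), abs(eig$vectors[, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(p$explained_variance[1], eig$values[1] / sum(eig$values),
               tolerance = 1e-8)
  # sign convention: the dominant loading of each component is positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)
})

test_that("PCA explained variances are non-increasing and sum to one", {
  set.seed(9)
  x <- matrix(stats::rnorm(200), ncol = 5,
              dimnames = list(NULL, paste0("d", 1:5)))
  p <- chemspacePCA(x)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-9)
})

test_that("duplicated descriptors concentrate variance on PC1; constants are dropped", {
  set.seed(10)
  base <- stats::rnorm(30)
  x <- cbind(a = base, b = base, c = stats::rnorm(30, sd = 0.01), k = rep(1, 30))
  expect_warning(p <- chemspacePCA(x), "constant")
  expect_false("k" %in% p$kept)
  expect_gt(p$explained_variance[1], 0.6)
  expect_error(chemspacePCA(x[1:2, ]), "at least 3")
})

test_that("the extended chemical-space descriptor set has 26 named columns", {
  d <- chemspaceDescriptors(c("c1ccccc1", "CCN1CCCCC1"))
  expect_equal(ncol(d), 26)
  expect_equal(unname(d[1, "AromaticAtoms"]), 6)
  expect_equal(unname(d[2, "BasicNitrogens"]), 1)
  expect_equal(unname(d[1, "Rings"]), 1)
})
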