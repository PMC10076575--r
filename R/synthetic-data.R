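# Synthetic cohort and pose-score generator. Structures are assembled from a
# closed fragment grammar (aryl heads, alkyl/ether linkers, amine or polar
# tails, echoing the scaffold families that dominate hERG binder collections)
# so descriptor calculation is real chemistry while nothing external is
# downloaded. A disjoint "novel" sub-grammar supports external sets of
# controlled dissimilarity.

.COHORT_GRAMMAR <- list(
  heads = c(
    phenyl         = "c1ccc(*)cc1",
    fluorophenyl   = "Fc1ccc(*)cc1",
    chlorophenyl   = "Clc1ccc(*)cc1",
    dichlorophenyl = "Clc1ccc(*)cc1Cl",
    methoxyphenyl  = "COc1ccc(*)cc1",
    tolyl          = "Cc1ccc(*)cc1",
    naphthyl       = "c1ccc2cc(*)ccc2c1",
    pyridyl        = "c1cc(*)ccn1",
    cf3phenyl      = "FC(F)(F)c1ccc(*)cc1",
    biphenyl       = "c1ccc(-c2ccc(*)cc2)cc1",
    cyanophenyl    = "N#Cc1ccc(*)cc1",
    hydroxyphenyl  = "Oc1ccc(*)cc1"),
  linkers = c("", "C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)", "OCC", "OCCC",
              "C(=O)CC", "COCC", "CNCC"),
  tails = c(
    dimethylamino     = "N(C)C",
    diethylamino      = "N(CC)CC",
    piperidine        = "N3CCCCC3",
    benzylpiperidine  = "N3CCC(Cc4ccccc4)CC3",
    piperazine        = "N3CCNCC3",
    nmethylpiperazine = "N3CCN(C)CC3",
    morpholine        = "N3CCOCC3",
    chiralamine       = "[C@@H](C)N(C)C",
    carboxyl          = "C(=O)O",
    sulfonamide       = "S(N)(=O)=O",
    amide             = "C(=O)N",
    hydroxyl          = "O",
    nitrile           = "C#N",
    methylester       = "C(=O)OC"))

.NOVEL_GRAMMAR <- list(
  heads = c(
    thienyl        = "c1cc(*)sc1",
    furyl          = "c1cc(*)oc1",
    pyrimidinyl    = "c1ncc(*)cn1",
    cyclohexyl     = "C1CCC(*)CC1",
    bromophenyl    = "Brc1ccc(*)cc1",
    dimethoxyphenyl= "COc1ccc(*)cc1OC"),
  linkers = c("C(C)C", "CCOCC", "CNC", "CCSCC", "C(=O)NC"),
  tails = c(
    pyrrolidine   = "N3CCCC3",
    azepane       = "N3CCCCCC3",
    trifluoromethyl = "C(F)(F)F",
    methylsulfone = "S(C)(=O)=O",
    aminoalcohol  = "N(C)CCO",
    chiralalcohol = "[C@H](O)CN(C)C"))

.assembleSmiles <- function(head, linker, tail) {
  sub("*", paste0(linker, tail), head, fixed = TRUE)
}

# Fixed chemotype SAR landscape: every (head, tail) fragment combination
# carries a standard-normal activity offset, drawn once from an internal
# constant seed so it is a property of the grammar itself — identical across
# cohorts, seeds and external sets. This is what makes nearest-neighbour
# similarity informative: models can learn the offsets of chemotypes they
# have seen, but not of novel ones.
.scaffoldEffects <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      heads <- c(names(.COHORT_GRAMMAR$heads), names(.NOVEL_GRAMMAR$heads))
      tails <- c(names(.COHORT_GRAMMAR$tails), names(.NOVEL_GRAMMAR$tails))
      cache <<- withSeed(8675309L, {
        matrix(stats::rnorm(length(heads) * length(tails)),
               nrow = length(heads), dimnames = list(heads, tails))
      })
    }
    cache
  }
})

#' Create a synthetic-data generator configuration
#'
#' All defaults encode the study conditions the generator emulates: a cohort
#' with ~57% binders, pK values concentrated near the 5.0 labelling
#' threshold, 5 docking poses per molecule for each of three engines, 25
#' shared rescoring functions (plus a 29-column pharmacophore-distance block
#' for the LiGen engine, totalling 55 descriptors there), a 2.4% per-engine
#' docking failure rate, and pose-level noise exceeding compound-level noise
#' so that averaging over poses denoises.
#'
#' @param nCompounds cohort size.
#' @param binderFraction target binder fraction.
#' @param pkCenter,pkSpread centre / sd of emitted pK values.
#' @param pkNoiseSd structure-independent latent-affinity noise (standardized
#'   scale); 0 makes pK an exact function of structure.
#' @param lipophilicityShift,polarityShift standardized effect sizes tying
#'   the latent affinity to computed logP (positively) and TPSA (negatively).
#' @param scaffoldEffectSd scale of the grammar's fixed chemotype activity
#'   offsets (structure-activity signal beyond bulk physicochemistry).
#' @param nPoses poses per molecule per engine.
#' @param engines engine identifiers.
#' @param nRescoring rescoring functions per engine.
#' @param nPharmacophoreDistances LiGen-mode distance block size.
#' @param poseNoiseSd,compoundNoiseSd,engineBiasSd score noise components.
#' @param undockedFraction per-engine docking failure fraction.
#' @param stereoisomerFraction fraction of compounds emitted as 2-isomer
#'   groups.
#' @param seed integer seed.
#' @return A [GeneratorConfig-class] object (validated).
#' @examples
#' generatorConfig(nCompounds = 100, seed = 7)
#' @export
generatorConfig <- function(nCompounds = 1000L,
                            binderFraction = 7303 / 12789,
                            pkCenter = 5.0, pkSpread = 1.0, pkNoiseSd = 0.5,
                            lipophilicityShift = 1.0, polarityShift = 0.7,
                            scaffoldEffectSd = 0.8,
                            nPoses = 5L,
                            engines = c("PLANTS", "LiGen", "GOLD"),
                            nRescoring = 25L, nPharmacophoreDistances = 29L,
                            poseNoiseSd = 2.5, compoundNoiseSd = 1.2,
                            engineBiasSd = 0.3,
                            undockedFraction = 0.024,
                            stereoisomerFraction = 0.1,
                            seed = 1L) {
  methods::new("GeneratorConfig",
    nCompounds = as.integer(nCompounds), binderFraction = binderFraction,
    pkCenter = pkCenter, pkSpread = pkSpread, pkNoiseSd = pkNoiseSd,
    lipophilicityShift = lipophilicityShift, polarityShift = polarityShift,
    scaffoldEffectSd = scaffoldEffectSd,
    nPoses = as.integer(nPoses), engines = engines,
    nRescoring = as.integer(nRescoring),
    nPharmacophoreDistances = as.integer(nPharmacophoreDistances),
    poseNoiseSd = poseNoiseSd, compoundNoiseSd = compoundNoiseSd,
    engineBiasSd = engineBiasSd, undockedFraction = undockedFraction,
    stereoisomerFraction = stereoisomerFraction, seed = as.integer(seed))
}

# Draw structures from a grammar; `novelWeight` is the probability that each
# slot is drawn from the novel sub-grammar instead of the core one.
.drawStructures <- function(n, novelWeight = 0) {
  pick <- function(core, novel) {
    useNovel <- stats::runif(n) < novelWeight
    out <- names(core)[sample.int(length(core), n, replace = TRUE)]
    if (any(useNovel)) out[useNovel] <- names(novel)[sample.int(length(novel), sum(useNovel), replace = TRUE)]
    out
  }
  allHeads <- c(.COHORT_GRAMMAR$heads, .NOVEL_GRAMMAR$heads)
  allLinkers <- c(.COHORT_GRAMMAR$linkers, .NOVEL_GRAMMAR$linkers)
  allTails <- c(.COHORT_GRAMMAR$tails, .NOVEL_GRAMMAR$tails)
  names(allLinkers) <- as.character(seq_along(allLinkers))
  coreL <- allLinkers[seq_along(.COHORT_GRAMMAR$linkers)]
  novelL <- allLinkers[-seq_along(.COHORT_GRAMMAR$linkers)]
  heads <- pick(.COHORT_GRAMMAR$heads, .NOVEL_GRAMMAR$heads)
  linkers <- pick(coreL, novelL)
  tails <- pick(.COHORT_GRAMMAR$tails, .NOVEL_GRAMMAR$tails)
  data.frame(head = heads, linker = linkers, tail = tails,
             smiles = mapply(.assembleSmiles, allHeads[heads],
                             allLinkers[linkers], allTails[tails],
                             USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

.buildCohort <- function(config, novelWeight = 0, idPrefix = "CPD") {
  n <- config@nCompounds
  empty <- data.frame(compound_id = character(0), smiles = character(0),
                      pK = numeric(0), label = character(0),
                      n_isomers = integer(0), stringsAsFactors = FALSE)
  if (n == 0) {
    return(methods::new("SyntheticCohort", compounds = empty,
                        activities = .emptyActivities(), poseTables = list(),
                        truth = data.frame(), params = list(config = config)))
  }
  withSeed(config@seed, {
    drawn <- .drawStructures(n, novelWeight)
    smiles <- drawn$smiles
    pc <- .physchem(smiles)
    logP <- pc[, "logP"]; tpsa <- pc[, "TPSA"]
    zL <- as.numeric(scale(logP)); zT <- as.numeric(scale(tpsa))
    zL[!is.finite(zL)] <- 0; zT[!is.finite(zT)] <- 0
    # Orthogonalized axes: u is the logP signal with TPSA partialled out and
    # vice versa, so each shift parameter controls exactly one class contrast.
    r <- safeCor(zL, zT)
    u <- zL - r * zT; v <- zT - r * zL
    u <- as.numeric(scale(u)); v <- as.numeric(scale(v))
    u[!is.finite(u)] <- 0; v[!is.finite(v)] <- 0
    chemotype <- .scaffoldEffects()[cbind(drawn$head, drawn$tail)]
    affinity <- config@lipophilicityShift * u - config@polarityShift * v +
      config@scaffoldEffectSd * chemotype +
      stats::rnorm(n, 0, config@pkNoiseSd)
    sdA <- stats::sd(affinity)
    z <- if (is.finite(sdA) && sdA > 0) (affinity - mean(affinity)) / sdA else affinity * 0
    pK <- config@pkCenter + config@pkSpread * (z - stats::qnorm(1 - config@binderFraction))
    label <- ifelse(pK >= config@pkCenter, "binder", "non-binder")
    nIso <- 1L + stats::rbinom(n, 1L, config@stereoisomerFraction)
    ids <- sprintf("%s%05d", idPrefix, seq_len(n))
    compounds <- data.frame(compound_id = ids, smiles = smiles, pK = pK,
                            label = label, n_isomers = nIso,
                            stringsAsFactors = FALSE)
    truth <- data.frame(compound_id = ids, affinity = affinity, logP = logP,
                        TPSA = tpsa, chemotype = chemotype,
                        head = drawn$head, tail = drawn$tail,
                        pK = pK, label = label, stringsAsFactors = FALSE)
    activities <- .emitActivities(compounds)
    methods::new("SyntheticCohort", compounds = compounds,
                 activities = activities, poseTables = list(), truth = truth,
                 params = list(config = config, novelWeight = novelWeight))
  })
}

.emptyActivities <- function() {
  data.frame(compound_id = character(0), smiles = character(0),
             endpoint = character(0), relation = character(0),
             value = numeric(0), unit = character(0), stringsAsFactors = FALSE)
}

# Emit 1-3 exact measurements per compound across endpoint types and units,
# plus occasional censored records that curation is expected to discard.
.emitActivities <- function(compounds) {
  n <- nrow(compounds)
  nMeas <- 1L + stats::rbinom(n, 2L, 0.2)
  idx <- rep(seq_len(n), nMeas)
  endpoints <- sample(c("IC50", "EC50", "Ki", "Kd"), length(idx), replace = TRUE,
                      prob = c(0.6, 0.1, 0.2, 0.1))
  unit <- sample(c("uM", "nM"), length(idx), replace = TRUE)
  molar <- 10^(-compounds$pK[idx])
  value <- ifelse(unit == "uM", molar * 1e6, molar * 1e9)
  act <- data.frame(compound_id = compounds$compound_id[idx],
                    smiles = compounds$smiles[idx],
                    endpoint = endpoints, relation = "=",
                    value = value, unit = unit, stringsAsFactors = FALSE)
  cens <- which(stats::runif(n) < 0.05)
  if (length(cens)) {
    censored <- data.frame(compound_id = compounds$compound_id[cens],
                           smiles = compounds$smiles[cens],
                           endpoint = "IC50",
                           relation = sample(c(">", "<"), length(cens), replace = TRUE),
                           value = 10, unit = "uM", stringsAsFactors = FALSE)
    act <- rbind(act, censored)
  }
  act[order(match(act$compound_id, compounds$compound_id)), , drop = FALSE]
}

#' Generate a synthetic compound cohort
#'
#' Assembles structures from the built-in fragment grammar, derives a latent
#' binding affinity from the computed lipophilicity and polarity of each
#' structure (plus Gaussian noise), maps it monotonically to a pK centred on
#' the labelling threshold, and emits activity records in raw
#' activity-table layout. When `poses = TRUE` a pose-score table is attached
#' for every configured engine.
#'
#' @param config a [GeneratorConfig-class].
#' @param poses attach pose-score tables for all configured engines?
#' @return A [SyntheticCohort-class].
#' @examples
#' cohort <- generateCohort(generatorConfig(nCompounds = 20, seed = 1), poses = FALSE)
#' head(cohort@compounds)
#' @export
generateCohort <- function(config, poses = TRUE) {
  methods::validObject(config)
  cohort <- .buildCohort(config, novelWeight = 0, idPrefix = "CPD")
  if (poses && nrow(cohort@compounds) > 0) {
    cohort@poseTables <- stats::setNames(
      lapply(config@engines, function(e) generatePoseScores(cohort, e, config)),
      config@engines)
  }
  cohort
}

# Shared rescoring-function dictionary (25 names echoing a docking rescoring
# tool's output: empirical score components, hydrophobic-contact scores,
# electrostatics, Lennard-Jones terms and contact counts).
.RESCORE_NAMES <- c(
  "PLP", "PLP95", "PLP_HB", "PLP_Steric", "ChemPLP_rescore",
  "XScore_HP", "XScore_HM", "XScore_HS", "XScore_HB", "XScore_RT", "XScore_AVG",
  "MLPInS", "MLPInS2", "MLPInS3", "MLPInS_Sum",
  "Elect", "ElectDD",
  "CVFF_LJ", "CHARMM_LJ",
  "Contacts4.0", "Contacts4.5", "Contacts5.0", "Contacts5.5", "Contacts6.0",
  "APBS_Elect")

.primaryScoreName <- function(engine) {
  switch(engine, PLANTS = "ChemPLP", GOLD = "GOLD.ChemPLP", LiGen = "CSopt",
         paste0(engine, ".score"))
}

#' Generate an engine-like pose-score table for a cohort
#'
#' Emulates docking plus rescoring output under a latent-factor model: every
#' scoring function loads on the compound's latent affinity (loadings drawn
#' once per engine from a seeded uniform(0.3, 1)), with additive
#' engine-level bias, compound-level noise shared across that engine's
#' columns, pose-level noise shared across columns within a pose, and a
#' smaller per-column jitter tied to the pose noise scale. The primary score
#' uses a lower-is-better convention (negative loading) and defines the pose
#' ranking; rank 1 is the best primary score. A seeded binomial draw marks a
#' fraction of compounds as undocked for this engine.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param engine one of `config@engines`.
#' @param config the [GeneratorConfig-class] used for the cohort.
#' @return A [PoseScoreTable-class].
#' @export
generatePoseScores <- function(cohort, engine, config) {
  stopIfNot(engine %in% config@engines,
            sprintf("unknown engine '%s' (configured: %s)", engine,
                    paste(config@engines, collapse = ", ")))
  comp <- cohort@compounds
  eIdx <- match(engine, config@engines)
  primary <- .primaryScoreName(engine)
  rescore <- .RESCORE_NAMES[seq_len(min(config@nRescoring, length(.RESCORE_NAMES)))]
  if (config@nRescoring > length(.RESCORE_NAMES)) {
    rescore <- c(rescore, sprintf("Rescore%02d", seq_len(config@nRescoring - length(.RESCORE_NAMES))))
  }
  pharm <- if (identical(engine, "LiGen") && config@nPharmacophoreDistances > 0) {
    sprintf("PharmDist%02d", seq_len(config@nPharmacophoreDistances))
  } else character(0)
  allNames <- c(primary, rescore, pharm)
  directions <- stats::setNames(c("lower", rep("higher", length(rescore)),
                                  rep("lower", length(pharm))), allNames)
  nP <- config@nPoses
  withSeed(deriveSeed(config@seed, 7919L * eIdx), {
    loadings <- c(-stats::runif(1, 0.3, 1),
                  stats::runif(length(rescore), 0.3, 1),
                  -stats::runif(length(pharm), 0.0, 0.2))
    names(loadings) <- allNames
    bias <- stats::rnorm(length(allNames), 0, config@engineBiasSd)
    nf <- length(allNames)
    docked <- if (nrow(comp)) stats::rbinom(nrow(comp), 1L, 1 - config@undockedFraction) == 1L else logical(0)
    keep <- which(docked)
    affinity <- cohort@truth$affinity[match(comp$compound_id, cohort@truth$compound_id)]
    # compound-level noise: most of it is the systematic part every engine
    # shares (rigid-receptor and scoring-function limits look the same to
    # all programs), the rest is engine-specific
    shared <- withSeed(deriveSeed(config@seed, 104729L),
                       stats::rnorm(nrow(comp), 0, config@compoundNoiseSd * sqrt(0.7)))
    compNoise <- shared + stats::rnorm(nrow(comp), 0, config@compoundNoiseSd * sqrt(0.3))
    # expand (compound, isomer) groups, nP pose rows each; fully vectorized
    nIsoK <- comp$n_isomers[keep]
    gComp <- rep(keep, nIsoK)
    gIso <- sequence(nIsoK)
    nGroups <- length(gComp)
    rowComp <- rep(gComp, each = nP)
    rowIso <- rep(gIso, each = nP)
    gid <- rep(seq_len(max(nGroups, 0)), each = nP)[seq_along(rowComp)]
    # compound- and pose-level noise perturb the effective binding quality a
    # pose presents, so every scoring function sees them through its own
    # loading; a small per-column jitter stays independent
    poseShift <- stats::rnorm(length(rowComp), 0, config@poseNoiseSd)
    jitter <- matrix(stats::rnorm(length(rowComp) * nf, 0, 0.25 * config@poseNoiseSd),
                     ncol = nf)
    quality <- affinity[rowComp] + compNoise[rowComp] + poseShift
    sc <- outer(quality, loadings) +
      matrix(bias, nrow = length(rowComp), ncol = nf, byrow = TRUE) + jitter
    ord <- order(gid, sc[, 1], method = "radix")    # primary is lower-is-better
    sc <- sc[ord, , drop = FALSE]
    rowComp <- rowComp[ord]; rowIso <- rowIso[ord]
    rows <- cbind(
      data.frame(compound_id = if (length(rowComp)) comp$compound_id[rowComp] else character(0),
                 isomer_id = if (length(rowComp)) sprintf("%s_i%d", comp$compound_id[rowComp], rowIso) else character(0),
                 pose_rank = rep(seq_len(nP), nGroups), stringsAsFactors = FALSE),
      stats::setNames(as.data.frame(sc), allNames))
    rownames(rows) <- NULL
    methods::new("PoseScoreTable", engine = engine, scores = rows,
                 scoreNames = allNames, directions = directions,
                 nPoses = as.integer(nP))
  })
}

#' Generate an external validation cohort of controlled dissimilarity
#'
#' Uses the same generative model as [generateCohort()] but draws an
#' increasing share of fragments from a disjoint sub-grammar, so the
#' nearest-neighbour Tanimoto similarity to a reference cohort shifts
#' downward as `dissimilarity` rises.
#'
#' @param config a [GeneratorConfig-class] (its `nCompounds` and `seed` apply
#'   to the external set).
#' @param dissimilarity one of `"low"`, `"medium"`, `"high"`.
#' @param poses attach pose tables?
#' @return A [SyntheticCohort-class].
#' @export
generateExternalSet <- function(config, dissimilarity = c("low", "medium", "high"),
                                poses = TRUE) {
  dissimilarity <- match.arg(dissimilarity)
  methods::validObject(config)
  w <- c(low = 0.2, medium = 0.6, high = 1.0)[[dissimilarity]]
  cohort <- .buildCohort(config, novelWeight = w, idPrefix = "EXT")
  if (poses && nrow(cohort@compounds) > 0) {
    cohort@poseTables <- stats::setNames(
      lapply(config@engines, function(e) generatePoseScores(cohort, e, config)),
      config@engines)
  }
  cohort
}
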