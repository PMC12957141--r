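test_that("simulated trees are ultrametric, unit-height and reproducible", {
  cfg <- simulationConfig(seed = 21)
  tr <- simulateHostTree(cfg)
  expect_equal(ape::Ntip(tr), cfg$nHosts)
  expect_true(isUltrametric(tr, tol = 1e-9))
  expect_equal(treeHeight(tr), 1, tolerance = 1e-12)
  expect_identical(writeNewick(simulateHostTree(cfg)), writeNewick(tr))
  # different seed, different tree
  expect_false(identical(writeNewick(simulateHostTree(simulationConfig(seed = 22))),
                         writeNewick(tr)))
})

test_that("simulated traits carry the configured type mix and tree signal", {
  cfg <- simulationConfig(seed = 23)
  tr <- simulateHostTree(cfg)
  tt <- simulateTraits(tr, cfg)
  expect_equal(sum(traitTypes(tt) == "quantitative"), cfg$nQuantTraits)
  expect_equal(sum(traitTypes(tt) == "ordinal"), cfg$nOrdinalTraits)
  expect_equal(sum(traitTypes(tt) == "categorical"), cfg$nCategoricalTraits)
  expect_equal(sum(traitTypes(tt) == "binary"), cfg$nBinaryTraits)
  expect_setequal(speciesNames(tt), tr$tip.label)
  # ordinal trait uses 5 ranks
  expect_true(all(tt@data$ord1 %in% 1:5))

  # Brownian variance across tips grows with tree height
  set.seed(24)
  vShort <- numeric(60); vTall <- numeric(60)
  base <- ape::rcoal(20)
  base$edge.length <- base$edge.length / treeHeight(base)
  tall <- base; tall$edge.length <- tall$edge.length * 16
  for (i in 1:60) {
    vShort[i] <- var(ape::rTraitCont(base, model = "BM", sigma = 1))
    vTall[i] <- var(ape::rTraitCont(tall, model = "BM", sigma = 1))
  }
  expect_gt(mean(vTall), 4 * mean(vShort))
})

test_that("theta controls phylogenetic clustering of simulated host sets", {
  baseCfg <- simulationConfig(seed = 25, nParasites = 20, nRegions = 4)
  tr <- simulateHostTree(baseCfg)
  meanDP <- function(theta) {
    cfg <- simulationConfig(seed = 25, nParasites = 20, nRegions = 4,
                            theta = theta)
    sim <- simulateIncidence(tr, cfg)
    nb <- nicheBreadthTable(sim$incidence, tr,
                            hostNiche:::NULL_DISS(tr$tip.label))
    mean(nb$DP[nb$scale != "continental"])
  }
  dpDiffuse <- meanDP(0)
  dpTight <- meanDP(60)
  # strong concentration pulls assemblages towards nearest neighbours
  expect_gt(dpDiffuse, dpTight + 0.5)

  # determinism of the full incidence draw
  cfg <- simulationConfig(seed = 26, nParasites = 12, nRegions = 3)
  a <- simulateIncidence(tr, cfg)
  b <- simulateIncidence(tr, cfg)
  expect_identical(a$incidence@records, b$incidence@records)
  expect_identical(a$truth, b$truth)
})

test_that("generated bundles pass the pipeline's validators unchanged", {
  study <- simulateStudy(simulationConfig(seed = 27, nParasites = 16,
                                          nRegions = 4, nHosts = 18))
  expect_s4_class(study$incidence, "IncidenceSet")
  expect_true(all(hostSpecies(study$incidence) %in% study$hostTree$tip.label))
  expect_true(all(parasites(study$incidence) %in% study$parasiteTree$tip.label))
  expect_true(all(study$parasiteTraits$abundance > 0))
  expect_true(all(study$parasiteTraits$bodySize > 0))
  # trait table covers every host and the Gower matrix is well-defined
  gd <- gowerMatrix(study$hostTraits)
  expect_true(all(hostSpecies(study$incidence) %in% rownames(gd)))
  # ground truth records the generating parameters
  expect_named(study$truth,
               c("theta", "focalHosts", "targetICC", "fBetween", "pilotICC",
                 "aCA", "bCA", "sdCA", "aBS", "bBS", "sdBS", "lambda"),
               ignore.order = TRUE)
  # (config, seed) fully determine the dataset
  study2 <- simulateStudy(simulationConfig(seed = 27, nParasites = 16,
                                           nRegions = 4, nHosts = 18))
  expect_identical(study$incidence@records, study2$incidence@records)
  expect_identical(study$parasiteTraits, study2$parasiteTraits)
})

test_that("known continental slopes are recoverable from generated responses", {
  # average recovered slope over replicate generated datasets
  slopes <- vapply(1:20, function(i) {
    cfg <- simulationConfig(seed = 300 + i, nParasites = 40, nRegions = 8,
                            nHosts = 30, bCA = 0.3, lambdaResid = 0.3)
    study <- simulateStudy(cfg)
    filt <- applyFilters(study$incidence, filterConfig())
    nb <- nicheBreadthTable(filt, study$hostTree,
                            gowerMatrix(study$hostTraits))
    t3 <- runAbundanceSuite(nb, study$parasiteTraits, study$parasiteTree,
                            "continental", seed = 1)
    t3$slope[t3$predictor == "DP"]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.3), 0.1)

  # negative body-size dependence propagates with the right sign
  cfg <- simulationConfig(seed = 31, nParasites = 50, nRegions = 8,
                          nHosts = 30, bBS = -0.6, sdBS = 0.1)
  study <- simulateStudy(cfg)
  filt <- applyFilters(study$incidence, filterConfig())
  nb <- nicheBreadthTable(filt, study$hostTree, gowerMatrix(study$hostTraits))
  t5 <- runBodySizeSuite(nb, study$parasiteTraits, study$parasiteTree,
                         "continental", seed = 1)
  expect_lt(t5$slope[t5$response == "DP"], 0)
})
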