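test_that("identical config and seed give an identical bundle", {
  cfg <- smallSimConfig(seed = 42L)
  b1 <- simulateBundle(cfg)
  b2 <- simulateBundle(cfg)
  expect_identical(as.character(proteins(b1$dataset)),
                   as.character(proteins(b2$dataset)))
  expect_identical(ptmSites(b1$dataset), ptmSites(b2$dataset))
  expect_identical(mutationTable(b1$dataset), mutationTable(b2$dataset))
  expect_identical(survivalTable(b1$dataset), survivalTable(b2$dataset))
  expect_identical(b1$truth, b2$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeBundle(b1$dataset, d1, b1$truth)
  writeBundle(b2$dataset, d2, b2$truth)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("degenerate composition settings behave as configured", {
  p0 <- simulateProteome(smallSimConfig(seed = 2L, ptmSiteRate = 0))
  expect_identical(nrow(ptmSites(p0)), 0L)

  pK <- simulateProteome(simConfig(seed = 2L, nProteins = 3L,
                                   proteinLengthMean = 60,
                                   lysineFreq = 1, nDriverGenes = 1L,
                                   plantedModuleSize = 2L))
  expect_true(all(strsplit(as.character(proteins(pK)[[1L]]),
                           "")[[1L]] == "K"))

  cfg <- smallSimConfig(seed = 3L, nSamples = 0L)
  prot <- simulateProteome(cfg)
  tr <- simulateTruth(cfg, prot)
  coh <- simulateCohort(cfg, prot, tr)
  expect_identical(nrow(coh$mutations), 0L)

  cfg2 <- smallSimConfig(seed = 3L, hypermutatorFraction = 0)
  b <- simulateBundle(cfg2)
  expect_false(any(b$samples$hypermutator))
})

test_that("invalid configuration fields are refused by name", {
  expect_error(simConfig(lysineFreq = 1.5), "lysineFreq")
  expect_error(simConfig(plantedModuleSize = 1), "plantedModuleSize")
  expect_error(simConfig(moduleHazardRatio = 0), "moduleHazardRatio")
  expect_error(simConfig(nProteins = 5, plantedModuleSize = 8),
               "plantedModuleSize")
})

test_that("every simulated mutation matches its reference residue", {
  b <- simulateBundle(smallSimConfig(seed = 7L))
  mu <- mutationTable(b$dataset)
  chars <- lapply(as.character(proteins(b$dataset)), strsplit, "")
  ok <- vapply(seq_len(nrow(mu)), function(r)
    chars[[mu$protein_id[r]]][[1L]][mu$position[r]] == mu$ref_aa[r],
    logical(1L))
  expect_true(all(ok))
  expect_true(all(mu$ref_aa != mu$alt_aa))
})

test_that("burden mean and dispersion are recovered from the cohort", {
  cfg <- simConfig(seed = 11L, nProteins = 20L, proteinLengthMean = 120,
                   nSamples = 5000L, burdenMean = 20,
                   burdenDispersion = 2, hypermutatorFraction = 0)
  prot <- simulateProteome(cfg)
  tr <- simulateTruth(cfg, prot)
  coh <- simulateCohort(cfg, prot, tr)
  burden <- coh$samples$burden
  m <- mean(burden); v <- var(burden)
  sizeHat <- m^2 / (v - m)
  expect_lt(abs(m - 20) / 20, 0.1)
  expect_lt(abs(sizeHat - 2) / 2, 0.1)
})

test_that("unit planted enrichment leaves PTM regions at background rate", {
  cfg <- simConfig(seed = 13L, nProteins = 40L, proteinLengthMean = 300,
                   nSamples = 2000L, burdenMean = 60,
                   driverPtmEnrichment = 1, hypermutatorFraction = 0)
  prot <- simulateProteome(cfg)
  tr <- simulateTruth(cfg, prot)
  coh <- simulateCohort(cfg, prot, tr)
  expect_gt(nrow(coh$mutations), 1e5)
  lens <- proteinLengths(prot)
  inLen <- outLen <- nIn <- nOut <- 0
  for (id in names(lens)) {
    sp <- ptmSites(prot)$position[ptmSites(prot)$protein_id == id]
    mask <- bruteRegionMask(sp, lens[[id]])
    mp <- coh$mutations$position[coh$mutations$protein_id == id]
    inLen <- inLen + sum(mask); outLen <- outLen + sum(!mask)
    nIn <- nIn + sum(mask[mp]); nOut <- nOut + sum(!mask[mp])
  }
  fc <- (nIn / inLen) / (nOut / outLen)
  expect_lt(abs(fc - 1), 0.1)
})

test_that("network and survival honour the degenerate settings", {
  cfg <- smallSimConfig(seed = 17L, censoringRate = 0,
                        networkEdgeProb = 0)
  b <- simulateBundle(cfg)
  expect_true(all(survivalTable(b$dataset)$event == 1L))
  nw <- networkEdges(b$dataset)
  expect_identical(nrow(nw), cfg@plantedModuleSize - 1L)
  expect_true(all(c(nw$protein_a, nw$protein_b) %in%
                    b$truth$planted_module))
})

test_that("the planted module is connected in the simulated network", {
  skip_if_not_installed("igraph")
  for (seed in c(19L, 23L, 29L)) {
    b <- simulateBundle(smallSimConfig(seed = seed,
                                       plantedModuleSize = 6L))
    g <- igraph::graph_from_data_frame(networkEdges(b$dataset),
                                       directed = FALSE)
    sub <- igraph::induced_subgraph(g, b$truth$planted_module)
    expect_true(igraph::is_connected(sub))
  }
})

test_that("unit hazard ratio gives uniform log-rank p over replicates", {
  cfg0 <- smallSimConfig(seed = 1L, nSamples = 120L,
                         moduleHazardRatio = 1)
  prot <- simulateProteome(cfg0)
  tr <- simulateTruth(cfg0, prot)
  coh <- simulateCohort(cfg0, prot, tr)
  ps <- c()
  for (seed in 1:150) {
    cfg <- smallSimConfig(seed = seed, nSamples = 120L,
                          moduleHazardRatio = 1)
    ns <- simulateNetworkSurvival(cfg, prot, tr, coh)
    sv <- ns$survival
    carriers <- .carrierSamplesOracle(prot, tr, coh)
    grp <- sv$patient_id %in% carriers
    if (sum(grp) < 5L || sum(!grp) < 5L) next
    r <- logrankTest(sv$time, sv$event, grp)
    if (!is.na(r$p)) ps <- c(ps, r$p)
  }
  expect_gt(length(ps), 100L)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth referencing unknown proteins is a consistency error", {
  cfg <- smallSimConfig(seed = 5L)
  prot <- simulateProteome(cfg)
  tr <- simulateTruth(cfg, prot)
  tr$driver_genes <- c(tr$driver_genes, "NOT_A_PROTEIN")
  expect_error(simulateCohort(cfg, prot, tr), "unknown protein")
})
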