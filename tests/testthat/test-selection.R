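test_that("maximal statistic hits the add-one floor 1/(B+1)", {
  set.seed(1)
  ds <- siteDataset(c(P1 = 100L), list(P1 = 50L))
  mu <- do.call(rbind, lapply(1:20, function(i)
    mutRow("P1", sample(44:56, 1L), "A", "V",
           sample = sprintf("S%02d", i))))
  enr <- bootstrapRegionEnrichment(ds, "acetylation", 999L,
                                   mutations = mu)
  expect_equal(enr@pEmpirical, 1 / 1000)
  expect_identical(enr@observed, 20)
})

test_that("a protein that is entirely one region is not applicable", {
  ds <- siteDataset(c(P1 = 15L), list(P1 = 8L))  # window covers all
  enr <- bootstrapRegionEnrichment(ds, "acetylation", 100L,
                                   mutations = mutRow("P1", 2L, "A", "V"))
  expect_false(identical(enr@note, "ok"))
  expect_true(is.na(enr@pEmpirical))
})

test_that("empirical p never drops below the add-one floor", {
  set.seed(2)
  for (rep in 1:5) {
    prot <- simulateProteome(smallSimConfig(seed = rep))
    tr <- simulateTruth(smallSimConfig(seed = rep), prot)
    coh <- simulateCohort(smallSimConfig(seed = rep), prot, tr)
    B <- 50L
    enr <- bootstrapRegionEnrichment(prot, "any", B,
                                     mutations = coh$mutations)
    expect_gte(enr@pEmpirical, 1 / (B + 1))
    expect_lte(enr@pEmpirical, 1)
  }
})

test_that("central-lysine enrichment recovers planted rate ratios", {
  # one long protein, 200 lysines, the first 100 modified
  set.seed(3)
  kpos <- seq(10L, by = 10L, length.out = 200L)
  ds <- PTMDataset(c(P1 = kProtein(2010L, kpos)),
                   sites = data.frame(protein_id = "P1",
                                      position = kpos[1:100],
                                      acetylation = TRUE,
                                      ubiquitination = FALSE))
  draw <- function(wMod, n) {
    w <- rep(1, 200); w[1:100] <- wMod
    pos <- sample(kpos, n, replace = TRUE, prob = w)
    data.frame(sample_id = sprintf("S%06d", seq_len(n)),
               protein_id = "P1", position = pos, ref_aa = "K",
               alt_aa = "R", cancer_type = "LUAD")
  }
  eq <- centralLysineEnrichment(ds, "acetylation", 500L,
                                mutations = draw(1, 20000L))
  expect_lt(abs(eq@foldChange - 1), 0.1)
  dbl <- centralLysineEnrichment(ds, "acetylation", 500L,
                                 mutations = draw(2, 100000L))
  expect_lt(abs(dbl@foldChange - 2), 0.1)
  expect_lt(dbl@pEmpirical, 0.01)
})

test_that("all lysines modified makes the lysine contrast inapplicable", {
  ds <- siteDataset(c(P1 = 30L), list(P1 = c(10L, 20L)))
  # P1 has exactly two K residues, both modified
  enr <- centralLysineEnrichment(ds, "acetylation", 100L,
                                 mutations = mutRow("P1", 10L))
  expect_match(enr@note, "all lysines modified")
})

test_that("domains covering everything give fold change exactly 1", {
  ds0 <- siteDataset(c(P1 = 100L), list(P1 = 50L))
  ds <- PTMDataset(proteins(ds0), sites = ptmSites(ds0),
                   domains = data.frame(protein_id = "P1",
                                        domain_id = "d1", start = 1L,
                                        end = 100L))
  mu <- do.call(rbind, lapply(1:8, function(i)
    mutRow("P1", 42L + i, "A", "V", sample = sprintf("S%d", i))))
  ann <- classifyMutations(ds, mu)
  enr <- domainEnrichment(ds, ann, 200L)
  expect_identical(enr@foldChange, 1)
  expect_identical(enr@pEmpirical, 1)
})

test_that("constant conservation gives a null contrast of exactly one", {
  ds0 <- siteDataset(c(P1 = 100L), list(P1 = 50L))
  ds <- PTMDataset(proteins(ds0), sites = ptmSites(ds0),
                   disorder = list(P1 = rep(FALSE, 100L)),
                   conservation = list(P1 = rep(0.5, 100L)))
  mu <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      mutRow("P1", 45L + i, "A", "V", sample = sprintf("A%d", i)))),
    do.call(rbind, lapply(1:5, function(i)
      mutRow("P1", 10L + i, "A", "V", sample = sprintf("B%d", i)))))
  ann <- classifyMutations(ds, mu)
  res <- conservationContrast(ds, ann, 200L)
  expect_identical(res$structured@foldChange, 1)
  expect_identical(res$structured@pEmpirical, 1)
  expect_match(res$disordered@note, "fewer than 2")
})

test_that("a shifted conservation mean is detected reliably", {
  set.seed(4)
  hits <- 0L
  nRep <- 15L
  for (rep in seq_len(nRep)) {
    n <- 2000L
    isPtm <- rep(c(TRUE, FALSE), c(500L, 1500L))
    v <- ifelse(isPtm, rbeta(n, 5 * 0.55, 5 * 0.45),
                rbeta(n, 5 * 0.45, 5 * 0.55))
    # single protein; all mutations structured
    ds <- PTMDataset(
      c(P1 = kProtein(n + 10L, 5L)),
      sites = data.frame(protein_id = "P1", position = 5L,
                         acetylation = TRUE, ubiquitination = FALSE),
      disorder = list(P1 = rep(FALSE, n + 10L)),
      conservation = list(P1 = c(rep(0, 10L), round(v, 4))))
    ann <- data.frame(sample_id = sprintf("S%d", 1:n),
                      protein_id = "P1", position = 10L + seq_len(n),
                      ref_aa = "A", alt_aa = "V", cancer_type = "LUAD",
                      category = ifelse(isPtm, "distal", "none"))
    res <- conservationContrast(ds, ann, 200L)
    if (res$structured@pEmpirical < 0.05 &&
        res$structured@foldChange > 1) hits <- hits + 1L
  }
  expect_gte(hits / nRep, 0.9)
})

test_that("single-group cohorts are a degenerate-stratum error", {
  ds <- siteDataset(c(P1 = 100L), list(P1 = 50L))
  mu <- mutRow("P1", 50L)
  ann <- classifyMutations(ds, mu)
  expect_error(conservationContrast(ds, ann, 50L), "degenerate")
})

test_that("the [[5,0],[0,5]] consensus table gives p = 1/C(10,5)", {
  dat <- makeImpactData(5L, 0L, 0L, 5L)
  dummy <- siteDataset(c(PX = 20L), list(PX = 10L))
  res <- impactAssociation(dummy, dat$annotations, dat$predictors)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_true(res$continuity)

  # all scores equal: odds ratio treated as 1, p = 1
  same <- makeImpactData(5L, 5L, 0L, 0L)
  res2 <- impactAssociation(dummy, same$annotations, same$predictors)
  expect_identical(res2$odds_ratio, 1)
  expect_identical(res2$p, 1)
})

test_that("one-sided Fisher p matches full enumeration on small tables", {
  set.seed(5)
  dummy <- siteDataset(c(PX = 20L), list(PX = 10L))
  for (i in 1:40) {
    repeat {
      cells <- as.integer(rmultinom(1, sample(8:30, 1L), rep(1, 4)))
      if (all(cells[c(1, 4)] + cells[c(2, 3)] > 0) &&
          sum(cells[1:2]) > 0 && sum(cells[3:4]) > 0 &&
          sum(cells[c(1, 3)]) > 0 && sum(cells[c(2, 4)]) > 0) break
    }
    dat <- makeImpactData(cells[1], cells[2], cells[3], cells[4])
    res <- impactAssociation(dummy, dat$annotations, dat$predictors)
    expect_equal(res$p,
                 fisherEnumOracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("mutations without predictor calls are excluded and counted", {
  dat <- makeImpactData(3L, 3L, 3L, 3L)
  dummy <- siteDataset(c(PX = 20L), list(PX = 10L))
  pred <- dat$predictors[-1L, ]
  res <- impactAssociation(dummy, dat$annotations, pred)
  expect_identical(res$n_excluded, 1L)
  expect_identical(sum(res$table), 11L)
})

test_that("stronger planted enrichment raises FC and lowers p", {
  medFC <- medP <- numeric(0L)
  for (f in c(1, 1.8, 3)) {
    fcs <- ps <- numeric(0L)
    for (rep in 1:6) {
      cfg <- simConfig(seed = 100L + rep, nProteins = 25L,
                       proteinLengthMean = 250, nSamples = 150L,
                       burdenMean = 25, nDriverGenes = 15L,
                       driverPtmEnrichment = f,
                       hypermutatorFraction = 0,
                       plantedModuleSize = 5L)
      prot <- simulateProteome(cfg)
      tr <- simulateTruth(cfg, prot)
      coh <- simulateCohort(cfg, prot, tr)
      enr <- bootstrapRegionEnrichment(prot, "any", 400L,
                                       mutations = coh$mutations)
      fcs <- c(fcs, enr@foldChange)
      ps <- c(ps, enr@pEmpirical)
    }
    medFC <- c(medFC, median(fcs))
    medP <- c(medP, median(ps))
  }
  expect_true(all(diff(medFC) > 0))
  expect_true(all(diff(medP) <= 0))
})
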