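test_that("uniform-rate fallback matches the closed form E", {
  # constant disorder, 10 mutations, merged regions cover 20% of length
  ds0 <- siteDataset(c(P1 = 150L), list(P1 = c(20L, 60L)))
  ds <- PTMDataset(proteins(ds0), sites = ptmSites(ds0),
                   disorder = list(P1 = rep(FALSE, 150L)))
  mu <- do.call(rbind, lapply(1:10, function(i)
    mutRow("P1", 100L + i, "A", "V", sample = sprintf("S%d", i))))
  m <- fitGeneModel(ds, "P1", mu)
  expect_true(m$fallback)
  expect_equal(m$E, 2.0, tolerance = 1e-12)
  expect_identical(m$O, 0L)
  expect_identical(m$p, 1)
})

test_that("gene tail p equals term-by-term Poisson summation", {
  expect_equal(genePtmPvalue(3, 3), poisTailOracle(3, 3),
               tolerance = 1e-12)
  expect_lt(genePtmPvalue(10, 1), 1e-6)
  expect_identical(genePtmPvalue(0, 5), 1)
  set.seed(6)
  for (i in 1:50) {
    O <- sample(0:200, 1L)
    lam <- runif(1, 0.01, 100)
    expect_equal(genePtmPvalue(O, lam), poisTailOracle(O, lam),
                 tolerance = 1e-10)
  }
})

test_that("planted per-gene region enrichment is recovered as O/E", {
  set.seed(7)
  # one gene, modest region coverage, 3x planted rate inside regions
  ds0 <- siteDataset(c(P1 = 400L), list(P1 = c(50L, 200L)))
  ds <- PTMDataset(proteins(ds0), sites = ptmSites(ds0),
                   disorder = list(P1 = rep(c(FALSE, TRUE),
                                            each = 200L)))
  mask <- bruteRegionMask(c(50L, 200L), 400L)
  w <- ifelse(mask, 3, 1)
  ratios <- replicate(10, {
    pos <- sample(400L, 200L, replace = TRUE, prob = w)
    mu <- data.frame(sample_id = sprintf("S%d", 1:200),
                     protein_id = "P1", position = pos,
                     ref_aa = ifelse(mask[pos] & pos %in% c(50L, 200L),
                                     "K", "A"),
                     alt_aa = "V", cancer_type = "LUAD")
    mu$ref_aa <- vapply(mu$position, function(p)
      substr(as.character(proteins(ds)[["P1"]]), p, p), character(1L))
    mu <- mu[mu$ref_aa != "V", ]
    m <- fitGeneModel(ds, "P1", mu)
    m$O / m$E
  })
  expect_lt(abs(mean(ratios) - 3) / 3, 0.2)
})

test_that("driver scan orders genes and adjusts with BH", {
  b <- simulateBundle(smallSimConfig(seed = 31L))
  dr <- scanDriverGenes(b$dataset)
  expect_true(!is.unsorted(dr$p))
  expect_equal(dr$fdr, bhOracle(dr$p), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(dr$E > 0))
  expect_true(all(dr$O <= dr$n_mutations))
})

test_that("central-lysine mode ignores signal planted only in flanks", {
  set.seed(8)
  ds0 <- siteDataset(c(P1 = 300L), list(P1 = 150L))
  ds <- ds0
  # pile mutations on flanks 3-7 residues away, never on the lysine
  pos <- rep(c(143:147, 153:157), 6L)
  mu <- data.frame(sample_id = sprintf("S%d", seq_along(pos)),
                   protein_id = "P1", position = pos, ref_aa = "A",
                   alt_aa = "V", cancer_type = "LUAD")
  region <- fitGeneModel(ds, "P1", mu, mode = "region")
  central <- fitGeneModel(ds, "P1", mu, mode = "central")
  expect_lt(region$p, 1e-6)
  expect_identical(central$O, 0L)
  expect_identical(central$p, 1)
})

test_that("gene p values are conservative under a uniform null", {
  cfg <- simConfig(seed = 33L, nProteins = 120L, proteinLengthMean = 300,
                   nSamples = 150L, burdenMean = 15,
                   driverPtmEnrichment = 1, hypermutatorFraction = 0)
  b <- simulateBundle(cfg)
  dr <- scanDriverGenes(b$dataset)
  expect_gt(nrow(dr), 80L)
  for (alpha in c(0.05, 0.2)) {
    frac <- mean(dr$p < alpha)
    se <- sqrt(alpha * (1 - alpha) / nrow(dr))
    expect_lte(frac, alpha + 3 * se)
  }
})

test_that("hotspots respect the more-than-five boundary exactly", {
  ds <- siteDataset(c(P1 = 200L), list(P1 = c(50L, 120L)))
  regions <- mergeRegions(ds)
  mk <- function(pos, n, tag)
    do.call(rbind, lapply(seq_len(n), function(i)
      mutRow("P1", pos, "A", "V", sample = sprintf("%s%d", tag, i))))
  mu <- rbind(mk(48L, 5L, "A"), mk(118L, 6L, "B"))
  ann <- classifyMutations(ds, mu)
  hs <- findHotspots(ann, regions, minSnvs = 6L)
  expect_identical(nrow(hs), 1L)
  expect_identical(hs$n_snvs, 6L)
  expect_identical(hs$start, 113L)
  expect_false(hs$combinatorial)  # acetylation-only fixture
})

test_that("BH adjustment equals the from-definition oracle", {
  set.seed(9)
  for (n in c(10L, 317L, 10000L)) {
    p <- runif(n)^2
    expect_identical(p.adjust(p, "BH"), bhOracle(p))
  }
})

test_that("degenerate overlaps give permutation p of one", {
  counts <- setNames(rpois(60L, 10), sprintf("G%02d", 1:60))
  known <- names(counts)[1:6]
  allDet <- cancerGenePermutationTest(names(counts), known, counts,
                                      nBins = 10L, nPermutations = 500)
  expect_identical(allDet$empirical_p, 1)
  expect_identical(allDet$observed_overlap, 6L)
  disj <- cancerGenePermutationTest(names(counts)[7:12], known, counts,
                                    nBins = 10L, nPermutations = 500)
  expect_identical(disj$observed_overlap, 0L)
  expect_identical(disj$empirical_p, 1)
})

test_that("single-bin permutation test agrees with the hypergeometric", {
  set.seed(10)
  counts <- setNames(rep(5L, 100L), sprintf("G%03d", 1:100))
  known <- sprintf("G%03d", 1:10)
  detected <- sprintf("G%03d", 6:25)  # overlap 5
  B <- 40000
  res <- cancerGenePermutationTest(detected, known, counts,
                                   nBins = 1L, nPermutations = B)
  exact <- phyper(res$observed_overlap - 1L, 20, 80, 10,
                  lower.tail = FALSE)
  se <- sqrt(exact * (1 - exact) / B)
  expect_lt(abs(res$empirical_p - exact), 4 * se + 2 / B)

  # detected containing every known gene, small detected set
  res2 <- cancerGenePermutationTest(sprintf("G%03d", 1:10), known,
                                    counts, nBins = 1L,
                                    nPermutations = 1e4)
  expect_lte(res2$empirical_p, 1e-2)
})

test_that("a gene outside the universe is rejected", {
  counts <- setNames(1:5, sprintf("G%d", 1:5))
  expect_error(cancerGenePermutationTest("G1", "NOPE", counts),
               "subset")
})
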