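test_that("mutation categories partition offsets as defined", {
  # single site at 21 in a length-41 protein; walk offsets -10..+10
  ds <- siteDataset(c(P1 = 41L), list(P1 = 21L))
  for (off in -10:10) {
    pos <- 21L + off
    ref <- if (pos == 21L) "K" else "A"
    alt <- if (ref == "K") "R" else "V"
    ann <- classifyMutations(ds, mutRow("P1", pos, ref, alt))
    want <- if (off == 0L) "direct"
      else if (abs(off) %in% 1:2) "proximal"
      else if (abs(off) %in% 3:7) "distal"
      else "none"
    expect_identical(ann$category, want, label = sprintf("offset %d", off))
    if (abs(off) <= 7)
      expect_identical(ann$nearest_site, 21L)
  }
})

test_that("region merging matches the worked interval examples", {
  ds <- siteDataset(c(P1 = 100L), list(P1 = c(10L, 20L)))
  r <- mergeRegions(ds)
  expect_identical(r$start, 3L)
  expect_identical(r$end, 27L)
  expect_identical(r$n_sites, 2L)

  ds2 <- siteDataset(c(P1 = 100L), list(P1 = 5L))
  r2 <- mergeRegions(ds2)
  expect_identical(c(r2$start, r2$end), c(1L, 12L))

  ds3 <- siteDataset(c(P1 = 100L), list(P1 = c(10L, 30L)))
  r3 <- mergeRegions(ds3)
  expect_identical(r3$start, c(3L, 23L))
  expect_identical(r3$end, c(17L, 37L))
})

test_that("region membership equals the brute-force marking oracle", {
  for (seed in c(3L, 9L)) {
    prot <- simulateProteome(smallSimConfig(seed = seed))
    regions <- mergeRegions(prot)
    lens <- proteinLengths(prot)
    for (id in names(lens)) {
      sp <- ptmSites(prot)$position[ptmSites(prot)$protein_id == id]
      oracle <- bruteRegionMask(sp, lens[[id]])
      sub <- regions[regions$protein_id == id, ]
      mask <- logical(lens[[id]])
      for (r in seq_len(nrow(sub)))
        mask[sub$start[r]:sub$end[r]] <- TRUE
      expect_identical(mask, oracle, label = id)
    }
  }
})

test_that("merging the member sites of a region reproduces it", {
  prot <- simulateProteome(smallSimConfig(seed = 4L))
  regions <- mergeRegions(prot)
  st <- ptmSites(prot)
  for (r in seq_len(nrow(regions))) {
    mem <- st$position[st$protein_id == regions$protein_id[r] &
                         st$position >= regions$start[r] &
                         st$position <= regions$end[r]]
    len <- proteinLengths(prot)[[regions$protein_id[r]]]
    expect_identical(max(1L, min(mem) - 7L), regions$start[r])
    expect_identical(min(len, max(mem) + 7L), regions$end[r])
  }
})

test_that("15-mer mapping finds every exact occurrence and only those", {
  mer <- "AAAAAAAKAAAAAAA"
  ds <- PTMDataset(c(P1 = paste0(mer, "CCCCC", mer),
                     P2 = "AAAAAAAKAAAAAAC"))
  rec <- data.frame(protein_id = "P1", ptm_type = "acetylation",
                    fifteen_mer = mer)
  m <- mapSites(rec, ds)
  expect_identical(m$sites$position, c(8L, 28L))  # two matches, two sites

  # one mismatch to the proteome: no site
  m2 <- mapSites(data.frame(protein_id = "P2",
                            ptm_type = "ubiquitination",
                            fifteen_mer = mer), ds)
  expect_identical(nrow(m2$sites), 0L)
  expect_identical(unname(m2$rejected[["no_match"]]), 1L)

  # central residue not K: rejected and counted
  m3 <- mapSites(data.frame(protein_id = "P1", ptm_type = "acetylation",
                            fifteen_mer = "AAAAAAARAAAAAAA"), ds)
  expect_identical(unname(m3$rejected[["bad_central"]]), 1L)
})

test_that("padded 15-mers match only at the protein termini", {
  ds <- PTMDataset(c(P1 = "ABKDEFGHIJABKDEFGHIJ"))
  # K at position 3: window -4..10 needs 5 leading pads
  mer <- paste0("_____", "ABKDEFGHIJ")
  m <- mapSites(data.frame(protein_id = "P1", ptm_type = "acetylation",
                           fifteen_mer = mer), ds)
  # core also occurs at position 11, but the padded pattern is anchored
  expect_identical(m$sites$position, 3L)

  dsR <- PTMDataset(c(P2 = "AAAAAAAAAAAAAAAAAAAK"))
  merR <- paste0("AAAAAAAK", "_______")
  mR <- mapSites(data.frame(protein_id = "P2", ptm_type = "acetylation",
                            fifteen_mer = merR), dsR)
  expect_identical(mR$sites$position, 20L)
})

test_that("position-resolved records validate and types are unioned", {
  ds <- PTMDataset(c(P1 = kProtein(30L, c(10L, 20L))))
  rec <- data.frame(protein_id = "P1",
                    ptm_type = c("acetylation", "ubiquitination",
                                 "acetylation"),
                    position = c(10L, 10L, 15L))
  m <- mapSites(rec, ds)
  expect_identical(nrow(m$sites), 1L)
  expect_true(m$sites$acetylation && m$sites$ubiquitination)
  expect_identical(unname(m$rejected[["bad_position"]]), 1L)  # 15 not K
})

test_that("equidistant flanking sites union their PTM types", {
  ds <- PTMDataset(c(P1 = kProtein(40L, c(10L, 14L))),
                   sites = data.frame(
                     protein_id = "P1", position = c(10L, 14L),
                     acetylation = c(TRUE, FALSE),
                     ubiquitination = c(FALSE, TRUE)))
  ann <- classifyMutations(ds, mutRow("P1", 12L, "A", "V"))
  expect_identical(ann$category, "proximal")
  expect_true(ann$site_acetylation && ann$site_ubiquitination)
  expect_false(is.na(ann$region_id))
})

test_that("hypermutator filtering follows the MAD rule exactly", {
  base <- do.call(rbind, lapply(1:10, function(i)
    mutRow("P1", i, "A", "V", sample = sprintf("S%02d", i))))
  ds <- NULL  # filter works on the table alone
  eq <- filterHypermutators(base, rule = "mad")
  expect_identical(nrow(eq$removed), 0L)

  heavy <- do.call(rbind, lapply(1:100, function(i)
    mutRow("P1", (i %% 20) + 1, "A", "V", sample = "HYPER")))
  tab <- rbind(base, heavy)
  # oracle: direct evaluation of the rule on log10 burdens
  burden <- table(tab$sample_id)
  lb <- log10(as.numeric(burden))
  flagged <- names(burden)[lb > median(lb) + 3 * mad(lb)]
  expect_identical(flagged, "HYPER")
  f <- filterHypermutators(tab, rule = "mad")
  expect_identical(f$removed$sample_id, "HYPER")
  expect_false("HYPER" %in% f$mutations$sample_id)
  expect_identical(nrow(f$mutations), 10L)

  untouched <- filterHypermutators(tab, rule = "none")
  expect_identical(untouched$mutations, tab)
})
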