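#' Simulate a synthetic proteome with PTM sites and per-residue tracks
#'
#' Draws protein sequences with a configurable lysine frequency, marks a
#' fraction of lysines as acetylation and/or ubiquitination sites,
#' generates a two-state disorder mask with geometric segment lengths,
#' Beta-distributed conservation scores whose mean is shifted upward
#' inside merged PTM-site regions, and random domain intervals. Among
#' exclusive sites, ubiquitination outnumbers acetylation about 4:1,
#' mirroring the composition of public lysine-PTM compendia.
#'
#' The proteome is a deterministic function of the configuration: the
#' same `config` (including its seed) always yields an identical object.
#'
#' @param config a [SimulationConfig-class].
#' @return a [PTMDataset-class] carrying proteins, sites, disorder,
#'   conservation and domain annotations (no cohort yet).
#' @examples
#' prot <- simulateProteome(simConfig(seed = 3, nProteins = 10))
#' @export
simulateProteome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nProteins
  ids <- sprintf("P%04d", seq_len(n))
  lens <- pmax(30L, as.integer(round(
    rgamma(n, shape = 4, scale = config@proteinLengthMean / 4))))

  other <- setdiff(.AA20, "K")
  seqs <- character(n)
  siteRows <- vector("list", n)
  disorder <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]
    isK <- runif(L) < config@lysineFreq
    s <- sample(other, L, replace = TRUE)
    s[isK] <- "K"
    seqs[i] <- paste(s, collapse = "")
    kpos <- which(isK)
    hasSite <- kpos[runif(length(kpos)) < config@ptmSiteRate]
    if (length(hasSite)) {
      shared <- runif(length(hasSite)) < config@sharedSiteRate
      # exclusive sites: acetylation with probability 0.2
      acOnly <- runif(length(hasSite)) < 0.2
      siteRows[[i]] <- data.frame(
        protein_id = ids[i], position = hasSite,
        acetylation = shared | acOnly,
        ubiquitination = shared | !acOnly)
    }
    disorder[[i]] <- .simDisorderTrack(L, config@disorderSegmentRate)
  }
  names(disorder) <- ids
  sites <- if (any(!vapply(siteRows, is.null, logical(1L))))
    do.call(rbind, siteRows) else emptySites()
  rownames(sites) <- NULL

  # conservation: Beta with concentration 5; mean 0.45 outside regions,
  # shifted up inside merged PTM regions so contrasts are recoverable
  lensNamed <- setNames(lens, ids)
  regions <- .regionRangesList(split(sites$position, sites$protein_id),
                               lensNamed, 7L)
  conservation <- vector("list", n)
  names(conservation) <- ids
  conc <- 5
  mOut <- 0.45
  mIn <- min(0.95, mOut + config@conservationShift)
  for (i in seq_len(n)) {
    L <- lens[i]
    cs <- rbeta(L, conc * mOut, conc * (1 - mOut))
    ir <- regions[[ids[i]]]
    if (!is.null(ir) && length(ir)) {
      idx <- unlist(lapply(seq_along(ir), function(j)
        IRanges::start(ir)[j]:IRanges::end(ir)[j]))
      cs[idx] <- rbeta(length(idx), conc * mIn, conc * (1 - mIn))
    }
    conservation[[i]] <- round(cs, 4)  # track resolution 1e-4
  }

  domRows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- rpois(1L, 1)
    if (k > 0L && lens[i] > 60L) {
      dl <- pmin(sample(40:120, k, replace = TRUE), lens[i] - 1L)
      st <- vapply(dl, function(d) sample.int(lens[i] - d, 1L), integer(1L))
      domRows[[i]] <- data.frame(
        protein_id = ids[i],
        domain_id = sprintf("%s_dom%d", ids[i], seq_len(k)),
        start = st, end = st + dl)
    }
  }
  domains <- if (any(!vapply(domRows, is.null, logical(1L))))
    do.call(rbind, domRows) else emptyDomains()
  rownames(domains) <- NULL

  PTMDataset(proteins = Biostrings::AAStringSet(setNames(seqs, ids)),
             sites = sites, disorder = disorder,
             conservation = conservation, domains = domains)
}

# two-state Markov chain over segments; mean disordered segment 20
.simDisorderTrack <- function(L, rho) {
  if (rho <= 0) return(rep(FALSE, L))
  if (rho >= 1) return(rep(TRUE, L))
  meanDis <- 20
  meanOrd <- meanDis * (1 - rho) / rho
  out <- logical(0L)
  state <- runif(1L) < rho
  while (length(out) < L) {
    m <- if (state) meanDis else meanOrd
    seg <- 1L + rgeom(1L, 1 / m)
    out <- c(out, rep(state, seg))
    state <- !state
  }
  out[seq_len(L)]
}

#' Choose planted ground truth for a simulated proteome
#'
#' Samples the driver genes and the planted survival module among
#' PTM-bearing proteins and records the planted effect sizes.
#'
#' @param config a [SimulationConfig-class].
#' @param proteome output of [simulateProteome()].
#' @return a list with elements `driver_genes`, `planted_module`,
#'   `planted_enrichment` and `planted_hazard_ratio`.
#' @export
simulateTruth <- function(config, proteome) {
  set.seed(config@seed + 7L)
  bearing <- .ptmBearingProteins(proteome)
  if (length(bearing) < max(config@nDriverGenes, config@plantedModuleSize))
    stop("not enough PTM-bearing proteins to plant drivers and module; ",
         "increase 'nProteins' or 'ptmSiteRate'")
  drivers <- sort(sample(bearing, config@nDriverGenes))
  # survival modules are made of recurrently mutated proteins: draw the
  # planted module from the driver set whenever it is large enough
  module <- if (config@nDriverGenes >= config@plantedModuleSize)
    sort(sample(drivers, config@plantedModuleSize))
  else sort(sample(bearing, config@plantedModuleSize))
  list(driver_genes = drivers, planted_module = module,
       planted_enrichment = config@driverPtmEnrichment,
       planted_hazard_ratio = config@moduleHazardRatio)
}

.checkTruth <- function(truth, proteome) {
  ids <- names(proteins(proteome))
  unknown <- setdiff(c(truth$driver_genes, truth$planted_module), ids)
  if (length(unknown))
    stop("truth references unknown protein(s): ",
         paste(head(unknown, 3L), collapse = ", "))
}

#' Simulate a tumour mutation cohort
#'
#' Per-sample mutation burden is negative binomial
#' (`mu = burdenMean`, `size = burdenDispersion`); a `hypermutatorFraction`
#' of samples has its burden multiplied by `hypermutatorMultiplier`.
#' Each mutation picks a protein with probability proportional to its
#' placement weight (sequence length, with merged-PTM-region residues of
#' driver genes up-weighted by `driverPtmEnrichment`), then a residue
#' uniformly within the chosen compartment, so the per-residue rate in
#' driver PTM regions is exactly the planted fold above background. The
#' reference amino acid is read off the sequence and the alternate is
#' drawn uniformly from the 19 others, so only missense substitutions
#' are emitted. Each mutation also receives independent boolean
#' deleteriousness calls from `nPredictors` simulated predictors, with a
#' higher per-call probability inside PTM regions.
#'
#' @param config a [SimulationConfig-class].
#' @param proteome output of [simulateProteome()].
#' @param truth output of [simulateTruth()].
#' @return list with `mutations`, `predictors` and a `samples` roster
#'   (sample id, cancer type, hypermutator flag, burden).
#' @export
simulateCohort <- function(config, proteome, truth) {
  if (length(proteins(proteome)) == 0L) stop("proteome is empty")
  .checkTruth(truth, proteome)
  set.seed(config@seed + 1L)

  ids <- names(proteins(proteome))
  lens <- proteinLengths(proteome)
  chars <- .seqChars(proteins(proteome))
  regions <- .regionRangesList(
    split(proteome@sites$position, proteome@sites$protein_id), lens, 7L)

  inLen <- setNames(numeric(length(ids)), ids)
  inPos <- setNames(vector("list", length(ids)), ids)
  for (id in names(regions)) {
    ir <- regions[[id]]
    inLen[[id]] <- sum(IRanges::end(ir) - IRanges::start(ir) + 1L)
    inPos[[id]] <- unlist(lapply(seq_along(ir), function(j)
      IRanges::start(ir)[j]:IRanges::end(ir)[j]))
  }
  f <- ifelse(ids %in% truth$driver_genes, config@driverPtmEnrichment, 1)
  outLen <- lens - inLen
  w <- outLen + f * inLen

  nS <- config@nSamples
  if (nS == 0L) {
    return(list(mutations = emptyMutations(),
                predictors = data.frame(),
                samples = data.frame(sample_id = character(),
                                     cancer_type = character(),
                                     hypermutator = logical(),
                                     burden = integer())))
  }
  sampleIds <- sprintf("S%05d", seq_len(nS))
  ctype <- sample(config@cancerTypes, nS, replace = TRUE)
  burden <- rnbinom(nS, size = config@burdenDispersion,
                    mu = config@burdenMean)
  hyper <- runif(nS) < config@hypermutatorFraction
  burden[hyper] <- as.integer(round(
    burden[hyper] * config@hypermutatorMultiplier))
  samples <- data.frame(sample_id = sampleIds, cancer_type = ctype,
                        hypermutator = hyper, burden = burden)

  M <- sum(burden)
  if (M == 0L) {
    return(list(mutations = emptyMutations(), predictors = data.frame(),
                samples = samples))
  }
  mutSample <- rep(sampleIds, burden)
  mutType <- rep(ctype, burden)
  prot <- sample(ids, M, replace = TRUE, prob = w)

  pos <- integer(M)
  inRegion <- logical(M)
  bySplit <- split(seq_len(M), prot)
  for (id in names(bySplit)) {
    idx <- bySplit[[id]]
    m <- length(idx)
    pIn <- f[match(id, ids)] * inLen[[id]] /
      (f[match(id, ids)] * inLen[[id]] + outLen[[id]])
    isIn <- runif(m) < pIn
    if (any(isIn))
      pos[idx[isIn]] <- inPos[[id]][sample.int(length(inPos[[id]]),
                                               sum(isIn), replace = TRUE)]
    if (any(!isIn)) {
      outPos <- setdiff(seq_len(lens[[id]]), inPos[[id]])
      pos[idx[!isIn]] <- outPos[sample.int(length(outPos), sum(!isIn),
                                           replace = TRUE)]
    }
    inRegion[idx] <- isIn
  }
  ref <- character(M)
  for (id in names(bySplit)) {
    idx <- bySplit[[id]]
    ref[idx] <- chars[[id]][pos[idx]]
  }
  altPick <- sample.int(19L, M, replace = TRUE)
  refIdx <- match(ref, .AA20)
  alt <- .AA20[ifelse(altPick < refIdx, altPick, altPick + 1L)]

  mutations <- data.frame(sample_id = mutSample, protein_id = prot,
                          position = pos, ref_aa = ref, alt_aa = alt,
                          cancer_type = mutType)

  pDel <- ifelse(inRegion, config@deleteriousProbPtm,
                 config@deleteriousProbBackground)
  calls <- matrix(runif(M * config@nPredictors) <
                    rep(pDel, config@nPredictors),
                  nrow = M)
  colnames(calls) <- sprintf("pred_%d", seq_len(config@nPredictors))
  predictors <- cbind(mutations[, c("sample_id", "protein_id", "position")],
                      as.data.frame(calls))

  list(mutations = mutations, predictors = predictors, samples = samples)
}

#' Simulate an interaction network and patient survival
#'
#' Background edges are Erdos-Renyi with probability `networkEdgeProb`,
#' restricted to pairs touching at least one PTM-bearing protein (edges
#' between two unmodified proteins are discarded, as in a PTM-centric
#' interaction network). The planted module is wired as a random
#' spanning tree over its members, so it is always connected. Event
#' times are exponential with rate `baselineHazard`, multiplied by
#' `moduleHazardRatio` for patients carrying at least one mutation in a
#' merged PTM region of a planted-module gene; a `censoringRate`
#' fraction of records is right-censored uniformly before the event.
#'
#' @param config a [SimulationConfig-class].
#' @param proteome output of [simulateProteome()].
#' @param truth output of [simulateTruth()].
#' @param cohort output of [simulateCohort()]; carrier status is read
#'   from its mutation table.
#' @return list with `network` (edge data.frame) and `survival`.
#' @export
simulateNetworkSurvival <- function(config, proteome, truth, cohort) {
  .checkTruth(truth, proteome)
  if (config@plantedModuleSize < 2L)
    stop("'plantedModuleSize' must be >= 2")
  set.seed(config@seed + 2L)

  ids <- names(proteins(proteome))
  n <- length(ids)
  bearing <- .ptmBearingProteins(proteome)

  nPairs <- n * (n - 1) / 2
  m <- rbinom(1L, nPairs, config@networkEdgeProb)
  edges <- NULL
  if (m > 0L) {
    k <- sort(sample(nPairs, m))
    # unrank upper-triangle pair index (row-major over i < j)
    i <- as.integer(ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * k)))
    off <- (i - 1) * n - i * (i + 1) / 2
    j <- as.integer(k - off)
    edges <- data.frame(protein_a = ids[i], protein_b = ids[j])
    keep <- edges$protein_a %in% bearing | edges$protein_b %in% bearing
    edges <- edges[keep, , drop = FALSE]
  }
  mod <- sample(truth$planted_module)  # random spanning tree
  tree <- data.frame(
    protein_a = mod[vapply(seq_along(mod)[-1L],
                           function(k) sample(k - 1L, 1L), integer(1L))],
    protein_b = mod[-1L])
  edges <- rbind(edges, tree)
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  edges <- unique(data.frame(protein_a = a, protein_b = b))
  rownames(edges) <- NULL

  samples <- cohort$samples
  if (nrow(samples) == 0L)
    return(list(network = edges, survival = emptySurvival()))

  lens <- proteinLengths(proteome)
  regions <- .regionRangesList(
    split(proteome@sites$position, proteome@sites$protein_id), lens, 7L)
  mu <- cohort$mutations
  carrierSamples <- character(0L)
  if (nrow(mu)) {
    inMod <- mu$protein_id %in% truth$planted_module
    if (any(inMod)) {
      sub <- mu[inMod, , drop = FALSE]
      hit <- vapply(seq_len(nrow(sub)), function(r)
        .inRanges(sub$position[r], regions[[sub$protein_id[r]]]),
        logical(1L))
      carrierSamples <- unique(sub$sample_id[hit])
    }
  }
  carrier <- samples$sample_id %in% carrierSamples
  rate <- config@baselineHazard *
    ifelse(carrier, config@moduleHazardRatio, 1)
  tEvent <- rexp(nrow(samples), rate)
  event <- as.integer(runif(nrow(samples)) >= config@censoringRate)
  time <- ifelse(event == 1L, tEvent, tEvent * runif(nrow(samples)))
  time <- round(pmax(time, 1e-4), 4)  # day resolution 1e-4
  survival <- data.frame(patient_id = samples$sample_id, time = time,
                         event = event,
                         cancer_type = samples$cancer_type)
  list(network = edges, survival = survival)
}

#' Simulate gene sets for pathway analysis
#'
#' The first set is the planted driver-gene set; the remaining
#' `nGeneSets - 1` sets draw members uniformly from PTM-bearing
#' proteins with sizes uniform in the configured range.
#'
#' @inheritParams simulateNetworkSurvival
#' @return named list of member-id vectors.
#' @export
simulateGeneSets <- function(config, proteome, truth) {
  set.seed(config@seed + 3L)
  bearing <- .ptmBearingProteins(proteome)
  sets <- vector("list", config@nGeneSets)
  sets[[1L]] <- truth$driver_genes
  if (config@nGeneSets > 1L) {
    for (k in 2:config@nGeneSets) {
      sz <- min(sample(config@geneSetSizeMin:config@geneSetSizeMax, 1L),
                length(bearing))
      sets[[k]] <- sort(sample(bearing, sz))
    }
  }
  names(sets) <- c("GS_PLANTED",
                   sprintf("GS%04d", seq_len(config@nGeneSets))[-1L])
  sets
}

#' Simulate a complete analysis bundle with planted ground truth
#'
#' Chains [simulateProteome()], [simulateTruth()], [simulateCohort()],
#' [simulateNetworkSurvival()] and [simulateGeneSets()] into one
#' [PTMDataset-class]. Identical configurations give byte-identical
#' bundles when written with [writeBundle()].
#'
#' @param config a [SimulationConfig-class].
#' @return list with `dataset` (a PTMDataset) and `truth`.
#' @examples
#' b <- simulateBundle(simConfig(seed = 11, nProteins = 15, nSamples = 40))
#' b$dataset
#' @export
simulateBundle <- function(config) {
  proteome <- simulateProteome(config)
  truth <- simulateTruth(config, proteome)
  cohort <- simulateCohort(config, proteome, truth)
  ns <- simulateNetworkSurvival(config, proteome, truth, cohort)
  gs <- simulateGeneSets(config, proteome, truth)
  dataset <- PTMDataset(
    proteins = proteins(proteome), sites = ptmSites(proteome),
    mutations = cohort$mutations, disorder = disorderTracks(proteome),
    conservation = conservationTracks(proteome),
    domains = domainTable(proteome), predictors = cohort$predictors,
    network = ns$network, survival = ns$survival, geneSets = gs)
  list(dataset = dataset, truth = truth, samples = cohort$samples)
}
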