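#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom IRanges IRanges reduce start end
#' @importFrom stats rnbinom rbinom rexp rbeta runif rhyper rgamma rpois
#'   rgeom ppois dpois pchisq p.adjust fisher.test glm poisson coef mad
#'   median quantile setNames
#' @importFrom utils read.delim write.table head
NULL

.PROB_FIELDS <- c("lysineFreq", "ptmSiteRate", "sharedSiteRate",
                  "disorderSegmentRate", "hypermutatorFraction",
                  "networkEdgeProb", "censoringRate",
                  "deleteriousProbPtm", "deleteriousProbBackground")

#' Simulation configuration
#'
#' Parameters of the synthetic proteome / tumour-cohort generator. All
#' downstream stages of the package can be exercised on the bundle these
#' parameters describe: lysine-bearing proteins with acetylation and
#' ubiquitination sites, a tumour cohort with negative-binomial mutation
#' burden and a hypermutator tail, driver genes with fold-enriched
#' mutation rates inside merged PTM-site regions, a sparse interaction
#' network carrying a planted connected module, and exponential survival
#' times in which carriers of module mutations have a multiplied hazard.
#'
#' @slot seed integer RNG seed; the whole bundle is a deterministic
#'   function of the configuration including this seed.
#' @slot nProteins number of proteins.
#' @slot proteinLengthMean mean protein length in residues (lengths are
#'   drawn around this mean, minimum 30).
#' @slot lysineFreq probability that a residue is lysine.
#' @slot ptmSiteRate probability that a lysine carries a PTM site.
#' @slot sharedSiteRate probability a site carries both PTM types.
#' @slot disorderSegmentRate stationary fraction of disordered sequence.
#' @slot conservationShift upward shift of mean conservation inside PTM
#'   regions (scores stay in \[0,1\]).
#' @slot nSamples number of tumour samples.
#' @slot burdenMean mean mutations per sample (negative binomial).
#' @slot burdenDispersion negative-binomial size parameter.
#' @slot hypermutatorFraction probability a sample is a hypermutator.
#' @slot hypermutatorMultiplier burden fold multiplier for hypermutators.
#' @slot nDriverGenes number of planted driver genes.
#' @slot driverPtmEnrichment fold change of the per-residue mutation rate
#'   inside PTM regions of driver genes (1 = null).
#' @slot networkEdgeProb background edge probability of the interaction
#'   network.
#' @slot plantedModuleSize size of the planted survival module (>= 2).
#' @slot moduleHazardRatio event-hazard multiplier for patients carrying
#'   PTM-region mutations in planted-module genes.
#' @slot censoringRate probability a patient record is right-censored.
#' @slot baselineHazard baseline exponential event rate per day.
#' @slot deleteriousProbPtm,deleteriousProbBackground per-predictor
#'   probability of a deleterious call for PTM-region / background
#'   mutations.
#' @slot nPredictors number of boolean variant-impact predictors.
#' @slot nGeneSets number of gene sets written to the bundle (the first
#'   one is the planted set of driver genes).
#' @slot geneSetSizeMin,geneSetSizeMax size range of null gene sets.
#' @slot cancerTypes labels sampled uniformly per tumour sample.
#' @seealso [simConfig()], [simulateBundle()]
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nProteins = "integer", proteinLengthMean = "numeric",
    lysineFreq = "numeric", ptmSiteRate = "numeric",
    sharedSiteRate = "numeric", disorderSegmentRate = "numeric",
    conservationShift = "numeric",
    nSamples = "integer", burdenMean = "numeric",
    burdenDispersion = "numeric", hypermutatorFraction = "numeric",
    hypermutatorMultiplier = "numeric",
    nDriverGenes = "integer", driverPtmEnrichment = "numeric",
    networkEdgeProb = "numeric", plantedModuleSize = "integer",
    moduleHazardRatio = "numeric", censoringRate = "numeric",
    baselineHazard = "numeric",
    deleteriousProbPtm = "numeric", deleteriousProbBackground = "numeric",
    nPredictors = "integer",
    nGeneSets = "integer", geneSetSizeMin = "integer",
    geneSetSizeMax = "integer", cancerTypes = "character"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  for (f in .PROB_FIELDS) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msgs <- c(msgs, sprintf("'%s' must be a probability in [0, 1]", f))
  }
  chkPos <- function(f, min = 0) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || v < min)
      msgs <<- c(msgs, sprintf("'%s' must be >= %g", f, min))
  }
  chkPos("nProteins", 1); chkPos("proteinLengthMean", 30)
  chkPos("nSamples", 0); chkPos("burdenMean", 0)
  chkPos("burdenDispersion", 1e-8)
  chkPos("hypermutatorMultiplier", 1)
  chkPos("nDriverGenes", 1); chkPos("driverPtmEnrichment", 1e-8)
  chkPos("plantedModuleSize", 2)
  chkPos("moduleHazardRatio", 1e-8)
  chkPos("baselineHazard", 1e-12)
  chkPos("nPredictors", 1); chkPos("nGeneSets", 1)
  chkPos("geneSetSizeMin", 1)
  if (object@geneSetSizeMax < object@geneSetSizeMin)
    msgs <- c(msgs, "'geneSetSizeMax' must be >= 'geneSetSizeMin'")
  if (object@conservationShift < 0 || object@conservationShift > 0.5)
    msgs <- c(msgs, "'conservationShift' must be in [0, 0.5]")
  if (object@nDriverGenes > object@nProteins)
    msgs <- c(msgs, "'nDriverGenes' must be <= 'nProteins'")
  if (object@plantedModuleSize > object@nProteins)
    msgs <- c(msgs, "'plantedModuleSize' must be <= 'nProteins'")
  if (length(object@cancerTypes) < 1L)
    msgs <- c(msgs, "'cancerTypes' must name at least one type")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Build a simulation configuration
#'
#' @param seed integer RNG seed.
#' @param nProteins,proteinLengthMean,lysineFreq,ptmSiteRate,sharedSiteRate
#'   proteome parameters; see [SimulationConfig-class].
#' @param disorderSegmentRate,conservationShift per-residue track
#'   parameters.
#' @param nSamples,burdenMean,burdenDispersion,hypermutatorFraction,hypermutatorMultiplier
#'   cohort burden parameters.
#' @param nDriverGenes,driverPtmEnrichment planted driver signal.
#' @param networkEdgeProb,plantedModuleSize,moduleHazardRatio,censoringRate,baselineHazard
#'   network and survival parameters.
#' @param deleteriousProbPtm,deleteriousProbBackground,nPredictors
#'   predictor-call parameters.
#' @param nGeneSets,geneSetSizeMin,geneSetSizeMax,cancerTypes bundle
#'   extras.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 7, nProteins = 20, nSamples = 30)
#' @export
simConfig <- function(seed = 1L,
                      nProteins = 100L, proteinLengthMean = 400,
                      lysineFreq = 0.06, ptmSiteRate = 0.25,
                      sharedSiteRate = 0.11, disorderSegmentRate = 0.3,
                      conservationShift = 0.15,
                      nSamples = 200L, burdenMean = 20,
                      burdenDispersion = 2, hypermutatorFraction = 0.03,
                      hypermutatorMultiplier = 20,
                      nDriverGenes = 5L, driverPtmEnrichment = 3,
                      networkEdgeProb = 0.05, plantedModuleSize = 8L,
                      moduleHazardRatio = 3, censoringRate = 0.3,
                      baselineHazard = 1 / 1000,
                      deleteriousProbPtm = 0.4,
                      deleteriousProbBackground = 0.2,
                      nPredictors = 5L,
                      nGeneSets = 50L, geneSetSizeMin = 5L,
                      geneSetSizeMax = 30L,
                      cancerTypes = c("LUAD", "BRCA", "GBM")) {
  new("SimulationConfig",
      seed = as.integer(seed),
      nProteins = as.integer(nProteins),
      proteinLengthMean = as.numeric(proteinLengthMean),
      lysineFreq = lysineFreq, ptmSiteRate = ptmSiteRate,
      sharedSiteRate = sharedSiteRate,
      disorderSegmentRate = disorderSegmentRate,
      conservationShift = conservationShift,
      nSamples = as.integer(nSamples), burdenMean = burdenMean,
      burdenDispersion = burdenDispersion,
      hypermutatorFraction = hypermutatorFraction,
      hypermutatorMultiplier = hypermutatorMultiplier,
      nDriverGenes = as.integer(nDriverGenes),
      driverPtmEnrichment = driverPtmEnrichment,
      networkEdgeProb = networkEdgeProb,
      plantedModuleSize = as.integer(plantedModuleSize),
      moduleHazardRatio = moduleHazardRatio,
      censoringRate = censoringRate, baselineHazard = baselineHazard,
      deleteriousProbPtm = deleteriousProbPtm,
      deleteriousProbBackground = deleteriousProbBackground,
      nPredictors = as.integer(nPredictors),
      nGeneSets = as.integer(nGeneSets),
      geneSetSizeMin = as.integer(geneSetSizeMin),
      geneSetSizeMax = as.integer(geneSetSizeMax),
      cancerTypes = cancerTypes)
}

#' Analysis configuration
#'
#' Tuning constants of the analysis stages. Positions are 1-based and all
#' intervals are closed throughout the package.
#'
#' @slot window flanking window around a modified lysine (residues; a
#'   site region spans the central K plus `window` residues either side).
#' @slot proximalRange,distalRange absolute offsets from the nearest
#'   central lysine called proximal / distal; they must be disjoint and
#'   `window` must cover the distal range.
#' @slot nShuffles bootstrap shuffles per selection test.
#' @slot nBins mutation-frequency bins of the cancer-gene permutation
#'   test.
#' @slot nGenePermutations permutations of the cancer-gene test.
#' @slot nNetworkPermutations network-shuffling permutations of the
#'   survival-module filter.
#' @slot fdrAlpha significance threshold on BH-adjusted p values.
#' @slot genesetMin,genesetMax retained gene-set size range (members
#'   restricted to PTM-bearing proteins).
#' @slot minMutatedProteins minimum number of separately mutated member
#'   proteins for a gene set to be reported.
#' @slot hotspotMinSnvs minimum SNV count for a recurrent region
#'   (default 6, i.e. more than five).
#' @slot hypermutationRule "mad" or "none".
#' @slot hypermutationK MAD multiplier of the log10-burden outlier rule.
#' @slot maxModuleSize cap on greedy module growth.
#' @slot minPatientsPerType cancer types with fewer patients are skipped.
#' @slot minSeedCarriers minimum mutation carriers for a gene to seed a
#'   module search.
#' @slot overlapThreshold minimum overlap coefficient for an
#'   enrichment-map edge.
#' @slot seed RNG seed of the analysis stages.
#' @export
setClass("AnalysisConfig",
  representation(
    window = "integer", proximalRange = "integer", distalRange = "integer",
    nShuffles = "integer", nBins = "integer",
    nGenePermutations = "numeric", nNetworkPermutations = "integer",
    fdrAlpha = "numeric", genesetMin = "integer", genesetMax = "integer",
    minMutatedProteins = "integer", hotspotMinSnvs = "integer",
    hypermutationRule = "character", hypermutationK = "numeric",
    maxModuleSize = "integer", minPatientsPerType = "integer",
    minSeedCarriers = "integer", overlapThreshold = "numeric",
    seed = "integer"
  )
)

setValidity("AnalysisConfig", function(object) {
  msgs <- character()
  if (object@window < max(object@distalRange))
    msgs <- c(msgs, "'window' must be >= max(distalRange)")
  if (length(intersect(object@proximalRange, object@distalRange)))
    msgs <- c(msgs, "'proximalRange' and 'distalRange' must be disjoint")
  if (object@genesetMin > object@genesetMax)
    msgs <- c(msgs, "'genesetMin' must be <= 'genesetMax'")
  if (!object@hypermutationRule %in% c("mad", "none"))
    msgs <- c(msgs, "'hypermutationRule' must be \"mad\" or \"none\"")
  if (object@nShuffles < 1L)
    msgs <- c(msgs, "'nShuffles' must be >= 1")
  if (object@nNetworkPermutations < 1L)
    msgs <- c(msgs, "'nNetworkPermutations' must be >= 1")
  if (object@fdrAlpha <= 0 || object@fdrAlpha >= 1)
    msgs <- c(msgs, "'fdrAlpha' must be in (0, 1)")
  if (object@maxModuleSize < 1L)
    msgs <- c(msgs, "'maxModuleSize' must be >= 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Build an analysis configuration
#'
#' Defaults follow the standard setup: a +/-7 residue window, offsets 1-2
#' proximal and 3-7 distal, 100,000 bootstrap shuffles, 100
#' mutation-frequency bins, 100 network permutations and BH FDR < 0.05.
#' The cancer-gene permutation count defaults to 1e5 and scales to 1e7.
#'
#' @param window,proximalRange,distalRange,nShuffles,nBins,nGenePermutations,nNetworkPermutations,fdrAlpha,genesetMin,genesetMax,minMutatedProteins,hotspotMinSnvs,hypermutationRule,hypermutationK,maxModuleSize,minPatientsPerType,minSeedCarriers,overlapThreshold,seed
#'   see [AnalysisConfig-class].
#' @return a validated [AnalysisConfig-class] object.
#' @export
analysisConfig <- function(window = 7L, proximalRange = 1:2,
                           distalRange = 3:7, nShuffles = 100000L,
                           nBins = 100L, nGenePermutations = 1e5,
                           nNetworkPermutations = 100L, fdrAlpha = 0.05,
                           genesetMin = 3L, genesetMax = 1000L,
                           minMutatedProteins = 2L, hotspotMinSnvs = 6L,
                           hypermutationRule = "mad", hypermutationK = 3,
                           maxModuleSize = 20L, minPatientsPerType = 10L,
                           minSeedCarriers = 1L, overlapThreshold = 0.5,
                           seed = 1L) {
  new("AnalysisConfig",
      window = as.integer(window),
      proximalRange = as.integer(proximalRange),
      distalRange = as.integer(distalRange),
      nShuffles = as.integer(nShuffles), nBins = as.integer(nBins),
      nGenePermutations = as.numeric(nGenePermutations),
      nNetworkPermutations = as.integer(nNetworkPermutations),
      fdrAlpha = fdrAlpha, genesetMin = as.integer(genesetMin),
      genesetMax = as.integer(genesetMax),
      minMutatedProteins = as.integer(minMutatedProteins),
      hotspotMinSnvs = as.integer(hotspotMinSnvs),
      hypermutationRule = hypermutationRule,
      hypermutationK = hypermutationK,
      maxModuleSize = as.integer(maxModuleSize),
      minPatientsPerType = as.integer(minPatientsPerType),
      minSeedCarriers = as.integer(minSeedCarriers),
      overlapThreshold = overlapThreshold,
      seed = as.integer(seed))
}

#' PTM mutation dataset
#'
#' The central container: a proteome with per-residue tracks, PTM sites,
#' a missense-mutation cohort and the optional side tables (domains,
#' predictor calls, interaction network, patient survival, gene sets).
#' Construct with [PTMDataset()], [readBundle()] or [simulateBundle()].
#'
#' @slot proteins an [Biostrings::AAStringSet] keyed by protein id.
#' @slot disorder named list of per-residue logical vectors.
#' @slot conservation named list of per-residue scores in \[0,1\].
#' @slot domains data.frame(protein_id, domain_id, start, end), closed
#'   1-based intervals.
#' @slot sites data.frame(protein_id, position, acetylation,
#'   ubiquitination); position is the central lysine.
#' @slot mutations data.frame(sample_id, protein_id, position, ref_aa,
#'   alt_aa, cancer_type).
#' @slot predictors data.frame(sample_id, protein_id, position,
#'   pred_1..pred_k logical).
#' @slot network data.frame(protein_a, protein_b), undirected edges.
#' @slot survival data.frame(patient_id, time, event, cancer_type).
#' @slot geneSets named list of character member vectors.
#' @export
setClass("PTMDataset",
  representation(
    proteins = "AAStringSet",
    disorder = "list", conservation = "list",
    domains = "data.frame", sites = "data.frame",
    mutations = "data.frame", predictors = "data.frame",
    network = "data.frame", survival = "data.frame",
    geneSets = "list"
  )
)

setValidity("PTMDataset", function(object) {
  msgs <- character()
  ids <- names(object@proteins)
  if (is.null(ids) || anyDuplicated(ids))
    return("protein ids must be unique and non-empty")
  len <- setNames(Biostrings::width(object@proteins), ids)
  chkTrack <- function(track, what, test) {
    bad <- setdiff(names(track), ids)
    if (length(bad))
      msgs <<- c(msgs, sprintf("%s track for unknown protein '%s'",
                               what, bad[1L]))
    for (id in intersect(names(track), ids)) {
      if (length(track[[id]]) != len[[id]]) {
        msgs <<- c(msgs, sprintf("%s track length mismatch for '%s'",
                                 what, id))
        break
      }
    }
  }
  if (length(object@disorder)) chkTrack(object@disorder, "disorder")
  if (length(object@conservation)) {
    chkTrack(object@conservation, "conservation")
    cc <- unlist(object@conservation, use.names = FALSE)
    if (length(cc) && (min(cc) < 0 || max(cc) > 1))
      msgs <- c(msgs, "conservation scores must lie in [0, 1]")
  }
  st <- object@sites
  if (nrow(st)) {
    if (!all(st$protein_id %in% ids)) {
      msgs <- c(msgs, "site on unknown protein")
    } else {
      if (any(st$position < 1L | st$position > len[st$protein_id]))
        msgs <- c(msgs, "site position outside protein sequence")
      else {
        res <- .residueAt(object@proteins, st$protein_id, st$position)
        if (!all(res == "K"))
          msgs <- c(msgs, "every PTM site position must hold residue K")
      }
      if (!all(st$acetylation | st$ubiquitination))
        msgs <- c(msgs, "each site must carry at least one PTM type")
    }
  }
  mu <- object@mutations
  if (nrow(mu)) {
    if (!all(mu$protein_id %in% ids))
      msgs <- c(msgs, "mutation on unknown protein")
    else if (any(mu$position < 1L | mu$position > len[mu$protein_id]))
      msgs <- c(msgs, "mutation position outside protein sequence")
    if (any(mu$ref_aa == mu$alt_aa))
      msgs <- c(msgs, "silent substitutions are not allowed")
  }
  dm <- object@domains
  if (nrow(dm)) {
    if (!all(dm$protein_id %in% ids))
      msgs <- c(msgs, "domain on unknown protein")
    else if (any(dm$start < 1L | dm$end > len[dm$protein_id] |
                 dm$start > dm$end))
      msgs <- c(msgs, "domain interval outside [1, length]")
  }
  nw <- object@network
  if (nrow(nw) && any(nw$protein_a == nw$protein_b))
    msgs <- c(msgs, "network must not contain self-loops")
  sv <- object@survival
  if (nrow(sv) && any(sv$time <= 0))
    msgs <- c(msgs, "survival times must be > 0")
  if (nrow(sv) && !all(sv$event %in% c(0L, 1L)))
    msgs <- c(msgs, "survival event flags must be 0 or 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

# vectorised single-residue lookup, 1-based
.residueAt <- function(aaset, protein_id, position) {
  out <- character(length(protein_id))
  idx <- split(seq_along(protein_id), protein_id)
  for (id in names(idx)) {
    s <- strsplit(as.character(aaset[[id]]), "", fixed = TRUE)[[1L]]
    out[idx[[id]]] <- s[position[idx[[id]]]]
  }
  out
}

#' Construct a PTMDataset
#'
#' @param proteins AAStringSet (or named character vector) of sequences.
#' @param sites,mutations,domains,predictors,network,survival data.frames
#'   as documented for [PTMDataset-class]; empty by default.
#' @param disorder,conservation named lists of per-residue tracks.
#' @param geneSets named list of member-id vectors.
#' @return a validated [PTMDataset-class].
#' @export
PTMDataset <- function(proteins, sites = emptySites(),
                       mutations = emptyMutations(),
                       disorder = list(), conservation = list(),
                       domains = emptyDomains(),
                       predictors = data.frame(),
                       network = emptyNetwork(),
                       survival = emptySurvival(),
                       geneSets = list()) {
  if (!is(proteins, "AAStringSet"))
    proteins <- Biostrings::AAStringSet(proteins)
  new("PTMDataset", proteins = proteins, sites = sites,
      mutations = mutations, disorder = disorder,
      conservation = conservation, domains = domains,
      predictors = predictors, network = network, survival = survival,
      geneSets = geneSets)
}

#' @rdname PTMDataset
#' @export
emptySites <- function()
  data.frame(protein_id = character(), position = integer(),
             acetylation = logical(), ubiquitination = logical())

#' @rdname PTMDataset
#' @export
emptyMutations <- function()
  data.frame(sample_id = character(), protein_id = character(),
             position = integer(), ref_aa = character(),
             alt_aa = character(), cancer_type = character())

#' @rdname PTMDataset
#' @export
emptyDomains <- function()
  data.frame(protein_id = character(), domain_id = character(),
             start = integer(), end = integer())

#' @rdname PTMDataset
#' @export
emptyNetwork <- function()
  data.frame(protein_a = character(), protein_b = character())

#' @rdname PTMDataset
#' @export
emptySurvival <- function()
  data.frame(patient_id = character(), time = numeric(),
             event = integer(), cancer_type = character())

#' Resampling enrichment result
#'
#' Observed versus expected mutation counts for one selection test, with
#' the fold change and the one-sided empirical p value from the
#' resampling null. The add-one rule p = (1 + b) / (1 + B) is used
#' throughout, so p is never zero and never below 1 / (B + 1).
#'
#' @slot label analysis name.
#' @slot ptmType "acetylation", "ubiquitination" or "any".
#' @slot stratum "all", "disordered" or "structured".
#' @slot observed observed count (or group statistic).
#' @slot expected mean of the null statistics.
#' @slot foldChange observed over expected rate ratio (see each test's
#'   documentation for the exact rate definition).
#' @slot pEmpirical one-sided empirical p.
#' @slot nShuffles number of resampling shuffles.
#' @slot note "ok", or a reason the test was not applicable.
#' @export
setClass("EnrichmentResult",
  representation(label = "character", ptmType = "character",
                 stratum = "character", observed = "numeric",
                 expected = "numeric", foldChange = "numeric",
                 pEmpirical = "numeric", nShuffles = "numeric",
                 note = "character"))

setValidity("EnrichmentResult", function(object) {
  if (identical(object@note, "ok")) {
    if (is.na(object@pEmpirical) || object@pEmpirical <= 0 ||
        object@pEmpirical > 1)
      return("pEmpirical must lie in (0, 1]")
    if (object@pEmpirical < 1 / (object@nShuffles + 1) - 1e-12)
      return("pEmpirical must be >= 1 / (nShuffles + 1)")
  }
  TRUE
})

.enrichmentResult <- function(label, ptmType = "any", stratum = "all",
                              observed = NA_real_, expected = NA_real_,
                              foldChange = NA_real_,
                              pEmpirical = NA_real_, nShuffles = NA_real_,
                              note = "ok") {
  new("EnrichmentResult", label = label, ptmType = ptmType,
      stratum = stratum, observed = as.numeric(observed),
      expected = as.numeric(expected),
      foldChange = as.numeric(foldChange),
      pEmpirical = as.numeric(pEmpirical),
      nShuffles = as.numeric(nShuffles), note = note)
}
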