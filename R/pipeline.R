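#' Run the analysis pipeline
#'
#' Chains the stages over a bundle directory and writes TSV result
#' tables plus a JSON run manifest (configuration echo, seed, package
#' and R versions, record counts, validation report). Stages are
#' self-contained: each recomputes the mapping it needs, so `drivers`
#' works without a prior `map` run. With the same configuration and
#' seed the result tables are byte-identical across runs.
#'
#' Subcommands: `simulate` (write a synthetic bundle with planted
#' truth), `map` (regions + mutation annotations), `select-stats`
#' (proteome-wide selection panel), `drivers` (per-gene scan, hotspots
#' and, when the bundle carries ground truth, the frequency-matched
#' known-gene permutation test), `pathways`, `modules`
#' (survival-correlated network modules with permutation filter) and
#' `all`.
#'
#' @param subcommand one of the stages above.
#' @param inputDir bundle directory (not needed for `simulate`).
#' @param outDir output directory.
#' @param config an [AnalysisConfig-class].
#' @param simCfg a [SimulationConfig-class], used by `simulate`.
#' @return named list of result objects, invisibly.
#' @export
runPipeline <- function(subcommand = c("all", "simulate", "map",
                                       "select-stats", "drivers",
                                       "pathways", "modules"),
                        inputDir = NULL, outDir,
                        config = analysisConfig(),
                        simCfg = simConfig()) {
  subcommand <- match.arg(subcommand)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file)
    write.table(df, file.path(outDir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  manifest <- list(
    subcommand = subcommand,
    seed = config@seed,
    package_version = as.character(utils::packageVersion("ptmsel")),
    r_version = R.version.string,
    analysis_config = .configAsList(config))

  if (subcommand == "simulate") {
    bundle <- simulateBundle(simCfg)
    writeBundle(bundle$dataset, outDir, truth = bundle$truth)
    manifest$simulation_config <- .configAsList(simCfg)
    manifest$counts <- .datasetCounts(bundle$dataset)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(bundle))
  }

  if (is.null(inputDir)) stop("'inputDir' is required for this stage")
  loaded <- readBundle(inputDir)
  dataset <- loaded$dataset
  manifest$validation_report <- as.list(loaded$report)

  set.seed(config@seed)
  filt <- filterHypermutators(mutationTable(dataset),
                              rule = config@hypermutationRule,
                              k = config@hypermutationK)
  dataset@mutations <- filt$mutations
  manifest$hypermutated_samples_removed <- nrow(filt$removed)
  manifest$counts <- .datasetCounts(dataset)

  ann <- classifyMutations(dataset,
                           proximalRange = config@proximalRange,
                           distalRange = config@distalRange,
                           window = config@window)
  results <- list(annotations = ann)

  if (subcommand %in% c("map", "all")) {
    regions <- mergeRegions(dataset, "any", config@window)
    tsv(regions, "regions.tsv")
    tsv(ann, "annotations.tsv")
    results$regions <- regions
  }
  if (subcommand %in% c("select-stats", "all")) {
    ss <- selectionStats(dataset, config, annotations = ann)
    tsv(ss, "selection_stats.tsv")
    results$selection_stats <- ss
  }
  if (subcommand %in% c("drivers", "all")) {
    dr <- scanDriverGenes(dataset, config)
    tsv(dr, "drivers.tsv")
    hs <- findHotspots(ann, mergeRegions(dataset, "any", config@window),
                       config@hotspotMinSnvs)
    tsv(hs, "hotspots.tsv")
    results$drivers <- dr
    results$hotspots <- hs
    if (!is.null(loaded$truth)) {
      counts <- table(factor(mutationTable(dataset)$protein_id,
                             levels = names(proteins(dataset))))
      cg <- cancerGenePermutationTest(
        detected = dr$gene[dr$significant],
        known = loaded$truth$driver_genes,
        geneCounts = setNames(as.integer(counts), names(counts)),
        nBins = config@nBins,
        nPermutations = config@nGenePermutations)
      jsonlite::write_json(cg,
                           file.path(outDir,
                                     "cancer_gene_enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
      results$cancer_gene_enrichment <- cg
    }
  }
  if (subcommand %in% c("pathways", "all")) {
    pw <- testGeneSets(dataset, ann, config)
    tsv(pw, "pathways.tsv")
    em <- enrichmentMapExport(pw, geneSets(dataset),
                              alpha = config@fdrAlpha,
                              overlapThreshold = config@overlapThreshold)
    tsv(em$nodes, "em_nodes.tsv")
    tsv(em$edges, "em_edges.tsv")
    results$pathways <- pw
    results$enrichment_map <- em
  }
  if (subcommand %in% c("modules", "all")) {
    mods <- searchSurvivalModules(dataset, ann, config)
    mods <- permutationFilter(mods, dataset, ann, config)
    tsv(mods, "modules.tsv")
    results$modules <- mods
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

.configAsList <- function(config) {
  out <- lapply(slotNames(class(config)), function(s) slot(config, s))
  names(out) <- slotNames(class(config))
  out
}

.datasetCounts <- function(dataset) {
  list(proteins = length(proteins(dataset)),
       sites = nrow(ptmSites(dataset)),
       mutations = nrow(mutationTable(dataset)),
       samples = length(unique(mutationTable(dataset)$sample_id)),
       network_edges = nrow(networkEdges(dataset)),
       survival_records = nrow(survivalTable(dataset)),
       gene_sets = length(geneSets(dataset)))
}
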