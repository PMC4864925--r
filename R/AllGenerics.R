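#' Accessors for PTMDataset
#'
#' Slot access for [PTMDataset-class] objects goes through these
#' accessors.
#'
#' @param x a PTMDataset.
#' @return the corresponding table, track list or sequence set.
#' @name ptm-accessors
NULL

#' @rdname ptm-accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname ptm-accessors
#' @export
setGeneric("ptmSites", function(x) standardGeneric("ptmSites"))
#' @rdname ptm-accessors
#' @export
setGeneric("mutationTable", function(x) standardGeneric("mutationTable"))
#' @rdname ptm-accessors
#' @export
setGeneric("disorderTracks", function(x) standardGeneric("disorderTracks"))
#' @rdname ptm-accessors
#' @export
setGeneric("conservationTracks",
           function(x) standardGeneric("conservationTracks"))
#' @rdname ptm-accessors
#' @export
setGeneric("domainTable", function(x) standardGeneric("domainTable"))
#' @rdname ptm-accessors
#' @export
setGeneric("predictorCalls", function(x) standardGeneric("predictorCalls"))
#' @rdname ptm-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname ptm-accessors
#' @export
setGeneric("survivalTable", function(x) standardGeneric("survivalTable"))
#' @rdname ptm-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname ptm-accessors
#' @export
setGeneric("proteinLengths", function(x) standardGeneric("proteinLengths"))

#' @rdname ptm-accessors
setMethod("proteins", "PTMDataset", function(x) x@proteins)
#' @rdname ptm-accessors
setMethod("ptmSites", "PTMDataset", function(x) x@sites)
#' @rdname ptm-accessors
setMethod("mutationTable", "PTMDataset", function(x) x@mutations)
#' @rdname ptm-accessors
setMethod("disorderTracks", "PTMDataset", function(x) x@disorder)
#' @rdname ptm-accessors
setMethod("conservationTracks", "PTMDataset", function(x) x@conservation)
#' @rdname ptm-accessors
setMethod("domainTable", "PTMDataset", function(x) x@domains)
#' @rdname ptm-accessors
setMethod("predictorCalls", "PTMDataset", function(x) x@predictors)
#' @rdname ptm-accessors
setMethod("networkEdges", "PTMDataset", function(x) x@network)
#' @rdname ptm-accessors
setMethod("survivalTable", "PTMDataset", function(x) x@survival)
#' @rdname ptm-accessors
setMethod("geneSets", "PTMDataset", function(x) x@geneSets)
#' @rdname ptm-accessors
setMethod("proteinLengths", "PTMDataset", function(x)
  setNames(Biostrings::width(x@proteins), names(x@proteins)))

setMethod("show", "PTMDataset", function(object) {
  cat("PTMDataset\n")
  cat(sprintf("  proteins    : %d (total %d residues)\n",
              length(object@proteins),
              sum(Biostrings::width(object@proteins))))
  st <- object@sites
  cat(sprintf("  PTM sites   : %d (%d acetylation, %d ubiquitination, %d shared)\n",
              nrow(st), sum(st$acetylation), sum(st$ubiquitination),
              sum(st$acetylation & st$ubiquitination)))
  cat(sprintf("  mutations   : %d in %d samples\n", nrow(object@mutations),
              length(unique(object@mutations$sample_id))))
  cat(sprintf("  domains     : %d; network edges: %d; survival records: %d\n",
              nrow(object@domains), nrow(object@network),
              nrow(object@survival)))
  cat(sprintf("  gene sets   : %d; predictor calls: %d\n",
              length(object@geneSets), nrow(object@predictors)))
  invisible(NULL)
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: %s [%s / %s]\n", object@label,
              object@ptmType, object@stratum))
  if (identical(object@note, "ok")) {
    cat(sprintf("  observed %.4g, expected %.4g, FC = %.4g\n",
                object@observed, object@expected, object@foldChange))
    cat(sprintf("  empirical p = %.4g (%g shuffles, one-sided)\n",
                object@pEmpirical, object@nShuffles))
  } else {
    cat(sprintf("  not applicable: %s\n", object@note))
  }
  invisible(NULL)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  %d proteins (mean length %g), %d samples, seed %d\n",
              object@nProteins, object@proteinLengthMean,
              object@nSamples, object@seed))
  cat(sprintf("  burden NB(mu=%g, size=%g), hypermutators %g%% x%g\n",
              object@burdenMean, object@burdenDispersion,
              100 * object@hypermutatorFraction,
              object@hypermutatorMultiplier))
  cat(sprintf("  %d drivers at %gx PTM-region rate; module size %d, HR %g\n",
              object@nDriverGenes, object@driverPtmEnrichment,
              object@plantedModuleSize, object@moduleHazardRatio))
  invisible(NULL)
})

#' @export
#' @method as.data.frame EnrichmentResult
as.data.frame.EnrichmentResult <- function(x, ...) {
  data.frame(label = x@label, ptm_type = x@ptmType, stratum = x@stratum,
             observed = x@observed, expected = x@expected,
             fold_change = x@foldChange, p_empirical = x@pEmpirical,
             n_shuffles = x@nShuffles, note = x@note,
             stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "EnrichmentResult", as.data.frame.EnrichmentResult)
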