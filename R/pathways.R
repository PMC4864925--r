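#' Poisson exact test (upper tail)
#'
#' p = P(X >= observed) for X ~ Poisson(lambda), from the exact
#' cumulative distribution.
#'
#' @param observed observed count (>= 0).
#' @param lambda expected count (> 0).
#' @return upper-tail probability.
#' @examples
#' poissonExactTest(1, 1)  # 1 - exp(-1)
#' @export
poissonExactTest <- function(observed, lambda) {
  if (length(lambda) != 1L || is.na(lambda) || lambda <= 0)
    stop("'lambda' must be a single positive value")
  if (observed < 0) stop("'observed' must be >= 0")
  if (observed == 0) return(1)
  ppois(observed - 1, lambda, lower.tail = FALSE)
}

#' Gene-set enrichment of PTM-region mutations
#'
#' Considers only PTM-bearing proteins. The background per-residue rate
#' is total PTM-region mutations over total merged PTM-region length
#' across the union of all pathway-annotated, PTM-bearing proteins.
#' Each set's expectation is that rate times the set's summed
#' PTM-region length, tested with the Poisson exact upper tail. Sets
#' with fewer than `genesetMin` or more than `genesetMax` PTM-bearing
#' members, or with fewer than `minMutatedProteins` separately mutated
#' member proteins, are dropped with a reason. BH FDR is computed over
#' the tested sets.
#'
#' @param dataset a [PTMDataset-class].
#' @param annotations output of [classifyMutations()].
#' @param config an [AnalysisConfig-class].
#' @param sets optional named list of gene sets overriding the
#'   dataset's.
#' @return data.frame of tested sets sorted by p, with an attribute
#'   `dropped` (data.frame set_id, reason) and `background_rate`.
#' @export
testGeneSets <- function(dataset, annotations,
                         config = analysisConfig(), sets = NULL) {
  if (is.null(sets)) sets <- geneSets(dataset)
  if (!length(sets)) stop("no gene sets provided")
  bearing <- .ptmBearingProteins(dataset)
  lens <- proteinLengths(dataset)
  rr <- .regionRangesList(
    .sitePositionsByProtein(ptmSites(dataset), "any"), lens,
    config@window)
  regLen <- vapply(rr, function(ir)
    sum(IRanges::end(ir) - IRanges::start(ir) + 1L), numeric(1L))
  ptmMut <- annotations[annotations$category != "none", , drop = FALSE]
  mutCount <- table(factor(ptmMut$protein_id, levels = bearing))

  universe <- intersect(unique(unlist(sets)), bearing)
  totLen <- sum(regLen[universe])
  totMut <- sum(mutCount[universe])
  rate <- if (totLen > 0) totMut / totLen else 0

  rows <- list()
  dropped <- list()
  for (sid in names(sets)) {
    mem <- intersect(sets[[sid]], bearing)
    if (length(mem) < config@genesetMin) {
      dropped[[sid]] <- "fewer PTM-bearing members than genesetMin"
      next
    }
    if (length(mem) > config@genesetMax) {
      dropped[[sid]] <- "more PTM-bearing members than genesetMax"
      next
    }
    obs <- sum(mutCount[mem])
    nMutProt <- sum(mutCount[mem] > 0L)
    if (nMutProt < config@minMutatedProteins) {
      dropped[[sid]] <- "fewer than minMutatedProteins separately mutated proteins"
      next
    }
    lam <- rate * sum(regLen[mem])
    p <- if (lam > 0) poissonExactTest(obs, lam) else 1
    rows[[sid]] <- data.frame(
      set_id = sid, n_members = length(sets[[sid]]),
      n_members_ptm = length(mem),
      region_length = sum(regLen[mem]), observed = as.numeric(obs),
      expected = lam, n_mutated_proteins = nMutProt, p = p)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_id = character(), n_members = integer(),
               n_members_ptm = integer(), region_length = numeric(),
               observed = numeric(), expected = numeric(),
               n_mutated_proteins = integer(), p = numeric())
  if (nrow(out)) {
    out$fdr <- p.adjust(out$p, method = "BH")
    out$significant <- out$fdr < config@fdrAlpha
    out <- out[order(out$p, out$set_id), ]
  } else {
    out$fdr <- numeric(); out$significant <- logical()
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(
    set_id = names(dropped),
    reason = unlist(dropped, use.names = FALSE))
  attr(out, "background_rate") <- rate
  out
}

#' Export enrichment-map node and edge tables
#'
#' Nodes are the significant gene sets; edges connect pairs whose
#' overlap coefficient |A intersect B| / min(|A|, |B|) reaches the
#' threshold (default 0.5). Similarity is symmetric, so each pair is
#' emitted once.
#'
#' @param results output of [testGeneSets()].
#' @param sets the gene sets (named list) the results refer to.
#' @param alpha FDR threshold selecting nodes (default 0.05).
#' @param overlapThreshold minimum overlap coefficient for an edge.
#' @return list with `nodes` and `edges` data.frames.
#' @export
enrichmentMapExport <- function(results, sets, alpha = 0.05,
                                overlapThreshold = 0.5) {
  sig <- results[!is.na(results$fdr) & results$fdr < alpha, ,
                 drop = FALSE]
  nodes <- sig[, c("set_id", "n_members_ptm", "observed", "expected",
                   "p", "fdr")]
  edges <- data.frame(set_a = character(), set_b = character(),
                      similarity = numeric())
  ids <- nodes$set_id
  if (length(ids) >= 2L) {
    rows <- list()
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        A <- sets[[ids[i]]]; B <- sets[[ids[j]]]
        sim <- length(intersect(A, B)) / min(length(A), length(B))
        if (sim >= overlapThreshold)
          rows[[length(rows) + 1L]] <- data.frame(
            set_a = ids[i], set_b = ids[j], similarity = sim)
      }
    }
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  rownames(nodes) <- NULL
  list(nodes = nodes, edges = edges)
}
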