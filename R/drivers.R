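#' Exact upper-tail Poisson p value for a gene's active-site mutations
#'
#' p = P(X >= observed) for X ~ Poisson(expected), computed from the
#' exact cumulative distribution (no normal approximation). With
#' observed = 0 the p value is 1. An expectation of zero with a
#' positive observation returns the smallest representable positive
#' value.
#'
#' @param observed observed PTM-region mutation count (integer >= 0).
#' @param expected expected count under the gene's null model.
#' @return upper-tail probability.
#' @examples
#' genePtmPvalue(3, 3)   # P(X >= 3 | lambda = 3)
#' @export
genePtmPvalue <- function(observed, expected) {
  stopifnot(length(observed) == 1L, length(expected) == 1L,
            observed >= 0, expected >= 0)
  if (observed == 0) return(1)
  if (expected == 0) return(.Machine$double.xmin)
  ppois(observed - 1, expected, lower.tail = FALSE)
}

#' Fit the per-gene null mutation model and score PTM-region burden
#'
#' Regresses per-residue mutation counts on the disorder indicator
#' (Poisson, log link), sums the fitted means over merged PTM-region
#' residues to get the expected active-site count E, and compares with
#' the observed count O through the exact Poisson upper tail. Degenerate
#' designs (constant disorder) or non-convergent fits fall back to the
#' uniform rate total/length, flagged in the output. In
#' `mode = "central"` only the central modified lysines count as active
#' residues.
#'
#' @param dataset a [PTMDataset-class].
#' @param gene protein id.
#' @param mutations optional mutation table overriding the dataset's.
#' @param window flanking window (default 7).
#' @param mode "region" (default) or "central".
#' @param useSiteDensity also include the local site-density covariate
#'   (sites per 15-residue window) in the null model.
#' @return one-row data.frame: gene, n_mutations, O (with per-category
#'   breakdown), E, p, fallback flag.
#' @export
fitGeneModel <- function(dataset, gene, mutations = NULL, window = 7L,
                         mode = c("region", "central"),
                         useSiteDensity = FALSE) {
  mode <- match.arg(mode)
  if (is.null(mutations)) mutations <- mutationTable(dataset)
  lens <- proteinLengths(dataset)
  if (!gene %in% names(lens)) stop("unknown gene: ", gene)
  L <- lens[[gene]]
  sp <- sort(ptmSites(dataset)[ptmSites(dataset)$protein_id == gene,
                               "position"])
  mp <- mutations$position[mutations$protein_id == gene]
  if (length(sp) == 0L || length(mp) == 0L)
    stop("gene must have at least one PTM site and one mutation")
  y <- tabulate(mp, nbins = L)
  diso <- disorderTracks(dataset)[[gene]]
  if (is.null(diso)) diso <- rep(FALSE, L)

  ir <- IRanges::reduce(IRanges::IRanges(pmax(1L, sp - window),
                                         pmin(L, sp + window)))
  active <- if (mode == "central") sp else
    unlist(lapply(seq_along(ir), function(j)
      IRanges::start(ir)[j]:IRanges::end(ir)[j]))

  fallback <- FALSE
  mu <- NULL
  covars <- data.frame(disorder = as.numeric(diso))
  if (useSiteDensity) {
    dens <- numeric(L)
    for (p in sp)
      dens[max(1L, p - window):min(L, p + window)] <-
        dens[max(1L, p - window):min(L, p + window)] + 1
    covars$site_density <- dens
  }
  varying <- vapply(covars, function(x) length(unique(x)) > 1L,
                    logical(1L))
  if (any(varying)) {
    fit <- tryCatch(
      glm(y ~ ., data = covars[, varying, drop = FALSE],
          family = poisson()),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && fit$converged) mu <- fit$fitted.values
  }
  if (is.null(mu)) {
    mu <- rep(sum(y) / L, L)
    fallback <- TRUE
  }
  E <- sum(mu[active])
  O <- sum(y[active])
  offs <- vapply(mp, function(p) min(abs(p - sp)), numeric(1L))
  data.frame(
    gene = gene, n_mutations = length(mp),
    O = O,
    O_direct = sum(offs == 0),
    O_proximal = sum(offs %in% 1:2),
    O_distal = sum(offs %in% 3:7),
    E = E, p = genePtmPvalue(O, E), fallback = fallback)
}

#' Scan all eligible genes for PTM-specific mutation enrichment
#'
#' Runs [fitGeneModel()] on every gene with at least one PTM site and
#' one mutation, adjusts p values with Benjamini-Hochberg over the
#' tested genes and sorts by p. `mode = "central"` repeats the analysis
#' counting only substitutions of the central modified lysines.
#'
#' @param dataset a [PTMDataset-class].
#' @param config an [AnalysisConfig-class].
#' @param mutations optional mutation table overriding the dataset's.
#' @param mode "region" or "central".
#' @param useSiteDensity forwarded to [fitGeneModel()].
#' @return data.frame sorted by p with BH `fdr` and `significant`
#'   columns.
#' @export
scanDriverGenes <- function(dataset, config = analysisConfig(),
                            mutations = NULL,
                            mode = c("region", "central"),
                            useSiteDensity = FALSE) {
  mode <- match.arg(mode)
  if (is.null(mutations)) mutations <- mutationTable(dataset)
  eligible <- intersect(unique(ptmSites(dataset)$protein_id),
                        unique(mutations$protein_id))
  if (!length(eligible)) {
    out <- data.frame(gene = character(), n_mutations = integer(),
                      O = numeric(), O_direct = numeric(),
                      O_proximal = numeric(), O_distal = numeric(),
                      E = numeric(), p = numeric(), fallback = logical(),
                      fdr = numeric(), significant = logical())
    return(out)
  }
  rows <- lapply(sort(eligible), function(g)
    fitGeneModel(dataset, g, mutations, window = config@window,
                 mode = mode, useSiteDensity = useSiteDensity))
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$gene), ]
  out$significant <- out$fdr < config@fdrAlpha
  rownames(out) <- NULL
  out
}

#' Recurrently mutated PTM regions (hotspots)
#'
#' Merged PTM regions holding more than `minSnvs - 1` mutations
#' (default: more than five), with a per-cancer-type breakdown and a
#' combinatorial flag marking regions whose member sites carry both PTM
#' types. Regions are disjoint, so no mutation is double-counted.
#'
#' @param annotations output of [classifyMutations()].
#' @param regions output of [mergeRegions()].
#' @param minSnvs minimum SNV count to report (default 6).
#' @return data.frame of hotspot regions sorted by count.
#' @export
findHotspots <- function(annotations, regions, minSnvs = 6L) {
  hit <- annotations[!is.na(annotations$region_id), , drop = FALSE]
  cnt <- table(hit$region_id)
  keep <- names(cnt)[cnt >= minSnvs]
  if (!length(keep)) {
    return(data.frame(region_id = character(), protein_id = character(),
                      start = integer(), end = integer(),
                      n_snvs = integer(), combinatorial = logical(),
                      by_cancer_type = character()))
  }
  sub <- regions[match(keep, regions$region_id), ]
  byType <- vapply(keep, function(rid) {
    tt <- sort(table(hit$cancer_type[hit$region_id == rid]),
               decreasing = TRUE)
    paste(sprintf("%s:%d", names(tt), as.integer(tt)), collapse = ";")
  }, character(1L))
  out <- data.frame(region_id = keep, protein_id = sub$protein_id,
                    start = sub$start, end = sub$end,
                    n_snvs = as.integer(cnt[keep]),
                    combinatorial = sub$acetylation & sub$ubiquitination,
                    by_cancer_type = byType)
  out <- out[order(-out$n_snvs, out$region_id), ]
  rownames(out) <- NULL
  out
}

#' Mutation-frequency-matched permutation test for known-gene overlap
#'
#' Bins the gene universe into `nBins` equal-size groups by per-gene
#' mutation count, then repeatedly draws a random gene set matching the
#' known genes' bin profile and counts its overlap with the detected
#' set. Within a bin the draw is uniform without replacement, so the
#' per-bin overlap is hypergeometric; the permutation statistic is
#' realised as the sum of independent per-bin hypergeometric draws,
#' which is distributionally identical to sampling gene identities and
#' scales to 1e7 permutations. One-sided empirical p with the add-one
#' rule.
#'
#' @param detected character vector of detected genes.
#' @param known character vector of known genes (subset of the
#'   universe).
#' @param geneCounts named integer vector: per-gene mutation counts for
#'   the whole universe.
#' @param nBins number of frequency bins (default 100; reduced to the
#'   universe size when larger).
#' @param nPermutations number of permutations.
#' @return list with `observed_overlap`, `null_mean`, `empirical_p`,
#'   `n_bins`, `n_permutations`.
#' @export
cancerGenePermutationTest <- function(detected, known, geneCounts,
                                      nBins = 100L,
                                      nPermutations = 1e5) {
  universe <- names(geneCounts)
  if (!all(known %in% universe))
    stop("'known' must be a subset of the gene universe")
  detected <- intersect(detected, universe)
  nG <- length(universe)
  nBins <- max(1L, min(as.integer(nBins), nG))
  ord <- order(geneCounts, universe)
  bin <- integer(nG)
  bin[ord] <- as.integer(ceiling(seq_len(nG) / (nG / nBins)))
  names(bin) <- universe
  obs <- length(intersect(known, detected))
  detBin <- tabulate(bin[detected], nBins)
  knownBin <- tabulate(bin[known], nBins)
  sizeBin <- tabulate(bin, nBins)
  stat <- numeric(0L)
  B <- as.numeric(nPermutations)
  chunk <- 1e6
  done <- 0
  nGE <- 0
  nullSum <- 0
  while (done < B) {
    b <- as.integer(min(chunk, B - done))
    s <- numeric(b)
    for (g in which(knownBin > 0L)) {
      k <- min(knownBin[g], sizeBin[g])
      s <- s + rhyper(b, detBin[g], sizeBin[g] - detBin[g], k)
    }
    nGE <- nGE + sum(s >= obs)
    nullSum <- nullSum + sum(s)
    done <- done + b
  }
  list(observed_overlap = obs, null_mean = nullSum / B,
       empirical_p = .empiricalP(nGE, B),
       n_bins = nBins, n_permutations = B)
}
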