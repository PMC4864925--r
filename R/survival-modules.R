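#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing event times between
#' carriers and non-carriers. Tied event times contribute jointly
#' through the shared risk set (all events at a time are evaluated
#' against the risk set entering that time). Returns a not-applicable
#' marker (NA statistic and p, with a note) when a group is empty or no
#' variance can be accumulated (e.g. no events).
#'
#' @param time positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group logical carrier flags (same length).
#' @return list with `statistic`, `p`, `observed` and `expected` events
#'   in the carrier group, `direction` (+1 means more carrier events
#'   than expected, i.e. reduced carrier survival) and `note`.
#' @export
logrankTest <- function(time, event, group) {
  stopifnot(length(time) == length(event),
            length(time) == length(group))
  group <- as.logical(group)
  if (!any(group) || all(group))
    return(list(statistic = NA_real_, p = NA_real_,
                observed = NA_real_, expected = NA_real_,
                direction = NA_real_, note = "a group is empty"))
  prep <- .survPrep(time, event)
  r <- .logrankCore(prep, group)
  if (is.na(r[["stat"]]))
    return(list(statistic = NA_real_, p = NA_real_,
                observed = r[["O1"]], expected = r[["E1"]],
                direction = NA_real_, note = "no usable event times"))
  list(statistic = r[["stat"]],
       p = pchisq(r[["stat"]], df = 1L, lower.tail = FALSE),
       observed = r[["O1"]], expected = r[["E1"]],
       direction = sign(r[["O1"]] - r[["E1"]]), note = "ok")
}

# sorted survival scaffold reused across many group evaluations
.survPrep <- function(time, event) {
  ord <- order(time)
  t_s <- time[ord]
  e_s <- as.integer(event[ord])
  n <- length(t_s)
  newt <- !duplicated(t_s)
  uid <- cumsum(newt)
  nD <- uid[n]
  f <- which(newt)                       # first sorted index per distinct time
  d <- tabulate(uid[e_s == 1L], nD)      # events per distinct time
  nAtRisk <- n - f + 1
  list(ord = ord, n = n, uid = uid, f = f, d = d, nAtRisk = nAtRisk,
       eventIdx = which(e_s == 1L), nD = nD)
}

# group: logical over patients in ORIGINAL order
.logrankCore <- function(prep, group) {
  g_s <- group[prep$ord]
  cc <- cumsum(g_s)
  sumg <- cc[prep$n]
  n1 <- sumg - c(0, cc)[prep$f]          # carriers at risk per distinct time
  ei <- prep$eventIdx
  d1 <- tabulate(prep$uid[ei[g_s[ei]]], prep$nD)
  keep <- prep$d > 0L
  dj <- prep$d[keep]; nj <- prep$nAtRisk[keep]
  n1j <- n1[keep]; d1j <- d1[keep]
  O1 <- sum(d1j)
  E1 <- sum(dj * n1j / nj)
  vok <- nj > 1
  V <- sum((dj * (n1j / nj) * (1 - n1j / nj) *
              (nj - dj) / (nj - 1))[vok])
  if (!is.finite(V) || V <= 0)
    return(c(stat = NA_real_, O1 = O1, E1 = E1))
  c(stat = (O1 - E1)^2 / V, O1 = O1, E1 = E1)
}

#' Greedily grow a survival-correlated module from a seed gene
#'
#' Starts from the seed and repeatedly adds the neighbouring gene whose
#' inclusion (through the union of mutation carriers) most decreases
#' the log-rank p value; growth stops when no neighbour strictly
#' improves p or the module reaches `maxSize`. Neighbours whose
#' carriers add nothing to the current carrier set cannot change p and
#' are never added. Ties between candidates break by smallest p, then
#' lexicographic gene id, so the search is deterministic.
#'
#' @param seed seed gene id (must be in the network and have carriers).
#' @param adjacency named list: gene -> character vector of neighbours.
#' @param carriers named list: gene -> integer indices of carrier
#'   patients (positions in the cohort vectors).
#' @param time,event cohort survival vectors (one entry per patient).
#' @param maxSize maximum module size (default 20).
#' @return list with `nodes` (sorted), `seed`, `carriers`, `statistic`,
#'   `p`, `direction`.
#' @export
growModule <- function(seed, adjacency, carriers, time, event,
                       maxSize = 20L) {
  if (!seed %in% names(adjacency)) stop("seed not in network: ", seed)
  prep <- .survPrep(time, event)
  n <- prep$n
  .p <- function(idx) {
    if (length(idx) == 0L || length(idx) == n) return(NA_real_)
    g <- logical(n); g[idx] <- TRUE
    r <- .logrankCore(prep, g)
    if (is.na(r[["stat"]])) return(NA_real_)
    pchisq(r[["stat"]], df = 1L, lower.tail = FALSE)
  }
  nodes <- seed
  curCar <- sort(unique(carriers[[seed]]))
  pCur <- .p(curCar)
  repeat {
    if (length(nodes) >= maxSize || is.na(pCur)) break
    cand <- setdiff(sort(unique(unlist(adjacency[nodes],
                                       use.names = FALSE))), nodes)
    if (!length(cand)) break
    bestP <- Inf; bestG <- NA_character_; bestCar <- NULL
    for (g in cand) {
      add <- carriers[[g]]
      if (is.null(add) || all(add %in% curCar)) next
      newCar <- sort(unique(c(curCar, add)))
      pNew <- .p(newCar)
      if (is.na(pNew)) next
      if (pNew < bestP || (pNew == bestP && !is.na(bestG) && g < bestG)) {
        bestP <- pNew; bestG <- g; bestCar <- newCar
      }
    }
    if (!is.finite(bestP) || !(bestP < pCur)) break
    nodes <- c(nodes, bestG)
    curCar <- bestCar
    pCur <- bestP
  }
  g <- logical(n); g[curCar] <- TRUE
  r <- if (length(curCar) > 0L && length(curCar) < n)
    .logrankCore(prep, g) else c(stat = NA_real_, O1 = NA, E1 = NA)
  list(nodes = sort(nodes), seed = seed, carriers = curCar,
       statistic = unname(r[["stat"]]), p = pCur,
       direction = unname(sign(r[["O1"]] - r[["E1"]])))
}

# one full greedy search over a seed set; shared by the observed run
# and the permutation null
.searchCore <- function(adjacency, carriers, time, event, maxSize,
                        minSeedCarriers, nPatients) {
  seeds <- names(carriers)[vapply(carriers, function(x)
    length(x) >= minSeedCarriers && length(x) < nPatients, logical(1L))]
  seeds <- intersect(seeds, names(adjacency))
  mods <- list()
  seen <- character(0L)
  for (s in sort(seeds)) {
    m <- growModule(s, adjacency, carriers, time, event, maxSize)
    if (is.na(m$p)) next
    key <- paste(m$nodes, collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    mods[[length(mods) + 1L]] <- m
  }
  mods[order(vapply(mods, `[[`, numeric(1L), "p"))]
}

#' Search survival-correlated network modules per cancer type
#'
#' For every cancer type with enough patients, seeds a greedy
#' [growModule()] run from each mutated network gene (genes whose
#' PTM-associated mutations have at least `minSeedCarriers` carriers in
#' the cohort), deduplicates modules with identical node sets and sorts
#' by log-rank p. Carriers are patients with at least one direct,
#' proximal or distal mutation in a module gene.
#'
#' @param dataset a [PTMDataset-class] with network and survival tables.
#' @param annotations output of [classifyMutations()].
#' @param config an [AnalysisConfig-class].
#' @return data.frame: cancer_type, seed, nodes (";"-joined), n_nodes,
#'   n_carriers, statistic, p_logrank, direction.
#' @export
searchSurvivalModules <- function(dataset, annotations,
                                  config = analysisConfig()) {
  sv <- survivalTable(dataset)
  nw <- networkEdges(dataset)
  empty <- data.frame(cancer_type = character(), seed = character(),
                      nodes = character(), n_nodes = integer(),
                      n_carriers = integer(), statistic = numeric(),
                      p_logrank = numeric(), direction = numeric())
  if (nrow(sv) == 0L || nrow(nw) == 0L) return(empty)
  adjacency <- .adjList(nw)
  ptmMut <- annotations[annotations$category != "none", , drop = FALSE]
  out <- list()
  for (ct in sort(unique(sv$cancer_type))) {
    coh <- sv[sv$cancer_type == ct, , drop = FALSE]
    if (nrow(coh) < config@minPatientsPerType) next
    carriers <- .carriersByGene(ptmMut, coh$patient_id,
                                names(adjacency))
    if (!length(carriers)) next
    mods <- .searchCore(adjacency, carriers, coh$time, coh$event,
                        config@maxModuleSize, config@minSeedCarriers,
                        nrow(coh))
    if (!length(mods)) next
    out[[ct]] <- data.frame(
      cancer_type = ct,
      seed = vapply(mods, `[[`, character(1L), "seed"),
      nodes = vapply(mods, function(m)
        paste(m$nodes, collapse = ";"), character(1L)),
      n_nodes = vapply(mods, function(m)
        length(m$nodes), integer(1L)),
      n_carriers = vapply(mods, function(m)
        length(m$carriers), integer(1L)),
      statistic = vapply(mods, `[[`, numeric(1L), "statistic"),
      p_logrank = vapply(mods, `[[`, numeric(1L), "p"),
      direction = vapply(mods, `[[`, numeric(1L), "direction"))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.adjList <- function(edges) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  adjacency <- setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) {
    adjacency[[nd]] <- sort(unique(c(
      edges$protein_b[edges$protein_a == nd],
      edges$protein_a[edges$protein_b == nd])))
  }
  adjacency
}

# gene -> indices (into the cohort patient vector) of carriers
.carriersByGene <- function(ptmMut, patients, networkGenes) {
  mu <- ptmMut[ptmMut$protein_id %in% networkGenes &
                 ptmMut$sample_id %in% patients, , drop = FALSE]
  if (!nrow(mu)) return(list())
  idx <- match(mu$sample_id, patients)
  lapply(split(idx, mu$protein_id), function(x) sort(unique(x)))
}

#' Network-shuffling permutation filter for survival modules
#'
#' Reruns the full greedy search on `nPermutations` copies of the data
#' in which the gene labels of the network nodes are randomly permuted
#' (the topology, per-gene carrier sets and survival data are
#' untouched, so only the gene-to-node assignment is broken). Each
#' permutation records the best (minimum) module p; a module's
#' empirical p is (1 + #{permutation best-p <= module p}) /
#' (nPermutations + 1), computed within its cancer type. Modules with
#' empirical p < 0.05 are flagged significant.
#'
#' @param modules output of [searchSurvivalModules()].
#' @param dataset,annotations,config as in [searchSurvivalModules()].
#' @return `modules` with added `p_empirical` and `significant`
#'   columns.
#' @export
permutationFilter <- function(modules, dataset, annotations,
                              config = analysisConfig()) {
  B <- config@nNetworkPermutations
  if (B < 1L) stop("'nNetworkPermutations' must be >= 1")
  if (nrow(modules) == 0L) {
    modules$p_empirical <- numeric(0L)
    modules$significant <- logical(0L)
    return(modules)
  }
  sv <- survivalTable(dataset)
  adjacency <- .adjList(networkEdges(dataset))
  nodes <- names(adjacency)
  ptmMut <- annotations[annotations$category != "none", , drop = FALSE]
  modules$p_empirical <- NA_real_
  for (ct in unique(modules$cancer_type)) {
    coh <- sv[sv$cancer_type == ct, , drop = FALSE]
    carriers <- .carriersByGene(ptmMut, coh$patient_id, nodes)
    bestP <- numeric(B)
    for (b in seq_len(B)) {
      perm <- setNames(sample(nodes), nodes)
      carPerm <- setNames(carriers, unname(perm[names(carriers)]))
      mods <- .searchCore(adjacency, carPerm, coh$time, coh$event,
                          config@maxModuleSize, config@minSeedCarriers,
                          nrow(coh))
      bestP[b] <- if (length(mods)) min(vapply(mods, `[[`,
                                               numeric(1L), "p")) else 1
    }
    sel <- modules$cancer_type == ct
    modules$p_empirical[sel] <- vapply(modules$p_logrank[sel],
                                       function(p)
                                         .empiricalP(sum(bestP <= p), B),
                                       numeric(1L))
  }
  modules$significant <- modules$p_empirical < 0.05
  modules
}
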