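#' Bootstrap enrichment of mutations in merged PTM-site regions
#'
#' Restricted to proteins carrying at least one site of the tested PTM
#' type, compares the per-residue mutation rate inside merged site
#' regions with the rate outside them. The null reassigns each
#' protein's mutations uniformly at random over that protein's
#' residues, preserving per-protein totals (realised as one binomial
#' draw per protein per shuffle, which is distributionally identical
#' and fast), and the one-sided empirical p uses the add-one rule
#' p = (1 + b) / (1 + B).
#'
#' @param dataset a [PTMDataset-class].
#' @param ptmType "acetylation", "ubiquitination" or "any".
#' @param nShuffles bootstrap shuffles.
#' @param mutations optional mutation table overriding the dataset's.
#' @param window flanking window (default 7).
#' @return an [EnrichmentResult-class]; the fold change is the in-region
#'   per-residue rate over the out-of-region rate.
#' @export
bootstrapRegionEnrichment <- function(dataset, ptmType = "any",
                                      nShuffles = 100000L,
                                      mutations = NULL, window = 7L) {
  if (is.null(mutations)) mutations <- mutationTable(dataset)
  byProt <- .sitePositionsByProtein(ptmSites(dataset), ptmType)
  scope <- names(byProt)
  label <- "region_enrichment"
  if (!length(scope))
    return(.enrichmentResult(label, ptmType,
                             note = "no proteins with sites of this type"))
  lens <- proteinLengths(dataset)
  rr <- .regionRangesList(byProt, lens, window)
  inLen <- vapply(rr, function(ir)
    sum(IRanges::end(ir) - IRanges::start(ir) + 1L), numeric(1L))
  mu <- mutations[mutations$protein_id %in% scope, , drop = FALSE]
  if (nrow(mu) == 0L)
    return(.enrichmentResult(label, ptmType, observed = 0, expected = 0,
                             foldChange = NA, pEmpirical = 1,
                             nShuffles = nShuffles,
                             note = "no mutations in scope"))
  nMut <- table(factor(mu$protein_id, levels = scope))
  inReg <- logical(nrow(mu))
  for (id in unique(mu$protein_id)) {
    sel <- mu$protein_id == id
    inReg[sel] <- .inRanges(mu$position[sel], rr[[id]])
  }
  obs <- sum(inReg)
  inTot <- sum(inLen)
  outTot <- sum(lens[scope]) - inTot
  if (outTot <= 0)
    return(.enrichmentResult(label, ptmType, observed = obs,
                             note = "regions cover the whole scope"))
  nullCounts <- numeric(nShuffles)
  for (id in scope) {
    m <- as.integer(nMut[[id]])
    if (m > 0L)
      nullCounts <- nullCounts + rbinom(nShuffles, m,
                                        inLen[[id]] / lens[[id]])
  }
  fc <- (obs / inTot) / ((nrow(mu) - obs) / outTot)
  .enrichmentResult(label, ptmType, observed = obs,
                    expected = mean(nullCounts), foldChange = fc,
                    pEmpirical = .empiricalP(sum(nullCounts >= obs),
                                             nShuffles),
                    nShuffles = nShuffles)
}

#' Bootstrap enrichment of substitutions at central modified lysines
#'
#' Compares the mutation rate of modified lysines with that of
#' non-modified lysines, both restricted to K residues of proteins
#' carrying sites of the tested type. The resampling null redistributes
#' each protein's lysine mutations uniformly over that protein's lysine
#' positions. Proteins without any non-modified lysine are excluded.
#'
#' @inheritParams bootstrapRegionEnrichment
#' @return an [EnrichmentResult-class]; fold change is the per-residue
#'   rate at modified K over the rate at non-modified K.
#' @export
centralLysineEnrichment <- function(dataset, ptmType = "any",
                                    nShuffles = 100000L,
                                    mutations = NULL) {
  if (is.null(mutations)) mutations <- mutationTable(dataset)
  byProt <- .sitePositionsByProtein(ptmSites(dataset), ptmType)
  label <- "central_lysine_enrichment"
  if (!length(byProt))
    return(.enrichmentResult(label, ptmType,
                             note = "no proteins with sites of this type"))
  chars <- .seqChars(proteins(dataset))
  nK <- vapply(names(byProt), function(id)
    sum(chars[[id]] == "K"), numeric(1L))
  nModK <- vapply(byProt, length, numeric(1L))
  keep <- nK > nModK  # needs at least one non-modified K
  if (!any(keep))
    return(.enrichmentResult(label, ptmType,
                             note = "all lysines modified"))
  scope <- names(byProt)[keep]
  mu <- mutations[mutations$protein_id %in% scope &
                    mutations$ref_aa == "K", , drop = FALSE]
  if (nrow(mu) == 0L)
    return(.enrichmentResult(label, ptmType, observed = 0, expected = 0,
                             foldChange = NA, pEmpirical = 1,
                             nShuffles = nShuffles,
                             note = "no lysine mutations in scope"))
  atMod <- vapply(seq_len(nrow(mu)), function(r)
    mu$position[r] %in% byProt[[mu$protein_id[r]]], logical(1L))
  obs <- sum(atMod)
  nKmut <- table(factor(mu$protein_id, levels = scope))
  nullCounts <- numeric(nShuffles)
  for (id in scope) {
    m <- as.integer(nKmut[[id]])
    if (m > 0L)
      nullCounts <- nullCounts + rbinom(nShuffles, m,
                                        nModK[[id]] / nK[[id]])
  }
  modTot <- sum(nModK[keep])
  unmodTot <- sum(nK[keep]) - modTot
  fc <- (obs / modTot) / ((nrow(mu) - obs) / unmodTot)
  .enrichmentResult(label, ptmType, observed = obs,
                    expected = mean(nullCounts), foldChange = fc,
                    pEmpirical = .empiricalP(sum(nullCounts >= obs),
                                             nShuffles),
                    nShuffles = nShuffles)
}

#' Bootstrap concentration of PTM-associated mutations in domains
#'
#' Among PTM-associated mutations (category direct/proximal/distal),
#' counts those falling inside annotated domain intervals and compares
#' with resampled placement of each protein's mutations over its
#' residues. Fold change is observed count over the null mean, so a
#' proteome fully covered by domains gives FC = 1 exactly.
#'
#' @param dataset a [PTMDataset-class].
#' @param annotations output of [classifyMutations()].
#' @param nShuffles bootstrap shuffles.
#' @return an [EnrichmentResult-class].
#' @export
domainEnrichment <- function(dataset, annotations,
                             nShuffles = 100000L) {
  label <- "domain_enrichment"
  dm <- domainTable(dataset)
  if (nrow(dm) == 0L)
    return(.enrichmentResult(label, note = "no domain annotations"))
  mu <- annotations[annotations$category != "none", , drop = FALSE]
  if (nrow(mu) == 0L)
    return(.enrichmentResult(label, observed = 0, expected = 0,
                             foldChange = NA, pEmpirical = 1,
                             nShuffles = nShuffles,
                             note = "no PTM-associated mutations"))
  lens <- proteinLengths(dataset)
  domRR <- lapply(split(dm, dm$protein_id), function(g)
    IRanges::reduce(IRanges::IRanges(g$start, g$end)))
  domLen <- setNames(numeric(length(lens)), names(lens))
  for (id in names(domRR))
    domLen[[id]] <- sum(IRanges::end(domRR[[id]]) -
                          IRanges::start(domRR[[id]]) + 1L)
  inDom <- logical(nrow(mu))
  for (id in unique(mu$protein_id)) {
    sel <- mu$protein_id == id
    inDom[sel] <- .inRanges(mu$position[sel], domRR[[id]])
  }
  obs <- sum(inDom)
  scope <- unique(mu$protein_id)
  nMut <- table(factor(mu$protein_id, levels = scope))
  nullCounts <- numeric(nShuffles)
  for (id in scope) {
    m <- as.integer(nMut[[id]])
    if (m > 0L && domLen[[id]] > 0)
      nullCounts <- nullCounts + rbinom(nShuffles, m,
                                        domLen[[id]] / lens[[id]])
  }
  expected <- mean(nullCounts)
  .enrichmentResult(label, observed = obs, expected = expected,
                    foldChange = if (expected > 0) obs / expected else NA,
                    pEmpirical = .empiricalP(sum(nullCounts >= obs),
                                             nShuffles),
                    nShuffles = nShuffles)
}

#' Conservation contrast of PTM versus non-PTM mutations
#'
#' Within each disorder stratum of the mutated residues, compares the
#' mean conservation score of PTM-associated mutations with that of
#' other mutations. The null shuffles the PTM / non-PTM labels over the
#' mutated residues of the stratum; one-sided p for greater
#' conservation of the PTM group.
#'
#' @inheritParams domainEnrichment
#' @return list of [EnrichmentResult-class], one per stratum
#'   ("disordered", "structured").
#' @export
conservationContrast <- function(dataset, annotations,
                                 nShuffles = 100000L) {
  if (nrow(annotations) == 0L) stop("no mutations to contrast")
  isPtm <- annotations$category != "none"
  if (all(isPtm) || !any(isPtm))
    stop("degenerate stratum: both PTM and non-PTM mutations required")
  cons <- conservationTracks(dataset)
  diso <- disorderTracks(dataset)
  v <- numeric(nrow(annotations))
  d <- logical(nrow(annotations))
  for (id in unique(annotations$protein_id)) {
    sel <- annotations$protein_id == id
    v[sel] <- cons[[id]][annotations$position[sel]]
    d[sel] <- diso[[id]][annotations$position[sel]]
  }
  out <- list()
  for (stratum in c("disordered", "structured")) {
    inStr <- if (stratum == "disordered") d else !d
    vs <- v[inStr]
    ls <- isPtm[inStr]
    label <- "conservation_contrast"
    if (sum(ls) < 2L || sum(!ls) < 2L) {
      out[[stratum]] <- .enrichmentResult(
        label, stratum = stratum,
        note = "fewer than 2 mutations in a group")
      next
    }
    n1 <- sum(ls)
    n <- length(vs)
    tot <- sum(vs)
    obsStat <- mean(vs[ls]) / mean(vs[!ls])
    nullStat <- numeric(nShuffles)
    for (b in seq_len(nShuffles)) {
      s1 <- sum(vs[sample.int(n, n1)])
      nullStat[b] <- (s1 / n1) / ((tot - s1) / (n - n1))
    }
    out[[stratum]] <- .enrichmentResult(
      label, stratum = stratum, observed = obsStat,
      expected = mean(nullStat), foldChange = obsStat,
      pEmpirical = .empiricalP(sum(nullStat >= obsStat), nShuffles),
      nShuffles = nShuffles)
  }
  out
}

#' Deleteriousness-ensemble association with PTM regions
#'
#' Scores each mutation 0..k by counting its true predictor calls;
#' consensus means all predictors call it deleterious. Tests the 2x2
#' table consensus/non-consensus by PTM-region/non-PTM with a one-sided
#' Fisher exact test (hypergeometric upper tail). The odds ratio is
#' (a d)/(b c), with a 0.5 substitution in every cell when any cell is
#' zero (reported via `continuity`).
#'
#' @param dataset a [PTMDataset-class].
#' @param annotations output of [classifyMutations()].
#' @param predictors optional predictor-call table overriding the
#'   dataset's.
#' @return list with `scores` (per-mutation score table), `table` (2x2
#'   counts), `odds_ratio`, `p`, `sidedness`, `continuity` and
#'   `n_excluded` (mutations without calls).
#' @export
impactAssociation <- function(dataset, annotations, predictors = NULL) {
  if (is.null(predictors)) predictors <- predictorCalls(dataset)
  if (nrow(annotations) == 0L || nrow(predictors) == 0L)
    stop("annotations and predictor calls are both required")
  predCols <- grep("^pred_", names(predictors), value = TRUE)
  idx <- match(.mutKey(annotations), .mutKey(predictors))
  excluded <- sum(is.na(idx))
  keep <- !is.na(idx)
  calls <- predictors[idx[keep], predCols, drop = FALSE]
  score <- as.integer(rowSums(calls))
  isPtm <- annotations$category[keep] != "none"
  consensus <- score == length(predCols)
  scores <- cbind(annotations[keep, c("sample_id", "protein_id",
                                      "position", "category")],
                  score = score, consensus = consensus)
  a <- sum(consensus & isPtm); b <- sum(consensus & !isPtm)
  cc <- sum(!consensus & isPtm); dd <- sum(!consensus & !isPtm)
  tab <- matrix(c(a, b, cc, dd), nrow = 2L, byrow = TRUE,
                dimnames = list(c("consensus", "other"),
                                c("ptm", "non_ptm")))
  if (all(consensus) || !any(consensus) || all(isPtm) || !any(isPtm)) {
    orv <- 1; p <- 1; continuity <- FALSE
  } else {
    continuity <- any(tab == 0L)
    orv <- if (continuity)
      ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
    else (a * dd) / (b * cc)
    p <- fisher.test(tab, alternative = "greater")$p.value
  }
  list(scores = scores, table = tab, odds_ratio = orv, p = p,
       sidedness = "greater", continuity = continuity,
       n_excluded = excluded)
}

#' Run the full proteome-wide selection panel
#'
#' Convenience wrapper producing one table row per test, PTM type and
#' stratum: region enrichment and central-lysine enrichment for each
#' PTM type, domain concentration, the conservation contrast per
#' disorder stratum, and the predictor-consensus association.
#'
#' @param dataset a [PTMDataset-class].
#' @param config an [AnalysisConfig-class].
#' @param annotations optional precomputed [classifyMutations()] output.
#' @return data.frame of results.
#' @export
selectionStats <- function(dataset, config = analysisConfig(),
                           annotations = NULL) {
  if (is.null(annotations))
    annotations <- classifyMutations(dataset,
                                     proximalRange = config@proximalRange,
                                     distalRange = config@distalRange,
                                     window = config@window)
  B <- config@nShuffles
  rows <- list()
  for (tp in c("acetylation", "ubiquitination")) {
    rows[[length(rows) + 1L]] <- as.data.frame(
      bootstrapRegionEnrichment(dataset, tp, B, window = config@window))
    rows[[length(rows) + 1L]] <- as.data.frame(
      centralLysineEnrichment(dataset, tp, B))
  }
  rows[[length(rows) + 1L]] <- as.data.frame(
    domainEnrichment(dataset, annotations, B))
  cc <- tryCatch(conservationContrast(dataset, annotations, B),
                 error = function(e) NULL)
  if (!is.null(cc))
    for (r in cc) rows[[length(rows) + 1L]] <- as.data.frame(r)
  ia <- tryCatch(impactAssociation(dataset, annotations),
                 error = function(e) NULL)
  if (!is.null(ia))
    rows[[length(rows) + 1L]] <- data.frame(
      label = "impact_consensus", ptm_type = "any", stratum = "all",
      observed = ia$table[1L, 1L], expected = NA,
      fold_change = ia$odds_ratio, p_empirical = ia$p, n_shuffles = NA,
      note = if (ia$continuity) "continuity-corrected OR" else "ok")
  do.call(rbind, rows)
}
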