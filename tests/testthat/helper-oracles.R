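# Independent oracles and small fixture builders shared by the suite.

# brute-force per-residue region marking: loop over sites, mark +/-window
bruteRegionMask <- function(sitePositions, len, window = 7L) {
  mask <- logical(len)
  for (p in sitePositions)
    mask[max(1L, p - window):min(len, p + window)] <- TRUE
  mask
}

# upper-tail Poisson probability by explicit term-by-term summation
poisTailOracle <- function(observed, lambda) {
  if (observed == 0) return(1)
  term <- exp(observed * log(lambda) - lambda - lgamma(observed + 1))
  total <- 0
  k <- observed
  repeat {
    total <- total + term
    term <- term * lambda / (k + 1)
    k <- k + 1
    if (term < total * 1e-18 || k > observed + 10000) break
  }
  total
}

# one-sided (greater) Fisher p by full enumeration of tables with the
# observed margins, each table weighted by its exact multinomial
# probability computed from log-factorials
fisherEnumOracle <- function(a, b, cc, dd) {
  r1 <- a + b; r2 <- cc + dd; c1 <- a + cc; c2 <- b + dd
  N <- r1 + r2
  lo <- max(0L, r1 + c1 - N); hi <- min(r1, c1)
  logP <- function(x) {
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1) -
      lgamma(N + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) -
      lgamma(c1 - x + 1) - lgamma(N - r1 - c1 + x + 1)
  }
  sum(exp(vapply(seq(a, hi), logP, numeric(1L))))
}

# Benjamini-Hochberg from the definition: step-up with cumulative minima
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# from-definition log-rank: loop distinct event times, hypergeometric
# moments against the shared risk set
logrankOracle <- function(time, event, group) {
  ut <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O1 - E1)^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# a protein that is all alanine except lysines at the given positions
kProtein <- function(len, kPositions) {
  s <- rep("A", len)
  s[kPositions] <- "K"
  paste(s, collapse = "")
}

# minimal dataset: one or more all-A proteins with K sites
siteDataset <- function(lens, sitePos, acetyl = TRUE, ubiq = FALSE) {
  ids <- names(lens)
  seqs <- vapply(ids, function(id)
    kProtein(lens[[id]], sitePos[[id]]), character(1L))
  sites <- do.call(rbind, lapply(ids, function(id) {
    if (!length(sitePos[[id]])) return(NULL)
    data.frame(protein_id = id, position = sitePos[[id]],
               acetylation = acetyl, ubiquitination = ubiq)
  }))
  if (is.null(sites)) sites <- emptySites()
  PTMDataset(proteins = setNames(seqs, ids), sites = sites)
}

mutRow <- function(protein, pos, ref = "K", alt = "R",
                   sample = "S1", ct = "LUAD") {
  data.frame(sample_id = sample, protein_id = protein, position = pos,
             ref_aa = ref, alt_aa = alt, cancer_type = ct)
}

smallSimConfig <- function(seed = 1L, ...) {
  args <- list(seed = seed, nProteins = 30L, proteinLengthMean = 250,
               nSamples = 60L, burdenMean = 12, nGeneSets = 10L,
               plantedModuleSize = 5L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simConfig, args)
}

# samples carrying a mutation inside a PTM region of a planted-module
# gene, computed with the brute-force region mask
.carrierSamplesOracle <- function(prot, truth, cohort) {
  mu <- cohort$mutations
  lens <- proteinLengths(prot)
  hits <- logical(nrow(mu))
  for (id in intersect(truth$planted_module, unique(mu$protein_id))) {
    sp <- ptmSites(prot)$position[ptmSites(prot)$protein_id == id]
    mask <- bruteRegionMask(sp, lens[[id]])
    sel <- mu$protein_id == id
    hits[sel] <- mask[mu$position[sel]]
  }
  unique(mu$sample_id[hits])
}

# build an annotation + predictor pair realising a given 2x2
# consensus-by-PTM table (for testing the Fisher path end to end)
makeImpactData <- function(a, b, cc, dd, nPred = 5L) {
  n <- a + b + cc + dd
  cat <- c(rep("direct", a), rep("none", b), rep("direct", cc),
           rep("none", dd))
  cons <- c(rep(TRUE, a + b), rep(FALSE, cc + dd))
  ann <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    protein_id = "P1", position = seq_len(n),
                    category = cat)
  calls <- matrix(TRUE, n, nPred)
  calls[!cons, 1L] <- FALSE
  colnames(calls) <- sprintf("pred_%d", seq_len(nPred))
  pred <- cbind(ann[, c("sample_id", "protein_id", "position")],
                as.data.frame(calls))
  list(annotations = ann, predictors = pred)
}
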