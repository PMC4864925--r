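#' Map 15-mer PTM site sequences onto a proteome
#'
#' Each record names a protein, a PTM type and a 15-mer whose central
#' (8th) residue is the modified lysine. The 15-mer is matched exactly
#' against the protein sequence; every exact occurrence yields a site,
#' so a 15-mer occurring twice gives two sites, while partial matches
#' are discarded. Terminal sites may pad the 15-mer with `_` on either
#' end; padded patterns match only at the corresponding protein
#' terminus. Records whose central residue is not `K` are rejected and
#' counted. Records that already carry a resolved `position` (and no
#' 15-mer) are validated against the sequence and passed through.
#' Output is deduplicated by (protein, position) with PTM types unioned.
#'
#' @param siteRecords data.frame with columns `protein_id`, `ptm_type`
#'   ("acetylation", "ubiquitination" or "shared") and either
#'   `fifteen_mer` or `position`.
#' @param proteome a [PTMDataset-class] (or AAStringSet).
#' @return list with `sites` (the site table, see
#'   [PTMDataset-class]) and `rejected` (a count by reason).
#' @examples
#' prot <- PTMDataset(c(P1 = "AAAAAAAKAAAAAAA"))
#' mapSites(data.frame(protein_id = "P1", ptm_type = "acetylation",
#'                     fifteen_mer = "AAAAAAAKAAAAAAA"), prot)$sites
#' @export
mapSites <- function(siteRecords, proteome) {
  aaset <- if (is(proteome, "PTMDataset")) proteins(proteome) else proteome
  ids <- names(aaset)
  lens <- setNames(Biostrings::width(aaset), ids)
  rejected <- c(bad_central = 0L, unknown_protein = 0L, no_match = 0L,
                bad_position = 0L)
  rows <- vector("list", nrow(siteRecords))
  hasMer <- "fifteen_mer" %in% names(siteRecords)
  hasPos <- "position" %in% names(siteRecords)
  for (r in seq_len(nrow(siteRecords))) {
    rec <- siteRecords[r, ]
    if (!rec$protein_id %in% ids) {
      rejected[["unknown_protein"]] <- rejected[["unknown_protein"]] + 1L
      next
    }
    mer <- if (hasMer) rec$fifteen_mer else NA_character_
    if (!is.na(mer) && nzchar(mer)) {
      hit <- .matchFifteenMer(mer, aaset[[rec$protein_id]])
      if (is.null(hit)) {
        rejected[["bad_central"]] <- rejected[["bad_central"]] + 1L
        next
      }
      if (length(hit) == 0L) {
        rejected[["no_match"]] <- rejected[["no_match"]] + 1L
        next
      }
      posv <- hit
    } else if (hasPos && !is.na(rec$position)) {
      p <- as.integer(rec$position)
      ok <- p >= 1L && p <= lens[[rec$protein_id]] &&
        as.character(Biostrings::subseq(aaset[[rec$protein_id]], p, p)) == "K"
      if (!ok) {
        rejected[["bad_position"]] <- rejected[["bad_position"]] + 1L
        next
      }
      posv <- p
    } else {
      rejected[["bad_position"]] <- rejected[["bad_position"]] + 1L
      next
    }
    rows[[r]] <- data.frame(
      protein_id = rec$protein_id, position = posv,
      acetylation = rec$ptm_type %in% c("acetylation", "shared"),
      ubiquitination = rec$ptm_type %in% c("ubiquitination", "shared"))
  }
  got <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(got))
    return(list(sites = emptySites(), rejected = rejected))
  st <- do.call(rbind, got)
  key <- paste(st$protein_id, st$position)
  sites <- do.call(rbind, lapply(split(st, key), function(g)
    data.frame(protein_id = g$protein_id[1L], position = g$position[1L],
               acetylation = any(g$acetylation),
               ubiquitination = any(g$ubiquitination))))
  sites <- sites[order(sites$protein_id, sites$position), ]
  rownames(sites) <- NULL
  list(sites = sites, rejected = rejected)
}

# all exact (possibly overlapping) occurrences of a 15-mer; returns the
# central-lysine positions, NULL if the central residue is not K
.matchFifteenMer <- function(mer, subject) {
  chars <- strsplit(mer, "", fixed = TRUE)[[1L]]
  if (length(chars) != 15L) return(NULL)
  if (chars[8L] != "K") return(NULL)
  leftPad <- match(FALSE, chars == "_", nomatch = 16L) - 1L
  rightPad <- match(FALSE, rev(chars) == "_", nomatch = 16L) - 1L
  core <- paste(chars[(leftPad + 1L):(15L - rightPad)], collapse = "")
  m <- Biostrings::matchPattern(core, subject)
  st <- IRanges::start(m)
  if (leftPad > 0L) st <- st[st == 1L]
  if (rightPad > 0L) {
    en <- st + nchar(core) - 1L
    st <- st[en == length(subject)]
  }
  # central K sits 8 - leftPad residues into the core
  st + (8L - leftPad) - 1L
}

#' Merge PTM site windows into maximal disjoint regions
#'
#' Each site contributes the closed window `[position - window,
#' position + window]` clipped to `[1, length]`; overlapping windows are
#' merged into maximal disjoint intervals per protein. Merging is
#' idempotent: re-merging the member sites of the output reproduces the
#' same intervals.
#'
#' @param dataset a [PTMDataset-class].
#' @param ptmType "any", "acetylation" or "ubiquitination"; regions are
#'   built from sites of that type only.
#' @param window flanking window in residues (default 7).
#' @return data.frame(protein_id, region_id, start, end, n_sites,
#'   acetylation, ubiquitination), sorted, with regions of one protein
#'   pairwise disjoint.
#' @export
mergeRegions <- function(dataset, ptmType = "any", window = 7L) {
  byProt <- .sitePositionsByProtein(ptmSites(dataset), ptmType)
  lens <- proteinLengths(dataset)
  rr <- .regionRangesList(byProt, lens, window)
  st <- ptmSites(dataset)
  out <- vector("list", length(rr))
  for (i in seq_along(rr)) {
    id <- names(rr)[i]
    ir <- rr[[i]]
    sPos <- byProt[[id]]
    sSub <- st[st$protein_id == id & st$position %in% sPos, ]
    k <- findInterval(sSub$position, IRanges::start(ir))
    out[[i]] <- data.frame(
      protein_id = id,
      region_id = sprintf("%s:%d-%d", id, IRanges::start(ir),
                          IRanges::end(ir)),
      start = IRanges::start(ir), end = IRanges::end(ir),
      n_sites = as.vector(table(factor(k, levels = seq_along(ir)))),
      acetylation = vapply(seq_along(ir), function(j)
        any(sSub$acetylation[k == j]), logical(1L)),
      ubiquitination = vapply(seq_along(ir), function(j)
        any(sSub$ubiquitination[k == j]), logical(1L)))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(), region_id = character(),
               start = integer(), end = integer(), n_sites = integer(),
               acetylation = logical(), ubiquitination = logical())
  res <- res[order(res$protein_id, res$start), ]
  rownames(res) <- NULL
  res
}

#' Classify mutations by proximity to modified lysines
#'
#' The category follows the minimal absolute offset between the mutated
#' residue and any same-protein central lysine: 0 is `direct`, offsets
#' in `proximalRange` (default 1-2) are `proximal`, offsets in
#' `distalRange` (default 3-7) are `distal`, anything farther (or a
#' protein without sites) is `none`. When two sites are equidistant the
#' PTM types of all tied nearest sites are unioned.
#'
#' @param dataset a [PTMDataset-class].
#' @param mutations mutation table (defaults to the dataset's).
#' @param proximalRange,distalRange,window offset ranges, see
#'   [AnalysisConfig-class].
#' @return the mutation table with added columns `category`, `offset`,
#'   `nearest_site`, `region_id`, `site_acetylation`,
#'   `site_ubiquitination`.
#' @export
classifyMutations <- function(dataset, mutations = NULL,
                              proximalRange = 1:2, distalRange = 3:7,
                              window = 7L) {
  if (is.null(mutations)) mutations <- mutationTable(dataset)
  n <- nrow(mutations)
  ann <- mutations
  ann$category <- rep("none", n)
  ann$offset <- rep(NA_integer_, n)
  ann$nearest_site <- rep(NA_integer_, n)
  ann$region_id <- rep(NA_character_, n)
  ann$site_acetylation <- rep(NA, n)
  ann$site_ubiquitination <- rep(NA, n)
  if (n == 0L) return(ann)

  st <- ptmSites(dataset)
  regions <- mergeRegions(dataset, "any", window)
  byProt <- split(seq_len(n), mutations$protein_id)
  for (id in names(byProt)) {
    idx <- byProt[[id]]
    sSub <- st[st$protein_id == id, ]
    if (nrow(sSub) == 0L) next
    sp <- sort(sSub$position)
    ac <- sSub$acetylation[order(sSub$position)]
    ub <- sSub$ubiquitination[order(sSub$position)]
    mp <- mutations$position[idx]
    i <- findInterval(mp, sp)
    dLeft <- ifelse(i >= 1L, mp - sp[pmax(i, 1L)], Inf)
    dRight <- ifelse(i < length(sp), sp[pmin(i + 1L, length(sp))] - mp, Inf)
    off <- pmin(dLeft, dRight)
    nearLeft <- dLeft <= dRight
    nearest <- ifelse(nearLeft, sp[pmax(i, 1L)],
                      sp[pmin(i + 1L, length(sp))])
    tie <- is.finite(dLeft) & is.finite(dRight) & dLeft == dRight &
      dLeft > 0
    sAc <- ifelse(nearLeft, ac[pmax(i, 1L)], ac[pmin(i + 1L, length(sp))])
    sUb <- ifelse(nearLeft, ub[pmax(i, 1L)], ub[pmin(i + 1L, length(sp))])
    if (any(tie)) {
      sAc[tie] <- sAc[tie] | ac[pmin(i + 1L, length(sp))][tie]
      sUb[tie] <- sUb[tie] | ub[pmin(i + 1L, length(sp))][tie]
    }
    cat <- ifelse(off == 0L, "direct",
           ifelse(off %in% proximalRange, "proximal",
           ifelse(off %in% distalRange, "distal", "none")))
    inWin <- off <= window
    ann$category[idx] <- cat
    ann$offset[idx] <- as.integer(off)
    ann$nearest_site[idx] <- ifelse(inWin, as.integer(nearest), NA)
    ann$site_acetylation[idx] <- ifelse(inWin, sAc, NA)
    ann$site_ubiquitination[idx] <- ifelse(inWin, sUb, NA)
    rSub <- regions[regions$protein_id == id, ]
    if (nrow(rSub)) {
      rIdx <- findInterval(mp, rSub$start)
      inReg <- rIdx >= 1L & mp <= rSub$end[pmax(rIdx, 1L)]
      ann$region_id[idx][inReg & inWin] <-
        rSub$region_id[rIdx[inReg & inWin]]
    }
  }
  ann
}

#' Remove hypermutated samples
#'
#' Flags samples with an extreme mutation burden and removes all their
#' mutations. The default rule flags samples whose log10 burden exceeds
#' the cohort median by more than `k` times the MAD of log10 burdens;
#' `rule = "none"` returns the input unchanged. The rule is pluggable
#' because the threshold for calling a sample hypermutated is a
#' cohort-level judgement; whatever rule is applied is reported.
#'
#' @param mutations mutation table.
#' @param rule "mad" or "none".
#' @param k MAD multiplier (default 3).
#' @return list with `mutations` (filtered), `removed` (data.frame of
#'   flagged samples with burdens), `rule` and `k`.
#' @export
filterHypermutators <- function(mutations, rule = c("mad", "none"), k = 3) {
  rule <- match.arg(rule)
  if (rule == "none" || nrow(mutations) == 0L)
    return(list(mutations = mutations,
                removed = data.frame(sample_id = character(),
                                     burden = integer()),
                rule = rule, k = k))
  burden <- table(mutations$sample_id)
  lb <- log10(as.numeric(burden))
  thr <- median(lb) + k * mad(lb)
  flagged <- names(burden)[lb > thr]
  list(mutations = mutations[!mutations$sample_id %in% flagged, ,
                             drop = FALSE],
       removed = data.frame(sample_id = flagged,
                            burden = as.integer(burden[flagged])),
       rule = rule, k = k)
}
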