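# shared internal helpers

# one-sided empirical p with the add-one rule; never 0, never < 1/(B+1)
.empiricalP <- function(nGreaterEqual, nShuffles)
  (1 + nGreaterEqual) / (1 + nShuffles)

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# split sequences once into character vectors, keyed by protein id
.seqChars <- function(aaset) {
  out <- strsplit(as.character(aaset), "", fixed = TRUE)
  names(out) <- names(aaset)
  out
}

# merged closed windows [p - window, p + window] clipped to [1, len],
# as an IRanges per protein; `positions` is a named list keyed by id
.regionRangesList <- function(positions, lengths, window = 7L) {
  out <- vector("list", length(positions))
  names(out) <- names(positions)
  for (id in names(positions)) {
    p <- positions[[id]]
    out[[id]] <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1L, p - window), end = pmin(lengths[[id]], p + window)))
  }
  out
}

# membership test of positions in an IRanges of disjoint intervals
.inRanges <- function(pos, ir) {
  if (length(ir) == 0L) return(rep(FALSE, length(pos)))
  s <- IRanges::start(ir)
  e <- IRanges::end(ir)
  i <- findInterval(pos, s)
  i > 0L & pos <= e[pmax(i, 1L)]
}

# site positions per protein for one PTM type ("any" keeps all sites)
.sitePositionsByProtein <- function(sites, ptmType = "any") {
  keep <- switch(ptmType,
                 any = rep(TRUE, nrow(sites)),
                 acetylation = sites$acetylation,
                 ubiquitination = sites$ubiquitination,
                 stop("unknown PTM type: ", ptmType))
  st <- sites[keep, , drop = FALSE]
  split(st$position, st$protein_id)
}

.ptmBearingProteins <- function(dataset, ptmType = "any") {
  names(.sitePositionsByProtein(dataset@sites, ptmType))
}

# aligned predictor/mutation join key
.mutKey <- function(df)
  paste(df$sample_id, df$protein_id, df$position, sep = "\r")
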