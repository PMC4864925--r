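#' Write an analysis bundle to disk
#'
#' Writes the full interchange bundle: `proteins.fasta`, `sites.tsv`,
#' `mutations.tsv`, `disorder.tsv`, `conservation.tsv`, `domains.tsv`,
#' `predictors.tsv`, `network.tsv`, `survival.tsv`, `genesets.gmt` and,
#' when ground truth is supplied, `truth.json`. All TSVs carry header
#' rows; positions are 1-based and intervals closed. Numeric tracks are
#' written with fixed precision so identical datasets produce
#' byte-identical bundles.
#'
#' @param dataset a [PTMDataset-class].
#' @param dir output directory (created if needed).
#' @param truth optional list from [simulateTruth()].
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(dataset, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file)
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  Biostrings::writeXStringSet(proteins(dataset),
                              file.path(dir, "proteins.fasta"))
  st <- ptmSites(dataset)
  tsv(data.frame(protein_id = st$protein_id, position = st$position,
                 ptm_types = ifelse(st$acetylation & st$ubiquitination,
                                    "acetylation;ubiquitination",
                                    ifelse(st$acetylation, "acetylation",
                                           "ubiquitination"))),
      "sites.tsv")
  tsv(mutationTable(dataset), "mutations.tsv")
  diso <- disorderTracks(dataset)
  tsv(data.frame(
    protein_id = rep(names(diso), lengths(diso)),
    position = unlist(lapply(lengths(diso), seq_len), use.names = FALSE),
    disorder = as.integer(unlist(diso, use.names = FALSE))),
    "disorder.tsv")
  cons <- conservationTracks(dataset)
  tsv(data.frame(
    protein_id = rep(names(cons), lengths(cons)),
    position = unlist(lapply(lengths(cons), seq_len), use.names = FALSE),
    score = sprintf("%.4f", unlist(cons, use.names = FALSE))),
    "conservation.tsv")
  tsv(domainTable(dataset), "domains.tsv")
  pr <- predictorCalls(dataset)
  if (nrow(pr)) {
    prOut <- pr
    for (cl in grep("^pred_", names(prOut)))
      prOut[[cl]] <- as.integer(prOut[[cl]])
    tsv(prOut, "predictors.tsv")
  } else {
    tsv(data.frame(sample_id = character(), protein_id = character(),
                   position = integer()), "predictors.tsv")
  }
  tsv(networkEdges(dataset), "network.tsv")
  sv <- survivalTable(dataset)
  sv$time <- sprintf("%.4f", sv$time)
  tsv(sv, "survival.tsv")
  writeGmt(geneSets(dataset), file.path(dir, "genesets.gmt"))
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read and cross-validate an analysis bundle
#'
#' Reads the files written by [writeBundle()] and validates all
#' cross-references. Records that fail validation are dropped and
#' counted in the report rather than aborting the run: sites beyond the
#' protein length or not on a lysine, mutations whose reference amino
#' acid does not match the sequence, silent substitutions. Duplicate
#' FASTA ids or a missing required column are format errors and stop
#' the run. Survival patients absent from the cohort sample ids are
#' kept but flagged in the report.
#'
#' @param dir bundle directory.
#' @return list with `dataset` (a [PTMDataset-class]), `truth` (or
#'   NULL) and `report` (named counts of dropped / flagged records).
#' @export
readBundle <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }
  rd <- function(f, cols) {
    df <- read.delim(need(f), stringsAsFactors = FALSE)
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("format error in %s: missing column(s) %s", f,
                   paste(miss, collapse = ", ")))
    df
  }
  prot <- Biostrings::readAAStringSet(need("proteins.fasta"))
  names(prot) <- sub("\\s.*$", "", names(prot))
  if (anyDuplicated(names(prot)))
    stop("format error in proteins.fasta: duplicate protein ids")
  lens <- setNames(Biostrings::width(prot), names(prot))
  chars <- .seqChars(prot)
  report <- c()

  stRaw <- rd("sites.tsv", c("protein_id", "position", "ptm_types"))
  ok <- stRaw$protein_id %in% names(prot)
  report["sites_unknown_protein"] <- sum(!ok)
  stRaw <- stRaw[ok, , drop = FALSE]
  inB <- stRaw$position >= 1L & stRaw$position <= lens[stRaw$protein_id]
  report["sites_out_of_bounds"] <- sum(!inB)
  stRaw <- stRaw[inB, , drop = FALSE]
  if (nrow(stRaw)) {
    isK <- vapply(seq_len(nrow(stRaw)), function(r)
      chars[[stRaw$protein_id[r]]][stRaw$position[r]] == "K",
      logical(1L))
  } else isK <- logical(0L)
  report["sites_not_lysine"] <- sum(!isK)
  stRaw <- stRaw[isK, , drop = FALSE]
  types <- strsplit(stRaw$ptm_types, ";", fixed = TRUE)
  sites <- data.frame(
    protein_id = stRaw$protein_id,
    position = as.integer(stRaw$position),
    acetylation = vapply(types, function(x)
      "acetylation" %in% x, logical(1L)),
    ubiquitination = vapply(types, function(x)
      "ubiquitination" %in% x, logical(1L)))

  mu <- rd("mutations.tsv", c("sample_id", "protein_id", "position",
                              "ref_aa", "alt_aa", "cancer_type"))
  ok <- mu$protein_id %in% names(prot)
  report["mutations_unknown_protein"] <- sum(!ok)
  mu <- mu[ok, , drop = FALSE]
  inB <- mu$position >= 1L & mu$position <= lens[mu$protein_id]
  report["mutations_out_of_bounds"] <- sum(!inB)
  mu <- mu[inB, , drop = FALSE]
  if (nrow(mu)) {
    refOk <- vapply(seq_len(nrow(mu)), function(r)
      chars[[mu$protein_id[r]]][mu$position[r]] == mu$ref_aa[r],
      logical(1L))
  } else refOk <- logical(0L)
  report["mutations_ref_mismatch"] <- sum(!refOk)
  mu <- mu[refOk, , drop = FALSE]
  silent <- mu$ref_aa == mu$alt_aa
  report["mutations_silent"] <- sum(silent)
  mu <- mu[!silent, , drop = FALSE]
  mu$position <- as.integer(mu$position)

  dtab <- rd("disorder.tsv", c("protein_id", "position", "disorder"))
  disorder <- lapply(split(dtab, dtab$protein_id), function(g)
    as.logical(g$disorder[order(g$position)]))
  ctab <- rd("conservation.tsv", c("protein_id", "position", "score"))
  conservation <- lapply(split(ctab, ctab$protein_id), function(g)
    as.numeric(g$score[order(g$position)]))

  dm <- rd("domains.tsv", c("protein_id", "domain_id", "start", "end"))
  ok <- dm$protein_id %in% names(prot) & dm$start >= 1L &
    dm$end <= lens[dm$protein_id] & dm$start <= dm$end
  report["domains_dropped"] <- sum(!ok)
  dm <- dm[ok, , drop = FALSE]

  pr <- read.delim(need("predictors.tsv"), stringsAsFactors = FALSE)
  for (cl in grep("^pred_", names(pr)))
    pr[[cl]] <- as.logical(pr[[cl]])

  nw <- rd("network.tsv", c("protein_a", "protein_b"))
  ok <- nw$protein_a != nw$protein_b
  report["network_self_loops"] <- sum(!ok)
  nw <- unique(nw[ok, , drop = FALSE])

  sv <- rd("survival.tsv", c("patient_id", "time", "event",
                             "cancer_type"))
  sv$time <- as.numeric(sv$time)
  sv$event <- as.integer(sv$event)
  ok <- sv$time > 0 & sv$event %in% c(0L, 1L)
  report["survival_dropped"] <- sum(!ok)
  sv <- sv[ok, , drop = FALSE]
  report["survival_unmatched_patients"] <-
    length(setdiff(sv$patient_id, mu$sample_id))

  gs <- readGmt(need("genesets.gmt"))

  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth$planted_enrichment <- as.numeric(truth$planted_enrichment)
    truth$planted_hazard_ratio <- as.numeric(truth$planted_hazard_ratio)
  }
  rownames(sites) <- rownames(mu) <- rownames(dm) <- rownames(nw) <-
    rownames(sv) <- NULL
  dataset <- PTMDataset(proteins = prot, sites = sites, mutations = mu,
                        disorder = disorder, conservation = conservation,
                        domains = dm, predictors = pr, network = nw,
                        survival = sv, geneSets = gs)
  list(dataset = dataset, truth = truth, report = report)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT dialect: tab-separated lines with a set id, a
#' description and then the member ids.
#'
#' @param path file path.
#' @return `readGmt`: named list of member vectors with a
#'   `descriptions` attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("format error in %s: line %d has fewer than 3 fields",
                 path, bad[1L]))
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets)))
    stop("format error: duplicate gene-set ids in ", path)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1L), 2L)
  sets
}

#' @rdname readGmt
#' @param sets named list of member-id vectors.
#' @export
writeGmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
    character(1L)), path)
  invisible(path)
}
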