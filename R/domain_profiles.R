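#' Default InterPro analysis roster
#'
#' The member-database analyses of the InterProScan 5.31-70.0 generation
#' (14 tools). Rosters drift across releases, so every function taking a
#' \code{tools} argument accepts any character vector.
#'
#' @return character vector of 14 analysis names.
#' @export
defaultToolset <- function() {
    c("CDD", "Gene3D", "HAMAP", "PANTHER", "Pfam", "PIRSF", "PRINTS",
      "ProDom", "ProSitePatterns", "ProSiteProfiles", "SFLD", "SMART",
      "SUPERFAMILY", "TIGRFAM")
}

#' Read InterProScan TSV domain annotations
#'
#' Uses the standard InterProScan TSV columns: 1 (protein accession),
#' 4 (analysis/tool), 5 (signature accession), 7 (start), 8 (stop);
#' coordinates are 1-based inclusive. Rows from analyses outside the
#' configured roster are ignored (a count is reported); exact duplicate
#' rows (same protein/tool/signature/start/stop) are collapsed.
#'
#' @param path path to an InterProScan \code{.tsv} file.
#' @param tools character vector of analyses to keep.
#' @return data.frame with columns \code{protein_id}, \code{tool},
#'   \code{signature}, \code{start}, \code{stop}.
#' @export
readInterproTsv <- function(path, tools = defaultToolset()) {
    if (!file.exists(path)) stop("InterPro TSV not found: ", path)
    emptyAnn <- data.frame(protein_id = character(), tool = character(),
                           signature = character(), start = integer(),
                           stop = integer(), stringsAsFactors = FALSE)
    if (file.size(path) == 0L) return(emptyAnn)
    raw <- utils::read.delim(path, header = FALSE, quote = "", fill = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(raw) < 8L)
        stop("expected >= 8 tab-separated columns (InterProScan TSV), got ",
             ncol(raw))
    start <- suppressWarnings(as.integer(raw[[7L]]))
    stop_ <- suppressWarnings(as.integer(raw[[8L]]))
    badNum <- which(is.na(start) | is.na(stop_))
    if (length(badNum))
        stop(sprintf("malformed InterPro row: non-numeric coordinates at line %d",
                     badNum[1L]))
    badRange <- which(start < 1L | start > stop_)
    if (length(badRange))
        stop(sprintf("malformed InterPro row: start %d > stop %d (or < 1) at line %d",
                     start[badRange[1L]], stop_[badRange[1L]], badRange[1L]))
    ann <- data.frame(protein_id = raw[[1L]], tool = raw[[4L]],
                      signature = raw[[5L]], start = start, stop = stop_,
                      stringsAsFactors = FALSE)
    off <- !(ann$tool %in% tools)
    if (any(off))
        message(sum(off), " InterPro row(s) ignored: analysis not in roster (",
                paste(unique(ann$tool[off]), collapse = ", "), ")")
    ann <- ann[!off, , drop = FALSE]
    ann <- unique(ann)
    rownames(ann) <- NULL
    ann
}

#' Ordered per-tool domain profiles
#'
#' For each protein and each tool, the signature accessions ordered by
#' their position on the amino-acid sequence: start ascending, then stop
#' ascending, then signature accession (a deterministic tie-break).
#' Proteins without annotations get an all-empty profile, so every protein
#' in \code{proteins} is representable.
#'
#' @param annotations data.frame from \code{\link{readInterproTsv}}.
#' @param proteins character vector of protein ids to cover.
#' @param tools character vector of analyses.
#' @return named list: protein id -> named list: tool -> character vector
#'   of ordered signature accessions.
#' @export
buildProfiles <- function(annotations, proteins, tools = defaultToolset()) {
    emptyProfile <- stats::setNames(
        rep(list(character()), length(tools)), tools)
    profiles <- stats::setNames(
        rep(list(emptyProfile), length(proteins)), proteins)
    ann <- annotations[annotations$protein_id %in% proteins, , drop = FALSE]
    if (!nrow(ann)) return(profiles)
    ann <- ann[order(ann$protein_id, ann$tool, ann$start, ann$stop,
                     ann$signature), , drop = FALSE]
    byProt <- split(ann, ann$protein_id)
    for (pid in names(byProt)) {
        byTool <- split(byProt[[pid]]$signature, byProt[[pid]]$tool)
        for (tool in names(byTool))
            profiles[[pid]][[tool]] <- byTool[[tool]]
    }
    profiles
}

#' Compare two ordered signature lists from one tool
#'
#' Labels, from strongest to weakest: \code{STONM} (same type, order and
#' number of motifs: the ordered lists are identical), \code{STNM} (same
#' type and number: identical as multisets), \code{STM} (same types: the
#' distinct-signature sets are identical, counts may differ), \code{NM}
#' (no match). \code{NP} (not present) is returned when at least one
#' protein has no prediction from the tool, including when both are empty,
#' and NP tools are skipped by the knowledge score rather than penalized.
#'
#' @param listA,listB character vectors of position-ordered signatures.
#' @return one of \code{"STONM"}, \code{"STNM"}, \code{"STM"}, \code{"NM"},
#'   \code{"NP"}.
#' @examples
#' compareToolProfiles(c("PF1", "PF2"), c("PF2", "PF1"))  # "STNM"
#' @export
compareToolProfiles <- function(listA, listB) {
    if (length(listA) == 0L || length(listB) == 0L) return("NP")
    if (length(listA) == length(listB)) {
        if (all(listA == listB)) return("STONM")
        if (identical(sort(listA), sort(listB))) return("STNM")
    }
    if (setequal(listA, listB)) return("STM")
    "NM"
}

#' Per-tool comparison labels for one protein pair
#'
#' @param profileA,profileB per-tool profiles (elements of
#'   \code{\link{buildProfiles}} output) built over the same tool roster.
#' @param tools character vector of analyses (label order).
#' @return named character vector, one label per tool.
#' @export
comparePair <- function(profileA, profileB, tools = defaultToolset()) {
    if (!all(tools %in% names(profileA)) || !all(tools %in% names(profileB)))
        stop("profiles were not built over the requested tool roster")
    vapply(tools,
           function(t) compareToolProfiles(profileA[[t]], profileB[[t]]),
           character(1))
}

#' Comparison labels for a table of pairs
#'
#' Pairs whose proteins carry no annotations (or are absent from
#' \code{profiles}) get all-NP labels, as required for proteins with no
#' InterPro prediction.
#'
#' @param profiles output of \code{\link{buildProfiles}}.
#' @param pairs data.frame with columns \code{protein_a}, \code{protein_b}.
#' @param tools character vector of analyses.
#' @return character matrix, rows aligned with \code{pairs}, one column per
#'   tool.
#' @export
compareAllPairs <- function(profiles, pairs, tools = defaultToolset()) {
    emptyProfile <- stats::setNames(
        rep(list(character()), length(tools)), tools)
    getProfile <- function(pid) {
        p <- profiles[[pid]]
        if (is.null(p)) emptyProfile else p
    }
    labels <- matrix(NA_character_, nrow = nrow(pairs),
                     ncol = length(tools),
                     dimnames = list(NULL, tools))
    for (i in seq_len(nrow(pairs)))
        labels[i, ] <- comparePair(getProfile(pairs$protein_a[[i]]),
                                   getProfile(pairs$protein_b[[i]]), tools)
    labels
}

#' Write per-pair tool labels as TSV
#' @param pairs data.frame with \code{protein_a}, \code{protein_b}.
#' @param labels matrix from \code{\link{compareAllPairs}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePairLabelsTsv <- function(pairs, labels, path) {
    out <- cbind(pairs[, c("protein_a", "protein_b")],
                 as.data.frame(labels, stringsAsFactors = FALSE))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
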