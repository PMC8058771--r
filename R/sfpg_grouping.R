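#' Form similar-function protein groups at a cutoff
#'
#' For every transcript \code{t} in the universe, its group is
#' \code{{t} union {u : score(t, u) >= csc}}. Groups are per-seed
#' neighborhoods and are deliberately not merged into connected
#' components: merging semi-overlapping neighborhoods would create
#' false-positive groups and lose specialized functions. Transcripts with
#' no qualifying partner become singleton groups so that expression
#' redistribution covers the whole universe.
#'
#' @param scores data.frame from \code{\link{scoreAllPairs}}; pair ids are
#'   taken from \code{transcript_a}/\code{transcript_b} when present,
#'   otherwise \code{protein_a}/\code{protein_b}.
#' @param csc confidence-score cutoff, a positive integer <= 100
#'   (default 95).
#' @param scoreType \code{"KS"} (default) or \code{"DS"}.
#' @param universe character vector of transcript ids to seed groups for
#'   (the kept protein-coding transcripts).
#' @param dedup if \code{TRUE}, groups with identical member sets are
#'   collapsed, keeping the lexicographically smallest seed as id
#'   (default \code{FALSE}: one group per seed).
#' @return an \linkS4class{SFPGSet}.
#' @examples
#' sc <- data.frame(protein_a = "A", protein_b = "B", KS = 97, DS = 99)
#' groups(buildGroups(sc, csc = 95, universe = c("A", "B", "C")))
#' @export
buildGroups <- function(scores, csc = 95L, scoreType = c("KS", "DS"),
                        universe, dedup = FALSE) {
    scoreType <- match.arg(scoreType)
    if (length(csc) != 1L || is.na(csc) || csc != round(csc) ||
        csc < 1 || csc > 100)
        stop("csc must be a positive integer <= 100, got: ", csc)
    csc <- as.integer(csc)
    universe <- unique(as.character(universe))
    idA <- if ("transcript_a" %in% names(scores)) scores$transcript_a
           else scores$protein_a
    idB <- if ("transcript_b" %in% names(scores)) scores$transcript_b
           else scores$protein_b
    ok <- scores[[scoreType]] >= csc
    edges <- data.frame(a = idA[ok], b = idB[ok], stringsAsFactors = FALSE)
    nb <- .neighborLists(edges)
    groupList <- lapply(universe, function(t)
        sort(unique(c(t, nb[[t]]))))
    names(groupList) <- universe
    if (dedup) {
        key <- vapply(groupList, paste, character(1), collapse = "\r")
        ord <- order(names(groupList))
        groupList <- groupList[ord][!duplicated(key[ord])]
    }
    new("SFPGSet", groups = groupList,
        membership = .invertGroups(groupList),
        cutoff = csc, scoreType = scoreType)
}

.neighborLists <- function(edges) {
    if (!nrow(edges)) return(list())
    both <- data.frame(t = c(edges$a, edges$b), u = c(edges$b, edges$a),
                       stringsAsFactors = FALSE)
    lapply(split(both$u, both$t), unique)
}

#' Summary statistics of an SFPG set
#'
#' The quantities behind the pair/group characterization plots: number of
#' groups, number of non-singleton groups, and the mean, median, maximum
#' and total of group sizes.
#'
#' @param sfpgs an \linkS4class{SFPGSet}.
#' @return a one-row data.frame.
#' @export
groupStats <- function(sfpgs) {
    stopifnot(is(sfpgs, "SFPGSet"))
    sz <- lengths(sfpgs@groups)
    data.frame(n_groups = length(sz),
               n_non_singleton = sum(sz > 1L),
               size_mean = if (length(sz)) mean(sz) else NA_real_,
               size_median = if (length(sz)) stats::median(sz) else NA_real_,
               size_max = if (length(sz)) max(sz) else 0L,
               size_total = sum(sz))
}

#' Count qualifying pairs by gene-name origin
#'
#' Classifies every pair at or above the cutoff by the origin of its gene
#' symbols (same gene, same gene family, different gene family, undefined;
#' see \code{\link{categorizePair}}) and counts each category.
#'
#' @param scores data.frame from \code{\link{scoreAllPairs}}.
#' @param catalog a \linkS4class{ProteinCatalog} providing gene symbols.
#' @param csc confidence-score cutoff.
#' @param scoreType \code{"KS"} or \code{"DS"}.
#' @return named integer vector over the four categories.
#' @export
categorizePairsReport <- function(scores, catalog, csc = 95L,
                                  scoreType = c("KS", "DS")) {
    scoreType <- match.arg(scoreType)
    stopifnot(is(catalog, "ProteinCatalog"))
    cats <- c("same_gene", "same_gene_family", "different_gene_family",
              "undefined")
    q <- scores[scores[[scoreType]] >= csc, , drop = FALSE]
    if (!nrow(q)) return(stats::setNames(rep(0L, 4L), cats))
    sym <- stats::setNames(catalog@records$gene_symbol,
                           catalog@records$protein_id)
    got <- categorizePair(unname(sym[q$protein_a]),
                          unname(sym[q$protein_b]))
    counts <- table(factor(got, levels = cats))
    stats::setNames(as.integer(counts), cats)
}

#' Write SFPGs and their membership index as TSV
#'
#' \code{groupsPath} gets one row per group (\code{group_id}, \code{size},
#' comma-joined members); \code{membershipPath} one row per transcript
#' (\code{transcript_id}, \code{n_groups}, comma-joined group ids).
#'
#' @param sfpgs an \linkS4class{SFPGSet}.
#' @param groupsPath,membershipPath output paths.
#' @return invisibly, c(groupsPath, membershipPath).
#' @export
writeGroupsTsv <- function(sfpgs, groupsPath, membershipPath) {
    stopifnot(is(sfpgs, "SFPGSet"))
    g <- data.frame(group_id = names(sfpgs@groups),
                    size = lengths(sfpgs@groups),
                    members = vapply(sfpgs@groups, paste, character(1),
                                     collapse = ","),
                    stringsAsFactors = FALSE)
    utils::write.table(g, groupsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    m <- data.frame(transcript_id = names(sfpgs@membership),
                    n_groups = lengths(sfpgs@membership),
                    group_ids = vapply(sfpgs@membership, paste, character(1),
                                       collapse = ","),
                    stringsAsFactors = FALSE)
    utils::write.table(m, membershipPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(groupsPath, membershipPath))
}
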