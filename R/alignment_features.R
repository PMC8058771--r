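#' Read BLAST+ tabular (outfmt 6) protein hits
#'
#' Parses the standard 12-column tabular output (query, subject, percent
#' identity, alignment length, mismatches, gap openings, coordinates,
#' e-value, bit score); extra trailing columns are tolerated and ignored.
#' Hits whose query or subject does not resolve in the catalog's kept
#' records are skipped (a count is reported via \code{message}); self hits
#' are dropped.
#'
#' The "number of gaps" consumed downstream by the gap score is column 6
#' (gap openings), the gap field standard tabular output always provides.
#'
#' @param path path to a BLAST+ outfmt 6 TSV.
#' @param catalog a \linkS4class{ProteinCatalog} used to resolve accessions.
#' @return data.frame of hits with columns \code{query_id}, \code{subject_id},
#'   \code{pident}, \code{aln_length}, \code{mismatches}, \code{gap_count},
#'   \code{evalue}, \code{bitscore}.
#' @export
readBlastTab <- function(path, catalog) {
    stopifnot(is(catalog, "ProteinCatalog"))
    if (!file.exists(path)) stop("BLAST file not found: ", path)
    raw <- utils::read.delim(path, header = FALSE, quote = "",
                             stringsAsFactors = FALSE,
                             colClasses = "character",
                             comment.char = "#")
    if (ncol(raw) < 12L)
        stop("expected >= 12 tab-separated columns (BLAST outfmt 6), got ",
             ncol(raw))
    num <- function(col, what) {
        v <- suppressWarnings(as.numeric(raw[[col]]))
        bad <- which(is.na(v) & !is.na(raw[[col]]))
        if (length(bad))
            stop(sprintf("malformed BLAST row: non-numeric %s '%s' at line %d",
                         what, raw[[col]][bad[1L]], bad[1L]))
        v
    }
    hits <- data.frame(
        query_id = raw[[1L]], subject_id = raw[[2L]],
        pident = num(3L, "percent identity"),
        aln_length = num(4L, "alignment length"),
        mismatches = num(5L, "mismatch count"),
        gap_count = num(6L, "gap count"),
        evalue = num(11L, "evalue"), bitscore = num(12L, "bitscore"),
        stringsAsFactors = FALSE)
    bad <- which(hits$pident < 0 | hits$pident > 100 | hits$aln_length < 1 |
                 hits$gap_count < 0)
    if (length(bad))
        stop(sprintf("malformed BLAST row: out-of-range values at line %d",
                     bad[1L]))
    known <- catalog@records$protein_id
    unresolved <- !(hits$query_id %in% known & hits$subject_id %in% known)
    if (any(unresolved))
        message(sum(unresolved),
                " BLAST hit(s) skipped: accession not in catalog kept records")
    hits <- hits[!unresolved, , drop = FALSE]
    hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Reduce hits to the single best hit per unordered pair
#'
#' Reciprocal hits and multiple HSPs for the same protein pair are
#' symmetrized to one representative: the hit with maximal bit score, ties
#' broken by lower e-value, then higher percent identity, then first
#' occurrence in the file. This makes the pair table deterministic and
#' independent of query/subject orientation.
#'
#' @param hits data.frame from \code{\link{readBlastTab}}.
#' @return data.frame with one row per unordered pair.
#' @export
bestHitPerPair <- function(hits) {
    if (!nrow(hits)) return(hits)
    key <- paste(pmin(hits$query_id, hits$subject_id),
                 pmax(hits$query_id, hits$subject_id), sep = "\r")
    ord <- order(key, -hits$bitscore, hits$evalue, -hits$pident,
                 seq_len(nrow(hits)))
    picked <- hits[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    rownames(picked) <- NULL
    picked
}

#' Alignment features per unordered protein pair
#'
#' Converts best hits into the per-pair feature records the confidence
#' scores consume: percent identity, alignment length, gap count, and the
#' two full sequence lengths. Lengths come from the FASTA catalog (which is
#' authoritative), not from BLAST columns. Pair members are stored sorted
#' lexicographically, so downstream scoring cannot depend on orientation.
#'
#' @param hits data.frame of (best) hits.
#' @param catalog a \linkS4class{ProteinCatalog}.
#' @return data.frame with columns \code{protein_a}, \code{protein_b},
#'   \code{pident}, \code{aln_length}, \code{gap_count}, \code{len_a},
#'   \code{len_b}.
#' @export
pairFeatures <- function(hits, catalog) {
    stopifnot(is(catalog, "ProteinCatalog"))
    lens <- stats::setNames(catalog@records$seq_length,
                            catalog@records$protein_id)
    a <- pmin(hits$query_id, hits$subject_id)
    b <- pmax(hits$query_id, hits$subject_id)
    if (anyNA(lens[a]) || anyNA(lens[b])) {
        missing <- unique(c(a, b)[is.na(lens[c(a, b)])])
        stop("accession(s) not in catalog kept records: ",
             paste(missing, collapse = ", "))
    }
    data.frame(protein_a = a, protein_b = b,
               pident = hits$pident, aln_length = hits$aln_length,
               gap_count = hits$gap_count,
               len_a = unname(lens[a]), len_b = unname(lens[b]),
               stringsAsFactors = FALSE)
}

#' One-call feature extraction from a BLAST tabular file
#'
#' \code{readBlastTab} + \code{bestHitPerPair} + \code{pairFeatures}.
#'
#' @inheritParams readBlastTab
#' @return see \code{\link{pairFeatures}}.
#' @export
alignmentFeatures <- function(path, catalog) {
    pairFeatures(bestHitPerPair(readBlastTab(path, catalog)), catalog)
}

#' Write pair features as TSV
#' @param features data.frame from \code{\link{pairFeatures}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePairFeaturesTsv <- function(features, path) {
    utils::write.table(features, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
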