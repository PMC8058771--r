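#' Read a transcript count matrix and effective lengths
#'
#' \code{countsPath}: TSV whose first column is the transcript id and
#' remaining columns are per-sample raw counts. \code{lengthsPath}: TSV
#' with columns \code{transcript_id} and \code{effective_length}. Every
#' transcript in the count matrix must have an effective length.
#'
#' @param countsPath,lengthsPath input TSV paths.
#' @return list with \code{counts} (numeric matrix, transcripts x samples)
#'   and \code{effLength} (named numeric vector).
#' @export
readCountsTsv <- function(countsPath, lengthsPath) {
    cdf <- utils::read.delim(countsPath, stringsAsFactors = FALSE,
                             check.names = FALSE)
    counts <- as.matrix(cdf[, -1L, drop = FALSE])
    rownames(counts) <- as.character(cdf[[1L]])
    storage.mode(counts) <- "double"
    if (any(counts < 0)) stop("negative raw counts")
    ldf <- utils::read.delim(lengthsPath, stringsAsFactors = FALSE)
    effLength <- stats::setNames(as.numeric(ldf$effective_length),
                                 as.character(ldf$transcript_id))
    missing <- setdiff(rownames(counts), names(effLength))
    if (length(missing))
        stop("transcripts without an effective length: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    list(counts = counts, effLength = effLength[rownames(counts)])
}

#' Read RSEM-style isoforms.results tables
#'
#' One file per sample with (at least) columns \code{transcript_id},
#' \code{effective_length} and \code{expected_count}. Effective lengths are
#' taken from the first file.
#'
#' @param paths character vector of per-sample isoform tables.
#' @param sampleNames sample names (default: file base names).
#' @return as \code{\link{readCountsTsv}}.
#' @export
readRsemIsoforms <- function(paths, sampleNames = NULL) {
    if (is.null(sampleNames))
        sampleNames <- sub("\\.isoforms\\.results$", "", basename(paths))
    tabs <- lapply(paths, utils::read.delim, stringsAsFactors = FALSE)
    ids <- tabs[[1L]]$transcript_id
    counts <- vapply(tabs, function(t) {
        if (!identical(t$transcript_id, ids))
            stop("isoform tables do not share one transcript order")
        as.numeric(t$expected_count)
    }, numeric(length(ids)))
    dimnames(counts) <- list(ids, sampleNames)
    list(counts = counts,
         effLength = stats::setNames(as.numeric(tabs[[1L]]$effective_length),
                                     ids))
}

#' Median-of-ratios per-sample size factors
#'
#' The default size-factor estimator of count-based differential
#' expression: the reference is the per-transcript geometric mean across
#' samples (computed in log space, over transcripts whose counts are
#' positive in every sample), and each sample's factor is the median of
#' its count/reference ratios. Agrees with
#' \code{DESeq2::estimateSizeFactorsForMatrix} up to that function's
#' geometric interpolation of even-length medians.
#'
#' @param counts numeric matrix, transcripts x samples (>= 2 samples).
#' @return named numeric vector of positive per-sample factors; divide raw
#'   counts by these to normalize.
#' @export
medianOfRatiosFactors <- function(counts) {
    counts <- as.matrix(counts)
    if (ncol(counts) < 2L)
        stop("need >= 2 samples for median-of-ratios factors")
    keep <- rowSums(counts > 0) == ncol(counts)
    if (!any(keep))
        stop("no transcript has nonzero counts in every sample; ",
             "a pseudo-reference fallback is not implemented")
    ref <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
    sf <- apply(counts[keep, , drop = FALSE], 2L,
                function(col) stats::median(col / ref))
    stats::setNames(as.numeric(sf), colnames(counts))
}

#' Normalized FPKM from counts and effective lengths
#'
#' Raw counts are divided by the per-sample size factors, then converted to
#' FPKM with the per-transcript effective length:
#' \deqn{FPKM_{tj} = n_{tj} \cdot 10^9 / (L_t \cdot \sum_t n_{tj})}
#' where \eqn{n} is the normalized count and the library size
#' \eqn{\sum_t n_{tj}} runs over transcripts with a positive effective
#' length. Transcripts with effective length 0 (shorter than the fragment
#' length) get FPKM 0 and are excluded from the library size; an all-zero
#' sample yields an all-zero column.
#'
#' @param counts numeric matrix, transcripts x samples.
#' @param effLength named numeric vector covering all transcripts.
#' @param factors per-sample size factors (default: computed from
#'   \code{counts} by \code{\link{medianOfRatiosFactors}}).
#' @return list with \code{fpkm} (matrix) and \code{sizeFactors}.
#' @export
toFPKM <- function(counts, effLength,
                   factors = medianOfRatiosFactors(counts)) {
    counts <- as.matrix(counts)
    effLength <- effLength[rownames(counts)]
    if (anyNA(effLength))
        stop("every transcript needs an effective length")
    if (any(effLength < 0)) stop("negative effective length")
    nz <- sum(effLength == 0)
    if (nz > 0)
        message(nz, " transcript(s) with effective length 0 set to FPKM 0")
    norm <- sweep(counts, 2L, factors, "/")
    lib <- colSums(norm[effLength > 0, , drop = FALSE])
    fpkm <- matrix(0, nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
    usable <- effLength > 0
    okSample <- lib > 0
    if (any(usable) && any(okSample)) {
        denom <- outer(effLength[usable], lib[okSample])
        fpkm[usable, okSample] <- norm[usable, okSample, drop = FALSE] *
            1e9 / denom
    }
    list(fpkm = fpkm, sizeFactors = factors)
}

.redistribute <- function(fpkm, sfpgs, weightFun, method) {
    stopifnot(is(sfpgs, "SFPGSet"))
    fpkm <- as.matrix(fpkm)
    members <- unique(unlist(sfpgs@groups, use.names = FALSE))
    missing <- setdiff(members, rownames(fpkm))
    if (length(missing))
        stop("group member(s) without an expression row: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    nGroups <- lengths(sfpgs@membership)
    if (any(nGroups[members] == 0L) || anyNA(nGroups[members]))
        stop("group member(s) with empty membership index")
    sizes <- lengths(sfpgs@groups)
    out <- matrix(0, length(sfpgs@groups), ncol(fpkm),
                  dimnames = list(names(sfpgs@groups), colnames(fpkm)))
    for (i in seq_along(sfpgs@groups)) {
        m <- sfpgs@groups[[i]]
        w <- weightFun(m, sizes[[i]])
        out[i, ] <- colSums(fpkm[m, , drop = FALSE] * w)
    }
    attr(out, "method") <- method
    out
}

#' Group expression by equal distribution (ED)
#'
#' Each member transcript's FPKM is split equally among all the groups it
#' belongs to: a member of \eqn{k} groups contributes \eqn{FPKM/k} to each.
#' Per sample, total expression is conserved exactly.
#'
#' @param fpkm FPKM matrix (transcripts x samples), e.g.
#'   \code{toFPKM(...)$fpkm}.
#' @param sfpgs an \linkS4class{SFPGSet} whose members all have expression
#'   rows.
#' @return group x sample matrix with attribute \code{method = "ED"}.
#' @export
recalcED <- function(fpkm, sfpgs) {
    nGroups <- lengths(sfpgs@membership)
    .redistribute(fpkm, sfpgs,
                  function(m, size) 1 / unname(nGroups[m]), "ED")
}

#' Group expression by group-size distribution (GD)
#'
#' Each member's FPKM is split among its groups proportionally to group
#' size, modeling genetic redundancy (bigger groups carry more conserved
#' function): a member of groups with sizes \eqn{s_1..s_k} contributes
#' \eqn{FPKM \cdot s_g / \sum_h s_h} to group \eqn{g}. Per sample, total
#' expression is conserved exactly; when all of a member's groups share one
#' size, GD equals ED.
#'
#' @inheritParams recalcED
#' @return group x sample matrix with attribute \code{method = "GD"}.
#' @export
recalcGD <- function(fpkm, sfpgs) {
    sizes <- lengths(sfpgs@groups)
    sizeSum <- vapply(sfpgs@membership,
                      function(g) sum(sizes[g]), numeric(1))
    .redistribute(fpkm, sfpgs,
                  function(m, size) size / unname(sizeSum[m]), "GD")
}

#' Final output matrix: group rows plus passthrough transcripts
#'
#' Excluded-biotype transcripts take no part in grouping but are retained
#' with their original FPKM as passthrough rows, so per-sample totals over
#' the output equal per-sample totals over all transcripts.
#'
#' @param groupExpr matrix from \code{\link{recalcED}} / \code{\link{recalcGD}}.
#' @param fpkm full FPKM matrix (must contain the passthrough rows).
#' @param passthroughIds transcript ids to append with their own FPKM
#'   (must be disjoint from group ids).
#' @return row-bound matrix carrying the \code{method} attribute.
#' @export
assembleOutput <- function(groupExpr, fpkm, passthroughIds = character()) {
    passthroughIds <- unique(as.character(passthroughIds))
    clash <- intersect(passthroughIds, rownames(groupExpr))
    if (length(clash))
        stop("passthrough id(s) collide with group ids: ",
             paste(utils::head(clash, 5L), collapse = ", "))
    missing <- setdiff(passthroughIds, rownames(fpkm))
    if (length(missing))
        stop("passthrough id(s) without an expression row: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    out <- rbind(groupExpr,
                 as.matrix(fpkm)[passthroughIds, , drop = FALSE])
    attr(out, "method") <- attr(groupExpr, "method")
    out
}

#' Write an expression matrix as TSV
#'
#' @param mat matrix with row ids (group or transcript ids); a
#'   \code{method} attribute, if present, is written into a column.
#' @param path output path.
#' @param idColumn name for the id column.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTsv <- function(mat, path, idColumn = "id") {
    df <- data.frame(id = rownames(mat), as.data.frame(mat),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1L] <- idColumn
    method <- attr(mat, "method")
    if (!is.null(method)) df$method <- rep(method, nrow(df))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
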