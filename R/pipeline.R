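#' Run the full functional-grouping pipeline
#'
#' FASTA to group expression in one call: parse the protein catalog, apply
#' biotype exclusions, reduce BLAST hits to per-pair alignment features,
#' build ordered per-tool domain profiles and comparison labels, score all
#' aligned pairs (DS and KS), form SFPGs at the cutoff, normalize the raw
#' counts (median-of-ratios, then FPKM via effective length) and
#' redistribute expression to groups, passing excluded-biotype transcripts
#' through with their original FPKM. Transcripts present in the count
#' matrix but absent from the kept catalog (excluded biotypes or unknown
#' ids) are passed through unchanged, so per-sample totals are conserved.
#'
#' @param fastaPath Ensembl-style peptide FASTA.
#' @param blastPath BLAST+ outfmt 6 TSV of all-vs-all protein hits.
#' @param interproPath InterProScan TSV.
#' @param countsPath transcript x sample raw-count TSV.
#' @param lengthsPath transcript effective-length TSV.
#' @param csc confidence-score cutoff (positive integer <= 100, default 95).
#' @param scoreType \code{"KS"} (default) or \code{"DS"}.
#' @param method expression redistribution, \code{"GD"} (default) or
#'   \code{"ED"}.
#' @param scheme a \linkS4class{ScoringScheme}, a YAML path, or \code{NULL}
#'   for defaults.
#' @param tools InterPro analysis roster.
#' @param exclusions biotype exclusion patterns.
#' @param dedup collapse duplicated member sets (see
#'   \code{\link{buildGroups}}).
#' @param outDir if non-NULL, write all result TSVs there.
#' @return list with \code{catalog}, \code{features}, \code{labels},
#'   \code{scores}, \code{sfpgs}, \code{fpkm}, \code{sizeFactors},
#'   \code{groupExpr} and the final \code{output} matrix (group rows +
#'   passthrough rows).
#' @export
runPipeline <- function(fastaPath, blastPath, interproPath, countsPath,
                        lengthsPath, csc = 95L, scoreType = c("KS", "DS"),
                        method = c("GD", "ED"), scheme = NULL,
                        tools = defaultToolset(),
                        exclusions = defaultBiotypeExclusions(),
                        dedup = FALSE, outDir = NULL) {
    scoreType <- match.arg(scoreType)
    method <- match.arg(method)
    if (!is(scheme, "ScoringScheme"))
        scheme <- loadScoringScheme(scheme, tools)

    catalog <- filterByBiotype(readProteinFasta(fastaPath), exclusions)
    kept <- keptRecords(catalog)

    features <- alignmentFeatures(blastPath, catalog)
    annotations <- readInterproTsv(interproPath, tools)
    profiles <- buildProfiles(annotations, kept$protein_id, tools)
    labels <- compareAllPairs(profiles, features, tools)
    scores <- scoreAllPairs(features, labels, scheme, catalog)

    cd <- readCountsTsv(countsPath, lengthsPath)
    missingExpr <- setdiff(kept$transcript_id, rownames(cd$counts))
    if (length(missingExpr))
        stop("kept transcript(s) without counts: ",
             paste(utils::head(missingExpr, 5L), collapse = ", "))
    norm <- toFPKM(cd$counts, cd$effLength)

    sfpgs <- buildGroups(scores, csc = csc, scoreType = scoreType,
                         universe = kept$transcript_id, dedup = dedup)
    groupExpr <- if (method == "GD") recalcGD(norm$fpkm, sfpgs)
                 else recalcED(norm$fpkm, sfpgs)
    passthrough <- setdiff(rownames(cd$counts), kept$transcript_id)
    output <- assembleOutput(groupExpr, norm$fpkm, passthrough)

    res <- list(catalog = catalog, features = features, labels = labels,
                scores = scores, sfpgs = sfpgs, fpkm = norm$fpkm,
                sizeFactors = norm$sizeFactors, groupExpr = groupExpr,
                output = output, method = method)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeCatalogTsv(catalog, file.path(outDir, "catalog.tsv"))
        writePairFeaturesTsv(features, file.path(outDir, "pair_features.tsv"))
        writePairLabelsTsv(features, labels,
                           file.path(outDir, "pair_labels.tsv"))
        writePairScoresTsv(scores, file.path(outDir, "pair_scores.tsv"))
        writeGroupsTsv(sfpgs, file.path(outDir, "groups.tsv"),
                       file.path(outDir, "membership.tsv"))
        utils::write.table(groupStats(sfpgs),
                           file.path(outDir, "group_stats.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeExpressionTsv(norm$fpkm,
                           file.path(outDir, "normalized_fpkm.tsv"),
                           idColumn = "transcript_id")
        writeExpressionTsv(output,
                           file.path(outDir, "group_expression.tsv"),
                           idColumn = "group_id")
    }
    res
}
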