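#' Default scoring scheme
#'
#' Implementation defaults (configurable, not canonical values): identity
#' weight 100, coverage weight 50, gap weight -50; for every tool the label
#' weights are STONM 10, STNM 6, STM 3, NM 0. Every scoring invariant
#' (identity bound, label monotonicity, NP neutrality) holds for any valid
#' scheme, so conclusions do not hinge on these numbers.
#'
#' @param tools character vector of tool names for the per-tool weights.
#' @return a \linkS4class{ScoringScheme}.
#' @export
defaultScoringScheme <- function(tools = defaultToolset()) {
    tw <- matrix(rep(c(10, 6, 3, 0), each = length(tools)),
                 nrow = length(tools),
                 dimnames = list(tools, .SCORED_LABELS))
    new("ScoringScheme", identityWeight = 100, coverageWeight = 50,
        gapWeight = -50, toolWeights = tw)
}

#' Load a scoring scheme from a config document
#'
#' Accepts a YAML file path or an already-parsed list with keys
#' \code{identity_weight}, \code{coverage_weight}, \code{gap_weight} and
#' \code{tool_weights}. \code{tool_weights} is either one label->weight
#' mapping applied to every tool, or a tool->(label->weight) mapping.
#' Missing keys (or \code{config = NULL}) fall back to
#' \code{\link{defaultScoringScheme}} values. Invalid weights (positive gap
#' weight, non-monotone label weights) are an error via class validity.
#'
#' @param config path to a YAML file, a list, or \code{NULL}.
#' @param tools tool roster for the scheme.
#' @return a validated \linkS4class{ScoringScheme}.
#' @export
loadScoringScheme <- function(config = NULL, tools = defaultToolset()) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("scheme config not found: ", config)
        config <- yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
    stopifnot(is.list(config))
    base <- defaultScoringScheme(tools)
    iw <- config$identity_weight %||% base@identityWeight
    cw <- config$coverage_weight %||% base@coverageWeight
    gw <- config$gap_weight %||% base@gapWeight
    tw <- base@toolWeights
    cfgTw <- config$tool_weights
    if (!is.null(cfgTw)) {
        if (all(names(cfgTw) %in% .SCORED_LABELS)) {
            for (lab in names(cfgTw))
                tw[, lab] <- as.numeric(cfgTw[[lab]])
        } else {
            for (tool in names(cfgTw)) {
                if (!tool %in% tools)
                    stop("tool_weights names a tool outside the roster: ", tool)
                for (lab in names(cfgTw[[tool]]))
                    tw[tool, lab] <- as.numeric(cfgTw[[tool]][[lab]])
            }
        }
    }
    new("ScoringScheme", identityWeight = as.numeric(iw),
        coverageWeight = as.numeric(cw), gapWeight = as.numeric(gw),
        toolWeights = tw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Alignment score components (AIS, ACS, AGS)
#'
#' From per-pair alignment features and a scheme:
#' \deqn{AIS = pident \cdot w_{id} / 100}
#' \deqn{ACS = (w_{cov}/100) \sum_{i \in \{a,b\}} (100 - 100\, len_i / aln)}
#' \deqn{AGS = gaps \cdot w_{gap} / 100}
#' The coverage sum runs over the two sequences of the pair; a local
#' alignment much shorter than the sequences drives ACS strongly negative,
#' while an alignment longer than a sequence (gapped) contributes a
#' positive term, which is applied literally.
#'
#' @param features data.frame from \code{\link{pairFeatures}} (vectorized
#'   over rows).
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return data.frame with columns \code{AIS}, \code{ACS}, \code{AGS}.
#' @export
alignmentComponents <- function(features, scheme) {
    stopifnot(is(scheme, "ScoringScheme"))
    if (any(features$aln_length < 1))
        stop("aln_length must be >= 1")
    # iw * (pident/100), not (pident*iw)/100: keeps AIS == iw exact at
    # pident 100 so the identity bound DS = KS = 100 holds to the bit
    AIS <- scheme@identityWeight * (features$pident / 100)
    ACS <- (scheme@coverageWeight / 100) *
        ((100 - 100 * features$len_a / features$aln_length) +
         (100 - 100 * features$len_b / features$aln_length))
    AGS <- features$gap_count * scheme@gapWeight / 100
    data.frame(AIS = AIS, ACS = ACS, AGS = AGS)
}

#' Discovery score (DS)
#'
#' The lenient confidence score from alignment evidence only:
#' \deqn{DS = clamp\big((AIS + ACS + AGS) \cdot 100 / maxAIS,\ 0,\ 100\big)}
#' where \eqn{maxAIS} is the identity weight (attained at 100\% identity).
#' A perfect self-alignment scores exactly 100.
#'
#' @inheritParams alignmentComponents
#' @return numeric vector of DS values in [0, 100].
#' @export
discoveryScore <- function(features, scheme) {
    comp <- alignmentComponents(features, scheme)
    raw <- (comp$AIS + comp$ACS + comp$AGS) / scheme@identityWeight * 100
    pmin(pmax(raw, 0), 100)
}

#' Knowledge score (KS)
#'
#' The stringent confidence score adding per-tool domain-comparison
#' weights. NP tools (no prediction for at least one protein) are skipped
#' in both the sum and its attainable maximum, so missing predictions are
#' neutral rather than penalizing:
#' \deqn{ITCS = \sum_{t:\ label_t \ne NP} w_t(label_t)}
#' \deqn{KS = clamp\Big((AIS + ACS + AGS + ITCS) \cdot
#'   \frac{100}{w_{id} + \sum_{t:\ label_t \ne NP} w_t(STONM)},\ 0,\ 100\Big)}
#' When every tool is NP there is no domain evidence at all and KS falls
#' back to DS. The denominator includes the identity weight so that
#' identical proteins with identical annotations score exactly 100; the
#' attainable maximum of the numerator is the natural normalizer for a
#' score bounded by 100.
#'
#' @inheritParams alignmentComponents
#' @param labels character matrix from \code{\link{compareAllPairs}}, rows
#'   aligned with \code{features}.
#' @return data.frame with columns \code{ITCS}, \code{max_itcs_nonNP},
#'   \code{KS}.
#' @export
knowledgeScore <- function(features, labels, scheme) {
    stopifnot(is(scheme, "ScoringScheme"))
    labels <- as.matrix(labels)
    if (nrow(labels) != nrow(features))
        stop("labels rows must align with features rows")
    tools <- rownames(scheme@toolWeights)
    if (!all(colnames(labels) %in% tools))
        stop("labels name tools missing from the scheme: ",
             paste(setdiff(colnames(labels), tools), collapse = ", "))
    tw <- scheme@toolWeights
    itcs <- numeric(nrow(labels))
    maxItcs <- numeric(nrow(labels))
    for (tool in colnames(labels)) {
        lab <- labels[, tool]
        nonNP <- lab != "NP"
        if (any(!lab %in% .COMPARISON_LABELS))
            stop("invalid comparison label(s): ",
                 paste(unique(lab[!lab %in% .COMPARISON_LABELS]),
                       collapse = ", "))
        w <- numeric(length(lab))
        w[nonNP] <- tw[tool, ][lab[nonNP]]
        itcs <- itcs + w
        maxItcs <- maxItcs + ifelse(nonNP, tw[tool, "STONM"], 0)
    }
    comp <- alignmentComponents(features, scheme)
    raw <- (comp$AIS + comp$ACS + comp$AGS + itcs) /
        (scheme@identityWeight + maxItcs) * 100
    ks <- pmin(pmax(raw, 0), 100)
    allNP <- rowSums(labels != "NP") == 0L
    if (any(allNP))
        ks[allNP] <- discoveryScore(features[allNP, , drop = FALSE], scheme)
    data.frame(ITCS = itcs, max_itcs_nonNP = maxItcs, KS = ks)
}

#' Score all aligned pairs
#'
#' One score record per aligned pair (pairs without a BLAST hit are
#' unaligned and therefore unscored). Pairs without InterPro annotations
#' must arrive with all-NP label rows (as \code{\link{compareAllPairs}}
#' produces). If a catalog is given, transcript ids are attached so the
#' grouping stage can work in transcript space. The number of pairs whose
#' raw score fell outside [0, 100] and was clamped is reported via
#' \code{message}.
#'
#' @param features data.frame of per-pair alignment features.
#' @param labels character matrix of per-pair, per-tool comparison labels.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param catalog optional \linkS4class{ProteinCatalog} for transcript ids.
#' @return data.frame with pair ids, AIS/ACS/AGS/ITCS components,
#'   \code{max_ais}, \code{max_itcs_nonNP}, \code{DS} and \code{KS}.
#' @export
scoreAllPairs <- function(features, labels, scheme, catalog = NULL) {
    comp <- alignmentComponents(features, scheme)
    ds <- discoveryScore(features, scheme)
    ksPart <- knowledgeScore(features, labels, scheme)
    rawDS <- (comp$AIS + comp$ACS + comp$AGS) / scheme@identityWeight * 100
    rawKS <- (comp$AIS + comp$ACS + comp$AGS + ksPart$ITCS) /
        (scheme@identityWeight + ksPart$max_itcs_nonNP) * 100
    nClamped <- sum(rawDS < 0 | rawDS > 100 | rawKS < 0 | rawKS > 100)
    if (nClamped > 0)
        message(nClamped, " pair score(s) clamped to [0, 100]")
    out <- data.frame(protein_a = features$protein_a,
                      protein_b = features$protein_b,
                      stringsAsFactors = FALSE)
    if (!is.null(catalog)) {
        tx <- stats::setNames(catalog@records$transcript_id,
                              catalog@records$protein_id)
        out$transcript_a <- unname(tx[out$protein_a])
        out$transcript_b <- unname(tx[out$protein_b])
    }
    out$AIS <- comp$AIS
    out$ACS <- comp$ACS
    out$AGS <- comp$AGS
    out$ITCS <- ksPart$ITCS
    out$max_ais <- rep(scheme@identityWeight, nrow(out))
    out$max_itcs_nonNP <- ksPart$max_itcs_nonNP
    out$DS <- ds
    out$KS <- ksPart$KS
    out
}

#' Write pair scores as TSV
#' @param scores data.frame from \code{\link{scoreAllPairs}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePairScoresTsv <- function(scores, path) {
    utils::write.table(scores, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
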