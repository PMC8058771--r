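#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
NULL

.CATALOG_COLS <- c("protein_id", "transcript_id", "gene_id", "gene_symbol",
                   "transcript_biotype", "seq_length")

.COMPARISON_LABELS <- c("STONM", "STNM", "STM", "NM", "NP")
.SCORED_LABELS <- c("STONM", "STNM", "STM", "NM")

#' ProteinCatalog: kept/excluded partition of a proteome
#'
#' Registry of protein records parsed from an Ensembl-style peptide FASTA.
#' The \code{records} slot holds proteins eligible for pairing and grouping;
#' \code{excluded} holds records removed by biotype filtering, which are
#' carried forward so their transcripts can be passed through with their
#' original expression.
#'
#' Both slots are \link[S4Vectors]{DataFrame}s with columns
#' \code{protein_id}, \code{transcript_id}, \code{gene_id},
#' \code{gene_symbol} (may be \code{NA}), \code{transcript_biotype} and
#' \code{seq_length} (amino acids, terminal stop stripped).
#'
#' @slot records DataFrame of kept protein records.
#' @slot excluded DataFrame of biotype-excluded records.
#' @aliases ProteinCatalog
#' @exportClass ProteinCatalog
setClass("ProteinCatalog",
         representation(records = "DFrame", excluded = "DFrame"))

.validateCatalogFrame <- function(df, what) {
    msgs <- character()
    missing <- setdiff(.CATALOG_COLS, colnames(df))
    if (length(missing))
        return(sprintf("%s lacks columns: %s", what,
                       paste(missing, collapse = ", ")))
    if (nrow(df)) {
        if (anyDuplicated(df$protein_id))
            msgs <- c(msgs, sprintf("duplicate protein_id in %s", what))
        if (anyDuplicated(df$transcript_id))
            msgs <- c(msgs, sprintf("duplicate transcript_id in %s", what))
        if (any(!is.finite(df$seq_length)) || any(df$seq_length < 1))
            msgs <- c(msgs, sprintf("seq_length must be >= 1 in %s", what))
    }
    msgs
}

setValidity("ProteinCatalog", function(object) {
    msgs <- c(.validateCatalogFrame(object@records, "records"),
              .validateCatalogFrame(object@excluded, "excluded"))
    if (!length(msgs)) {
        overlap <- intersect(object@records$protein_id,
                             object@excluded$protein_id)
        if (length(overlap))
            msgs <- c(msgs, sprintf(
                "records and excluded overlap (e.g. %s)", overlap[[1L]]))
    }
    if (length(msgs)) msgs else TRUE
})

.emptyCatalogFrame <- function() {
    DataFrame(protein_id = character(), transcript_id = character(),
              gene_id = character(), gene_symbol = character(),
              transcript_biotype = character(), seq_length = integer())
}

#' Construct a ProteinCatalog
#'
#' @param records DataFrame (or data.frame) of kept records.
#' @param excluded DataFrame of excluded records (default empty).
#' @return A \linkS4class{ProteinCatalog}.
#' @export
ProteinCatalog <- function(records, excluded = .emptyCatalogFrame()) {
    new("ProteinCatalog",
        records = as(as.data.frame(records), "DFrame"),
        excluded = as(as.data.frame(excluded), "DFrame"))
}

#' ScoringScheme: weights for pair confidence scores
#'
#' Holds the weights of the pair-scoring scheme: the identity, coverage and
#' gap weights applied to the BLAST-derived alignment components, and a
#' per-tool weight for each domain-comparison label (STONM, STNM, STM, NM;
#' NP tools are skipped). The gap weight must be non-positive and, within
#' every tool, label weights must be monotone
#' STONM >= STNM >= STM >= NM.
#'
#' @slot identityWeight positive numeric, weight on percent identity.
#' @slot coverageWeight numeric, weight on the two coverage terms.
#' @slot gapWeight non-positive numeric, weight per gap opening.
#' @slot toolWeights numeric matrix, tools x c(STONM, STNM, STM, NM).
#' @aliases ScoringScheme
#' @exportClass ScoringScheme
setClass("ScoringScheme",
         representation(identityWeight = "numeric",
                        coverageWeight = "numeric",
                        gapWeight = "numeric",
                        toolWeights = "matrix"))

setValidity("ScoringScheme", function(object) {
    msgs <- character()
    if (length(object@identityWeight) != 1L ||
        !is.finite(object@identityWeight) || object@identityWeight <= 0)
        msgs <- c(msgs, "identityWeight must be a single positive number")
    if (length(object@coverageWeight) != 1L ||
        !is.finite(object@coverageWeight))
        msgs <- c(msgs, "coverageWeight must be a single finite number")
    if (length(object@gapWeight) != 1L || !is.finite(object@gapWeight) ||
        object@gapWeight > 0)
        msgs <- c(msgs, "gapWeight must be <= 0 (gaps penalize similarity)")
    tw <- object@toolWeights
    if (!is.numeric(tw) || !identical(colnames(tw), .SCORED_LABELS)) {
        msgs <- c(msgs, sprintf("toolWeights must be a numeric matrix with columns %s",
                                paste(.SCORED_LABELS, collapse = ", ")))
    } else {
        if (is.null(rownames(tw)) || anyDuplicated(rownames(tw)) ||
            any(!nzchar(rownames(tw))))
            msgs <- c(msgs, "toolWeights rows must be uniquely named by tool")
        bad <- tw[, "STONM"] < tw[, "STNM"] | tw[, "STNM"] < tw[, "STM"] |
               tw[, "STM"] < tw[, "NM"]
        if (any(bad))
            msgs <- c(msgs, sprintf(
                "label weights must satisfy STONM >= STNM >= STM >= NM (violated for %s)",
                paste(rownames(tw)[bad], collapse = ", ")))
    }
    if (length(msgs)) msgs else TRUE
})

#' SFPGSet: similar-function protein groups at a cutoff
#'
#' One group per seed transcript: the seed plus every transcript whose
#' confidence score with it meets the cutoff. Groups are seed
#' neighborhoods, deliberately not merged into connected components, so
#' semi-overlapping groups coexist and preserve specialized functions.
#' The \code{membership} slot is the exact inverse index
#' (transcript -> group ids) that drives expression redistribution.
#'
#' @slot groups named list; group id (seed transcript) -> character vector
#'   of member transcript ids (sorted, includes the seed).
#' @slot membership named list; transcript id -> character vector of group
#'   ids it belongs to.
#' @slot cutoff integer confidence-score cutoff used.
#' @slot scoreType "KS" or "DS".
#' @aliases SFPGSet
#' @exportClass SFPGSet
setClass("SFPGSet",
         representation(groups = "list", membership = "list",
                        cutoff = "integer", scoreType = "character"))

setValidity("SFPGSet", function(object) {
    msgs <- character()
    g <- object@groups
    if (length(g) && (is.null(names(g)) || anyDuplicated(names(g))))
        msgs <- c(msgs, "groups must be uniquely named")
    seedIn <- vapply(seq_along(g),
                     function(i) names(g)[[i]] %in% g[[i]], logical(1))
    if (length(g) && !all(seedIn))
        msgs <- c(msgs, "every group must contain its seed")
    inv <- .invertGroups(g)
    memb <- object@membership[order(names(object@membership))]
    memb <- lapply(memb, sort)
    if (!identical(lapply(inv[order(names(inv))], sort), memb))
        msgs <- c(msgs, "membership is not the inverse of groups")
    if (length(object@cutoff) != 1L || is.na(object@cutoff) ||
        object@cutoff < 1L || object@cutoff > 100L)
        msgs <- c(msgs, "cutoff must be an integer in [1, 100]")
    if (!(length(object@scoreType) == 1L &&
          object@scoreType %in% c("KS", "DS")))
        msgs <- c(msgs, "scoreType must be 'KS' or 'DS'")
    if (length(msgs)) msgs else TRUE
})

.invertGroups <- function(groups) {
    if (!length(groups)) return(structure(list(), names = character()))
    members <- unlist(groups, use.names = FALSE)
    gids <- rep(names(groups), lengths(groups))
    split(gids, members)
}

#' FixtureSpec: parameters of the synthetic input bundle
#'
#' Describes a synthetic proteome with planted ground truth: families of
#' near-identical proteins (pairwise identity hit exactly by mutating
#' disjoint position sets of a family root), per-tool planted domain
#' architectures with optional perturbations, negative-binomial counts with
#' planted per-sample size factors, and optional excluded-biotype decoy
#' transcripts.
#'
#' @slot familySizes integer vector, one entry (>= 1) per planted family.
#' @slot withinIdentity target percent identity within a family.
#' @slot betweenIdentity target percent identity between families; 0 means
#'   unrelated families and no between-family alignment rows.
#' @slot nToolsAnnotated how many tools of the roster carry planted
#'   architectures (0..length(tools)).
#' @slot perturbations list of per-family architecture perturbation plans;
#'   each element is \code{list(family=, member=, tool=, type=)} with type
#'   one of "swap" (order change), "dup" (count change), "replace"
#'   (different signatures), "drop" (no prediction).
#' @slot nSamples number of expression samples.
#' @slot sizeFactors planted per-sample scale factors (length nSamples).
#' @slot nbDispersion negative-binomial dispersion of the counts.
#' @slot nExcluded number of excluded-biotype decoy transcripts.
#' @slot rootLength family root length in amino acids.
#' @slot seed integer seed; bundles are byte-identical given a seed.
#' @aliases FixtureSpec
#' @exportClass FixtureSpec
setClass("FixtureSpec",
         representation(familySizes = "integer", withinIdentity = "numeric",
                        betweenIdentity = "numeric",
                        nToolsAnnotated = "integer", perturbations = "list",
                        nSamples = "integer", sizeFactors = "numeric",
                        nbDispersion = "numeric", nExcluded = "integer",
                        rootLength = "integer", seed = "integer"))

setValidity("FixtureSpec", function(object) {
    msgs <- character()
    if (!length(object@familySizes) || any(object@familySizes < 1L))
        msgs <- c(msgs, "familySizes must all be >= 1")
    if (object@withinIdentity > 100 || object@withinIdentity < 0 ||
        object@betweenIdentity > 100 || object@betweenIdentity < 0)
        msgs <- c(msgs, "identity targets must lie in [0, 100]")
    if (object@withinIdentity <= object@betweenIdentity)
        msgs <- c(msgs, "withinIdentity must exceed betweenIdentity")
    if (object@nSamples < 1L)
        msgs <- c(msgs, "nSamples must be >= 1")
    if (length(object@sizeFactors) != object@nSamples ||
        any(object@sizeFactors <= 0))
        msgs <- c(msgs, "sizeFactors must be positive, one per sample")
    if (object@nbDispersion <= 0)
        msgs <- c(msgs, "nbDispersion must be positive")
    if (object@nExcluded < 0L) msgs <- c(msgs, "nExcluded must be >= 0")
    if (object@rootLength < 30L)
        msgs <- c(msgs, "rootLength must be >= 30 aa")
    kw <- round((1 - object@withinIdentity / 100) * object@rootLength / 2)
    if (max(object@familySizes) * max(kw, 1) > object@rootLength)
        msgs <- c(msgs, "rootLength too short for the requested family sizes and identity")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn FixtureSpec constructor with the default study conditions.
#' @param familySizes,withinIdentity,betweenIdentity,nToolsAnnotated,perturbations,nSamples,sizeFactors,nbDispersion,nExcluded,rootLength,seed see slots.
#' @export
fixtureSpec <- function(familySizes = c(5L, 5L), withinIdentity = 98,
                        betweenIdentity = 0, nToolsAnnotated = 4L,
                        perturbations = list(), nSamples = 3L,
                        sizeFactors = c(0.5, 1, 2), nbDispersion = 0.1,
                        nExcluded = 2L, rootLength = 300L, seed = 1L) {
    new("FixtureSpec", familySizes = as.integer(familySizes),
        withinIdentity = as.numeric(withinIdentity),
        betweenIdentity = as.numeric(betweenIdentity),
        nToolsAnnotated = as.integer(nToolsAnnotated),
        perturbations = perturbations, nSamples = as.integer(nSamples),
        sizeFactors = as.numeric(sizeFactors),
        nbDispersion = as.numeric(nbDispersion),
        nExcluded = as.integer(nExcluded),
        rootLength = as.integer(rootLength), seed = as.integer(seed))
}

setMethod("show", "ProteinCatalog", function(object) {
    cat(sprintf("ProteinCatalog: %d kept, %d excluded protein records\n",
                nrow(object@records), nrow(object@excluded)))
    bt <- table(object@records$transcript_biotype)
    if (length(bt))
        cat("  kept biotypes:",
            paste(sprintf("%s (%d)", names(bt), bt), collapse = ", "), "\n")
})

setMethod("show", "ScoringScheme", function(object) {
    cat(sprintf(
        "ScoringScheme: identity %g, coverage %g, gap %g; %d tools\n",
        object@identityWeight, object@coverageWeight, object@gapWeight,
        nrow(object@toolWeights)))
    cat("  label weights (first tool):",
        paste(sprintf("%s=%g", colnames(object@toolWeights),
                      object@toolWeights[1L, ]), collapse = ", "), "\n")
})

setMethod("show", "SFPGSet", function(object) {
    sz <- lengths(object@groups)
    cat(sprintf(
        "SFPGSet: %d groups (%d non-singleton) at %s >= %d; max size %d\n",
        length(sz), sum(sz > 1L), object@scoreType, object@cutoff,
        if (length(sz)) max(sz) else 0L))
})

setMethod("show", "FixtureSpec", function(object) {
    cat(sprintf(
        "FixtureSpec: %d families (%s members), within %g%% / between %g%% identity, %d tools annotated, %d samples, seed %d\n",
        length(object@familySizes),
        paste(object@familySizes, collapse = "+"),
        object@withinIdentity, object@betweenIdentity,
        object@nToolsAnnotated, object@nSamples, object@seed))
})
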