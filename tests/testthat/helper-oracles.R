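# Independent straight-line oracles and tiny fixture builders used across
# the suite. These re-derive expected values from first principles and are
# kept free of any call into the package's scoring/grouping code paths.

# Straight-line evaluation of the two confidence scores for one pair.
oracleScorePair <- function(pident, alnLen, gaps, lenA, lenB, labels,
                            identityWeight, coverageWeight, gapWeight,
                            toolWeights) {
    ais <- pident * identityWeight / 100
    acs <- ((100 - lenA / alnLen * 100) + (100 - lenB / alnLen * 100)) *
        coverageWeight / 100
    ags <- gaps * gapWeight / 100
    ds <- (ais + acs + ags) * 100 / identityWeight
    ds <- min(max(ds, 0), 100)
    itcs <- 0
    maxItcs <- 0
    for (tool in names(labels)) {
        lab <- labels[[tool]]
        if (lab == "NP") next
        itcs <- itcs + toolWeights[tool, lab]
        maxItcs <- maxItcs + toolWeights[tool, "STONM"]
    }
    if (all(unlist(labels) == "NP")) {
        ks <- ds
    } else {
        ks <- (ais + acs + ags + itcs) * 100 / (identityWeight + maxItcs)
        ks <- min(max(ks, 0), 100)
    }
    list(AIS = ais, ACS = acs, AGS = ags, ITCS = itcs, DS = ds, KS = ks)
}

# Brute-force domain-comparison classifier written from the label
# definitions (presence, order, counts, types) without reusing the
# package's decision path.
bruteLabel <- function(a, b) {
    if (length(a) == 0 || length(b) == 0) return("NP")
    if (paste(a, collapse = "\x01") == paste(b, collapse = "\x01"))
        return("STONM")
    cntA <- table(a)
    cntB <- table(b)
    sameCounts <- length(cntA) == length(cntB) &&
        all(names(cntA) %in% names(cntB)) &&
        all(cntA == cntB[names(cntA)])
    if (sameCounts) return("STNM")
    typesA <- sort(unique(a))
    typesB <- sort(unique(b))
    if (length(typesA) == length(typesB) && all(typesA == typesB))
        return("STM")
    "NM"
}

# Independent median-of-ratios estimator (geometric-mean reference over
# all-positive rows, per-sample median of count/reference).
oracleMedianOfRatios <- function(counts) {
    keep <- rowSums(counts > 0) == ncol(counts)
    ref <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
    apply(counts[keep, , drop = FALSE], 2,
          function(col) stats::median(col / ref))
}

# Random valid scoring scheme (any such scheme must satisfy the scoring
# invariants).
randomScheme <- function(tools = defaultToolset()) {
    tw <- t(vapply(tools, function(t) sort(stats::runif(4, 0, 20),
                                           decreasing = TRUE),
                   numeric(4)))
    colnames(tw) <- c("STONM", "STNM", "STM", "NM")
    methods::new("ScoringScheme",
                 identityWeight = stats::runif(1, 10, 200),
                 coverageWeight = stats::runif(1, -20, 100),
                 gapWeight = -stats::runif(1, 0, 80),
                 toolWeights = tw)
}

# Random per-tool label vector, biased so that all-NP rows occur.
randomLabels <- function(tools = defaultToolset(), pAllNP = 0.1) {
    if (stats::runif(1) < pAllNP)
        return(stats::setNames(rep("NP", length(tools)), tools))
    stats::setNames(sample(c("STONM", "STNM", "STM", "NM", "NP"),
                           length(tools), replace = TRUE), tools)
}

# Random single-row alignment features table.
randomFeatures <- function() {
    alnLen <- sample(30:400, 1)
    data.frame(protein_a = "A", protein_b = "B",
               pident = stats::runif(1, 0, 100),
               aln_length = alnLen,
               gap_count = sample(0:10, 1),
               len_a = sample(30:400, 1),
               len_b = sample(30:400, 1),
               stringsAsFactors = FALSE)
}

# Minimal in-memory catalog from parallel vectors.
makeCatalog <- function(protein_id, transcript_id = protein_id,
                        gene_id = protein_id,
                        gene_symbol = rep(NA_character_, length(protein_id)),
                        transcript_biotype = rep("protein_coding",
                                                 length(protein_id)),
                        seq_length = rep(100L, length(protein_id))) {
    ProteinCatalog(data.frame(
        protein_id = protein_id, transcript_id = transcript_id,
        gene_id = gene_id, gene_symbol = gene_symbol,
        transcript_biotype = transcript_biotype,
        seq_length = as.integer(seq_length), stringsAsFactors = FALSE))
}

# Write a small FASTA from records; seq defaults to runs of 'M'.
writeTestFasta <- function(path, headers, seqs) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(headers)) {
        writeLines(headers[[i]], con)
        writeLines(seqs[[i]], con)
    }
    path
}

# All signature lists over an alphabet up to a maximum length.
allListsUpTo <- function(alphabet, maxLen) {
    out <- list(character())
    for (len in seq_len(maxLen)) {
        grid <- do.call(expand.grid,
                        c(rep(list(alphabet), len),
                          list(stringsAsFactors = FALSE)))
        out <- c(out, lapply(seq_len(nrow(grid)),
                             function(i) as.character(grid[i, ])))
    }
    out
}
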