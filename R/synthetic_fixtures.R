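.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a self-contained synthetic input bundle with planted truth
#'
#' Emits, deterministically for a given seed, every input the pipeline
#' consumes: a peptide FASTA, BLAST-like tabular hits, InterPro-like TSV
#' annotations, a raw-count matrix and effective lengths, plus a ground
#' truth object (also written as \code{truth.json}).
#'
#' Protein families are planted by mutating a family root: each member
#' substitutes a disjoint set of \eqn{k = round((1 - id/100) L / 2)}
#' positions, so every within-family pair differs at exactly \eqn{2k}
#' positions and realizes the identity target exactly. When
#' \code{betweenIdentity > 0} the family roots themselves are mutants of a
#' common ancestor (again on disjoint positions) and between-family
#' alignment rows are emitted with realized identities; at 0 the families
#' are unrelated and no between-family rows exist, as an aligner would
#' find no hit. Alignment rows carry realized identity, the root length as
#' alignment length and zero gaps; e-value and bit score fields are filled
#' but carry no statistical realism.
#'
#' Planted domain architectures (3 signatures per annotated tool, shared
#' within a family) yield STONM for unperturbed within-family pairs.
#' Perturbation plans downgrade one member in one tool: \code{"swap"}
#' reorders two signatures (STNM), \code{"dup"} duplicates one (STM),
#' \code{"replace"} substitutes different signatures (NM), \code{"drop"}
#' removes the tool's prediction (NP). At most one perturbation per
#' family/tool combination.
#'
#' Counts are negative-binomial around lognormal baseline means scaled by
#' the planted per-sample size factors; \code{nExcluded} decoy transcripts
#' with a nonsense-mediated-decay biotype are added to the FASTA and count
#' matrix (but to no alignments) to exercise passthrough.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with \code{dir}, \code{files} (named paths:
#'   proteins, blast, interpro, counts, lengths, truth) and \code{truth}
#'   (see Details).
#' @export
makeFixture <- function(spec, dir = tempfile("fixture")) {
    stopifnot(is(spec, "FixtureSpec"))
    validObject(spec)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(spec@seed)
    tools <- defaultToolset()
    annTools <- utils::head(tools, spec@nToolsAnnotated)
    L <- spec@rootLength
    nFam <- length(spec@familySizes)

    # --- sequences -------------------------------------------------------
    kb <- as.integer(round((1 - spec@betweenIdentity / 100) * L / 2))
    kw <- as.integer(round((1 - spec@withinIdentity / 100) * L / 2))
    roots <- vector("list", nFam)
    rootPos <- vector("list", nFam)
    if (spec@betweenIdentity > 0) {
        if (nFam * kb > L)
            stop("rootLength too short for the requested betweenIdentity")
        ancestor <- sample(.AA20, L, replace = TRUE)
        perm <- sample.int(L)
        for (f in seq_len(nFam)) {
            pos <- if (kb > 0) perm[((f - 1L) * kb + 1L):(f * kb)] else integer()
            roots[[f]] <- .mutateAt(ancestor, pos)
            rootPos[[f]] <- pos
        }
    } else {
        for (f in seq_len(nFam)) {
            roots[[f]] <- sample(.AA20, L, replace = TRUE)
            rootPos[[f]] <- integer()
        }
    }
    seqs <- list()
    fam <- character()
    for (f in seq_len(nFam)) {
        # member substitutions sit inside the family's own root-divergence
        # positions when they fit, so between-family identities stay at
        # their target instead of drifting lower with every member
        pool <- if (spec@betweenIdentity > 0 &&
                    spec@familySizes[[f]] * kw <= length(rootPos[[f]]))
            rootPos[[f]] else seq_len(L)
        perm <- pool[sample.int(length(pool))]
        for (m in seq_len(spec@familySizes[[f]])) {
            pos <- if (kw > 0) perm[((m - 1L) * kw + 1L):(m * kw)] else integer()
            seqs[[length(seqs) + 1L]] <- .mutateAt(roots[[f]], pos)
            fam <- c(fam, paste0("FAM", f))
        }
    }
    n <- length(seqs)
    pid <- paste0("P", sprintf("%03d", seq_len(n)))
    tid <- paste0("T", sprintf("%03d", seq_len(n)))
    gid <- paste0("G", sprintf("%03d", seq_len(n)))
    memberIdx <- unlist(lapply(spec@familySizes, seq_len))
    symbol <- paste0(fam, LETTERS[memberIdx])

    nEx <- spec@nExcluded
    if (nEx > 0) {
        for (i in seq_len(nEx))
            seqs[[n + i]] <- sample(.AA20, L, replace = TRUE)
        pid <- c(pid, paste0("PX", sprintf("%02d", seq_len(nEx))))
        tid <- c(tid, paste0("TX", sprintf("%02d", seq_len(nEx))))
        gid <- c(gid, paste0("GX", sprintf("%02d", seq_len(nEx))))
        symbol <- c(symbol, paste0("NMDGENE", seq_len(nEx)))
        fam <- c(fam, rep(NA_character_, nEx))
    }
    biotype <- c(rep("protein_coding", n),
                 rep("nonsense_mediated_decay", nEx))
    nAll <- n + nEx

    fastaPath <- file.path(dir, "proteins.fa")
    .writeFixtureFasta(fastaPath, pid, tid, gid, biotype, symbol, seqs)

    # --- alignment rows --------------------------------------------------
    idPct <- function(i, j) 100 * mean(seqs[[i]] == seqs[[j]])
    rows <- list()
    famIdx <- split(seq_len(n), fam[seq_len(n)])
    for (f in names(famIdx)) {
        idx <- famIdx[[f]]
        for (i in idx) for (j in idx) if (i < j)
            rows[[length(rows) + 1L]] <- .blastRow(pid[i], pid[j],
                                                   idPct(i, j), L)
    }
    nWithin <- length(rows)
    if (spec@betweenIdentity > 0 && nFam > 1L) {
        for (fi in seq_len(nFam - 1L)) for (fj in (fi + 1L):nFam) {
            for (i in famIdx[[paste0("FAM", fi)]])
                for (j in famIdx[[paste0("FAM", fj)]])
                    rows[[length(rows) + 1L]] <- .blastRow(pid[i], pid[j],
                                                           idPct(i, j), L)
        }
    }
    blastPath <- file.path(dir, "blast.tsv")
    writeLines(vapply(rows, identity, character(1)), blastPath)

    # --- domain annotations ---------------------------------------------
    pert <- .normalizePerturbations(spec@perturbations, spec@familySizes,
                                    annTools)
    ipRows <- character()
    step <- max(1L, L %/% 3L)
    dlen <- max(10L, L %/% 6L)
    for (i in seq_len(n)) {
        f <- as.integer(sub("FAM", "", fam[[i]]))
        for (tIdx in seq_along(annTools)) {
            tool <- annTools[[tIdx]]
            sigs <- paste0("F", f, "T", tIdx, "D", 1:3)
            starts <- (0:2) * step + 1L
            stops <- pmin(starts + dlen, L)
            key <- paste(f, memberIdx[[i]], tool, sep = "/")
            type <- pert[[key]]
            if (!is.null(type)) {
                if (type == "drop") next
                if (type == "swap") sigs <- sigs[c(2L, 1L, 3L)]
                if (type == "dup") { sigs <- c(sigs, sigs[[1L]])
                                     starts <- c(starts, min(starts[3] + step, L))
                                     stops <- pmin(starts + dlen, L) }
                if (type == "replace") sigs <- paste0("F", f, "T", tIdx,
                                                      "X", seq_along(sigs))
            }
            ipRows <- c(ipRows, sprintf(
                "%s\tmd5\t%d\t%s\t%s\tsynthetic domain\t%d\t%d\t1e-10\tT\t01-01-2020",
                pid[[i]], L, tool, sigs, starts, stops))
        }
    }
    interproPath <- file.path(dir, "interpro.tsv")
    writeLines(ipRows, interproPath)

    # --- counts and lengths ---------------------------------------------
    counts <- .simulateNbCounts(nAll, spec@sizeFactors, spec@nbDispersion)
    dimnames(counts) <- list(tid, paste0("sample_", seq_len(spec@nSamples)))
    effLength <- round(stats::runif(nAll, 500, 2000))
    countsPath <- file.path(dir, "counts.tsv")
    utils::write.table(
        data.frame(transcript_id = tid, counts, check.names = FALSE),
        countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    lengthsPath <- file.path(dir, "lengths.tsv")
    utils::write.table(
        data.frame(transcript_id = tid, effective_length = effLength),
        lengthsPath, sep = "\t", quote = FALSE, row.names = FALSE)

    # --- ground truth ----------------------------------------------------
    truth <- .buildTruth(spec, pid, tid, fam, memberIdx, seqs, annTools,
                         pert, idPct)
    truthPath <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

    invisible(list(dir = dir,
                   files = c(proteins = fastaPath, blast = blastPath,
                             interpro = interproPath, counts = countsPath,
                             lengths = lengthsPath, truth = truthPath),
                   truth = truth))
}

.mutateAt <- function(seqChars, positions) {
    out <- seqChars
    for (p in positions) {
        alt <- setdiff(.AA20, out[[p]])
        out[[p]] <- alt[[sample.int(length(alt), 1L)]]
    }
    out
}

.writeFixtureFasta <- function(path, pid, tid, gid, biotype, symbol, seqs) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(pid)) {
        header <- sprintf(
            ">%s pep gene:%s transcript:%s gene_biotype:%s transcript_biotype:%s gene_symbol:%s",
            pid[[i]], gid[[i]], tid[[i]], biotype[[i]], biotype[[i]],
            symbol[[i]])
        writeLines(header, con)
        s <- paste0(paste(seqs[[i]], collapse = ""), "*")
        writeLines(substring(s, seq(1L, nchar(s), 60L),
                             pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s))),
                   con)
    }
}

.blastRow <- function(q, s, pident, L) {
    mism <- as.integer(round((100 - pident) / 100 * L))
    sprintf("%s\t%s\t%.4f\t%d\t%d\t0\t1\t%d\t1\t%d\t%.2e\t%.1f",
            q, s, pident, L, mism, L, L, 1e-100, 2 * L - 2 * mism)
}

.normalizePerturbations <- function(perturbations, familySizes, annTools) {
    out <- list()
    for (p in perturbations) {
        stopifnot(is.list(p),
                  all(c("family", "member", "tool", "type") %in% names(p)))
        if (!p$type %in% c("swap", "dup", "replace", "drop"))
            stop("unknown perturbation type: ", p$type)
        tool <- if (is.numeric(p$tool)) annTools[[p$tool]] else p$tool
        if (!tool %in% annTools)
            stop("perturbation names an unannotated tool: ", tool)
        if (p$family > length(familySizes) ||
            p$member > familySizes[[p$family]])
            stop("perturbation indexes a nonexistent family member")
        key <- paste(p$family, p$member, tool, sep = "/")
        if (!is.null(out[[key]]))
            stop("at most one perturbation per family/member/tool")
        dupKey <- vapply(names(out), function(k)
            identical(strsplit(k, "/")[[1L]][c(1L, 3L)],
                      c(as.character(p$family), tool)), logical(1))
        if (any(dupKey))
            stop("at most one perturbation per family/tool combination")
        out[[key]] <- p$type
    }
    out
}

.simulateNbCounts <- function(nTranscripts, sizeFactors, dispersion,
                              meanLog = log(500), sdLog = 1) {
    mu <- stats::rlnorm(nTranscripts, meanLog, sdLog)
    counts <- vapply(sizeFactors, function(sf)
        stats::rnbinom(nTranscripts, mu = mu * sf, size = 1 / dispersion),
        numeric(nTranscripts))
    if (!any(rowSums(counts > 0) == ncol(counts)))
        counts[1L, ] <- counts[1L, ] + 1
    counts
}

#' Simulate negative-binomial counts with planted size factors
#'
#' Standalone generator used for size-factor recovery checks: per-transcript
#' lognormal baseline means, scaled per sample by the planted factors, with
#' NB noise at the given dispersion.
#'
#' @param nTranscripts number of transcripts.
#' @param sizeFactors planted per-sample scale factors.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed optional integer seed.
#' @return transcripts x samples count matrix.
#' @export
simulateCounts <- function(nTranscripts, sizeFactors, dispersion = 0.1,
                           seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    counts <- .simulateNbCounts(nTranscripts, sizeFactors, dispersion)
    dimnames(counts) <- list(paste0("T", seq_len(nTranscripts)),
                             paste0("sample_", seq_along(sizeFactors)))
    counts
}

.buildTruth <- function(spec, pid, tid, fam, memberIdx, seqs, annTools,
                        pert, idPct) {
    n <- sum(spec@familySizes)
    families <- lapply(split(tid[seq_len(n)], fam[seq_len(n)]), sort)
    pairs <- list()
    famIdx <- split(seq_len(n), fam[seq_len(n)])
    scheme <- defaultScoringScheme()
    for (f in names(famIdx)) {
        idx <- famIdx[[f]]
        fNum <- as.integer(sub("FAM", "", f))
        for (i in idx) for (j in idx) if (i < j) {
            labels <- vapply(seq_along(annTools), function(tIdx) {
                keyI <- paste(fNum, memberIdx[[i]], annTools[[tIdx]], sep = "/")
                keyJ <- paste(fNum, memberIdx[[j]], annTools[[tIdx]], sep = "/")
                ti <- pert[[keyI]]; tj <- pert[[keyJ]]
                t1 <- if (!is.null(ti)) ti else if (!is.null(tj)) tj else "none"
                switch(t1, none = "STONM", swap = "STNM", dup = "STM",
                       replace = "NM", drop = "NP")
            }, character(1))
            labels <- c(labels,
                        rep("NP", length(defaultToolset()) - length(annTools)))
            annLab <- labels[seq_along(annTools)]
            nonNP <- annLab != "NP"
            tw <- scheme@toolWeights[annTools, , drop = FALSE]
            itcs <- sum(tw[cbind(which(nonNP),
                                 match(annLab[nonNP], .SCORED_LABELS))])
            maxItcs <- sum(tw[nonNP, "STONM"])
            ks <- if (all(labels == "NP")) idPct(i, j)
                  else (idPct(i, j) + itcs) * 100 /
                      (scheme@identityWeight + maxItcs)
            pairs[[length(pairs) + 1L]] <- list(
                transcript_a = tid[[i]], transcript_b = tid[[j]],
                family = f,
                identity = idPct(i, j),
                labels = stats::setNames(as.list(labels), defaultToolset()),
                expected_ks_default_scheme = min(max(ks, 0), 100))
        }
    }
    qualifying <- vapply(pairs, function(p)
        p$expected_ks_default_scheme >= 95, logical(1))
    list(seed = spec@seed,
         families = families,
         transcript_family = stats::setNames(as.list(fam[seq_len(n)]),
                                             tid[seq_len(n)]),
         excluded_transcripts = if (length(tid) > n)
             tid[(n + 1L):length(tid)] else character(),
         within_pairs = pairs,
         n_expected_qualifying_at_95 = sum(qualifying),
         planted_size_factors = spec@sizeFactors)
}

#' Check recovered groups against planted families
#'
#' Exact-recovery check: the pipeline's non-singleton groups must each
#' equal the planted family of their seed, and every multi-member family
#' must be recovered by each of its members' seeds. Under-grouping (all
#' singletons at a cutoff above the planted similarity) and merged
#' neighborhoods (between-family identity near the within-family target)
#' are reported as named failure modes.
#'
#' @param sfpgs an \linkS4class{SFPGSet} produced from a fixture bundle.
#' @param truth the \code{truth} element returned by
#'   \code{\link{makeFixture}} (or read back from \code{truth.json}).
#' @return list with \code{pass} (logical), \code{n_exact} (groups equal to
#'   their planted family), \code{n_non_singleton} and \code{notes}.
#' @export
verifyAgainstTruth <- function(sfpgs, truth) {
    stopifnot(is(sfpgs, "SFPGSet"))
    famOf <- unlist(truth$transcript_family)
    families <- lapply(truth$families, unlist)
    g <- sfpgs@groups
    sizes <- lengths(g)
    nonSingleton <- names(g)[sizes > 1L]
    notes <- character()
    exact <- vapply(nonSingleton, function(seed) {
        f <- famOf[seed]
        !is.na(f) && setequal(g[[seed]], families[[f]])
    }, logical(1))
    if (length(nonSingleton) && !all(exact))
        notes <- c(notes, sprintf(
            "merged or partial neighborhoods: %d group(s) differ from their planted family",
            sum(!exact)))
    multiFam <- names(families)[lengths(families) > 1L]
    expectedSeeds <- unlist(families[multiFam], use.names = FALSE)
    missed <- setdiff(expectedSeeds, nonSingleton)
    if (length(missed))
        notes <- c(notes, sprintf(
            "under-grouping: %d planted family member(s) yielded singleton groups",
            length(missed)))
    list(pass = length(notes) == 0L,
         n_exact = sum(exact),
         n_non_singleton = length(nonSingleton),
         notes = notes)
}
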