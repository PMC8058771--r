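features1 <- function(pident, aln, gaps, lenA, lenB) {
    data.frame(protein_a = "A", protein_b = "B", pident = pident,
               aln_length = aln, gap_count = gaps, len_a = lenA,
               len_b = lenB, stringsAsFactors = FALSE)
}

npRow <- function(tools = defaultToolset()) {
    matrix("NP", 1, length(tools), dimnames = list(NULL, tools))
}

labelRow <- function(labels, tools = defaultToolset()) {
    m <- npRow(tools)
    m[1, names(labels)] <- labels
    m
}

test_that("scheme loading: defaults, yaml overrides, invariant violations", {
    s <- loadScoringScheme(NULL)
    expect_equal(s@identityWeight, 100)
    expect_equal(s@coverageWeight, 50)
    expect_equal(s@gapWeight, -50)
    expect_equal(unname(s@toolWeights["Pfam", ]), c(10, 6, 3, 0))
    expect_equal(nrow(s@toolWeights), 14L)

    cfg <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("identity_weight: 80", "gap_weight: -10",
                 "tool_weights:", "  STONM: 5", "  STNM: 4",
                 "  STM: 2", "  NM: 1"), cfg)
    s2 <- loadScoringScheme(cfg)
    expect_equal(s2@identityWeight, 80)
    expect_equal(unname(s2@toolWeights["SMART", ]), c(5, 4, 2, 1))

    expect_error(loadScoringScheme(list(gap_weight = 5)), "gapWeight")
    expect_error(loadScoringScheme(list(tool_weights = list(STONM = 3,
                                                            STNM = 6))),
                 "STONM >= STNM")
    expect_error(loadScoringScheme(list(identity_weight = -1)),
                 "identityWeight")
})

test_that("alignment components evaluate the identity, coverage and gap terms", {
    s <- defaultScoringScheme()
    # perfect self-alignment
    c1 <- alignmentComponents(features1(100, 100, 0, 100, 100), s)
    expect_equal(unlist(c1), c(AIS = 100, ACS = 0, AGS = 0))
    # alignment half the sequence length drives coverage negative
    c2 <- alignmentComponents(features1(90, 50, 0, 100, 100), s)
    expect_equal(c2$AIS, 90)
    expect_equal(c2$ACS, 0.5 * ((100 - 200) + (100 - 200)))
    expect_equal(c2$AGS, 0)
    # four gap openings at weight -50
    c3 <- alignmentComponents(features1(95, 100, 4, 100, 100), s)
    expect_equal(c3$AGS, -2)
})

test_that("discovery score normalizes by the maximum identity score and clamps", {
    s <- defaultScoringScheme()
    expect_equal(discoveryScore(features1(100, 100, 0, 100, 100), s), 100)
    # components (90, -100, 0): raw -10 clamps to 0
    expect_equal(discoveryScore(features1(90, 50, 0, 100, 100), s), 0)
    # components (95, -2, -1) with lengths 102/102 vs aln 100, 2 gaps
    f <- features1(95, 100, 2, 102, 102)
    comp <- alignmentComponents(f, s)
    expect_equal(unlist(comp), c(AIS = 95, ACS = -2, AGS = -1))
    expect_equal(discoveryScore(f, s), 92)
})

test_that("knowledge score skips NP tools and falls back to DS when all NP", {
    s <- defaultScoringScheme()
    # identical proteins, identical annotations in one tool -> exactly 100
    f0 <- features1(100, 100, 0, 100, 100)
    ks0 <- knowledgeScore(f0, labelRow(c(Pfam = "STONM")), s)
    expect_equal(ks0$KS, 100)
    expect_equal(ks0$ITCS, 10)
    expect_equal(ks0$max_itcs_nonNP, 10)

    # all 14 tools NP: KS = DS whatever the features
    f1 <- features1(73.2, 150, 3, 160, 140)
    expect_equal(knowledgeScore(f1, npRow(), s)$KS, discoveryScore(f1, s))

    # components (95, -2, -1) + one STNM tool: (92 + 6) * 100 / 110
    f2 <- features1(95, 100, 2, 102, 102)
    ks2 <- knowledgeScore(f2, labelRow(c(SMART = "STNM")), s)
    expect_equal(ks2$KS, 98 * 100 / 110, tolerance = 1e-12)
})

test_that("scoreAllPairs emits one row per aligned pair with transcript ids", {
    cat <- makeCatalog(c("A", "B", "C"), transcript_id = c("tA", "tB", "tC"))
    f <- rbind(features1(98, 100, 0, 100, 100),
               features1(50, 80, 1, 100, 90),
               features1(90, 100, 2, 100, 100))
    f$protein_b <- c("B", "C", "C")
    f$protein_a <- c("A", "A", "B")
    labs <- rbind(labelRow(c(Pfam = "STONM")), npRow(), npRow())
    sc <- scoreAllPairs(f, labs, defaultScoringScheme(), cat)
    expect_equal(nrow(sc), 3L)
    expect_equal(sc$transcript_a, c("tA", "tA", "tB"))
    expect_true(all(c("AIS", "ACS", "AGS", "ITCS", "DS", "KS") %in%
                    names(sc)))
    expect_true(all(sc$DS >= 0 & sc$DS <= 100))
    expect_true(all(sc$KS >= 0 & sc$KS <= 100))
})

test_that("optimized scores equal the straight-line oracle on random triples", {
    set.seed(101)
    s_tools <- defaultToolset()
    for (i in 1:200) {
        scheme <- randomScheme()
        f <- randomFeatures()
        labs <- randomLabels()
        got <- scoreAllPairs(f, labelRow(labs), scheme)
        want <- oracleScorePair(f$pident, f$aln_length, f$gap_count,
                                f$len_a, f$len_b, as.list(labs),
                                scheme@identityWeight,
                                scheme@coverageWeight, scheme@gapWeight,
                                scheme@toolWeights)
        expect_equal(got$DS, want$DS, tolerance = 1e-9)
        expect_equal(got$KS, want$KS, tolerance = 1e-9)
        expect_equal(got$ITCS, want$ITCS, tolerance = 1e-9)
    }
})

test_that("scores are independent of pair orientation", {
    set.seed(55)
    for (i in 1:50) {
        scheme <- randomScheme()
        f <- randomFeatures()
        labs <- labelRow(randomLabels())
        swapped <- f
        swapped$len_a <- f$len_b
        swapped$len_b <- f$len_a
        expect_equal(scoreAllPairs(f, labs, scheme)$KS,
                     scoreAllPairs(swapped, labs, scheme)$KS,
                     tolerance = 1e-12)
        expect_equal(scoreAllPairs(f, labs, scheme)$DS,
                     scoreAllPairs(swapped, labs, scheme)$DS,
                     tolerance = 1e-12)
    }
})

test_that("identical sequences and annotations give DS = KS = 100 for any valid scheme", {
    set.seed(77)
    for (i in 1:50) {
        scheme <- randomScheme()
        len <- sample(50:400, 1)
        f <- features1(100, len, 0, len, len)
        nAnn <- sample.int(14, 1)
        labs <- stats::setNames(rep("NP", 14), defaultToolset())
        labs[sample.int(14, nAnn)] <- "STONM"
        got <- scoreAllPairs(f, labelRow(labs[labs != "NP"]), scheme)
        expect_equal(got$DS, 100)
        expect_equal(got$KS, 100)
    }
})

test_that("upgrading one tool's label never decreases KS; NP tools are neutral", {
    set.seed(88)
    ladder <- c("NM", "STM", "STNM", "STONM")
    for (i in 1:50) {
        scheme <- randomScheme()
        f <- randomFeatures()
        labs <- randomLabels(pAllNP = 0)
        tool <- sample(names(labs)[labs != "NP"], 1)
        ksLadder <- vapply(ladder, function(lv) {
            labs[tool] <- lv
            knowledgeScore(f, labelRow(labs), scheme)$KS
        }, numeric(1))
        expect_true(all(diff(ksLadder) >= -1e-12))

        # adding an NP tool to both proteins leaves KS unchanged:
        # score over a wider roster where the extra tools are NP
        sub <- names(labs)[labs != "NP"]
        subScheme <- methods::new("ScoringScheme",
                                  identityWeight = scheme@identityWeight,
                                  coverageWeight = scheme@coverageWeight,
                                  gapWeight = scheme@gapWeight,
                                  toolWeights = scheme@toolWeights[sub, ,
                                                                   drop = FALSE])
        ksSub <- knowledgeScore(
            f, matrix(labs[sub], 1, dimnames = list(NULL, sub)), subScheme)$KS
        ksFull <- knowledgeScore(f, labelRow(labs), scheme)$KS
        expect_equal(ksSub, ksFull, tolerance = 1e-12)
    }
})

test_that("within-family pairs outscore between-family pairs on a planted fixture", {
    spec <- fixtureSpec(familySizes = c(5L, 5L), withinIdentity = 98,
                        betweenIdentity = 30, nExcluded = 0L, seed = 13L)
    b <- makeFixture(spec, withr::local_tempdir())
    cat <- readProteinFasta(b$files["proteins"])
    f <- alignmentFeatures(b$files["blast"], cat)
    prof <- buildProfiles(readInterproTsv(b$files["interpro"]),
                          keptRecords(cat)$protein_id)
    sc <- scoreAllPairs(f, compareAllPairs(prof, f),
                        defaultScoringScheme(), cat)
    famOf <- unlist(b$truth$transcript_family)
    within <- famOf[sc$transcript_a] == famOf[sc$transcript_b]
    expect_equal(sum(within), 20L)
    expect_equal(sum(!within), 25L)
    expect_gt(min(sc$KS[within]), max(sc$KS[!within]))
})
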