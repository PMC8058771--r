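mkSFPG <- function(groupList, csc = 95L, scoreType = "KS") {
    methods::new("SFPGSet", groups = groupList,
                 membership = SFPGtools:::.invertGroups(groupList),
                 cutoff = as.integer(csc), scoreType = scoreType)
}

test_that("median-of-ratios factors: symmetry, doubling, and failure mode", {
    m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
                dimnames = list(paste0("t", 1:3), c("s1", "s2")))
    expect_equal(unname(medianOfRatiosFactors(m)), c(1, 1))

    m2 <- m
    m2[, 2] <- 2 * m[, 1]
    expect_equal(unname(medianOfRatiosFactors(m2)),
                 c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

    zeros <- matrix(c(0, 5, 3, 0), ncol = 2)
    expect_error(medianOfRatiosFactors(zeros), "pseudo-reference")
    expect_error(medianOfRatiosFactors(m[, 1, drop = FALSE]), "2 samples")
})

test_that("median-of-ratios agrees with the DESeq2 estimator", {
    set.seed(19)
    m <- matrix(stats::rnbinom(500 * 4, mu = 80, size = 5), ncol = 4,
                dimnames = list(paste0("t", 1:500), paste0("s", 1:4)))
    # DESeq2 interpolates even-length medians geometrically rather than
    # arithmetically, hence the loose-but-tiny tolerance
    expect_equal(unname(medianOfRatiosFactors(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-3)
    # odd number of usable rows: the two definitions coincide exactly
    m2 <- m[1:499, ][rowSums(m[1:499, ] > 0) == 4, ]
    m2 <- m2[seq_len(2 * (nrow(m2) %/% 2) - 1), ]
    expect_equal(unname(medianOfRatiosFactors(m2)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m2)),
                 tolerance = 1e-12)
})

test_that("planted size factors are recovered from simulated NB counts", {
    planted <- c(0.5, 1, 2)
    counts <- simulateCounts(2000, planted, dispersion = 0.1, seed = 23)
    sf <- medianOfRatiosFactors(counts)
    rescale <- function(x) x / exp(mean(log(x)))
    expect_equal(unname(rescale(sf)), unname(rescale(planted)),
                 tolerance = 0.02)
})

test_that("FPKM conversion follows the effective-length formula", {
    counts <- matrix(c(10, 10), ncol = 2,
                     dimnames = list("t1", c("s1", "s2")))
    r <- toFPKM(counts, c(t1 = 1000), factors = c(s1 = 1, s2 = 1))
    expect_equal(unname(r$fpkm["t1", "s1"]), 1e6)  # 10 * 1e9 / (1000 * 10)

    counts2 <- matrix(c(0, 8, 4, 2), ncol = 2,
                      dimnames = list(c("t1", "t2"), c("s1", "s2")))
    r2 <- toFPKM(counts2, c(t1 = 500, t2 = 1000), factors = c(1, 1))
    expect_equal(unname(r2$fpkm["t1", "s1"]), 0)  # zero count stays zero

    # doubling every effective length halves every FPKM
    r3 <- toFPKM(counts2, c(t1 = 1000, t2 = 2000), factors = c(1, 1))
    expect_equal(r3$fpkm, r2$fpkm / 2)

    # effective length 0: row zeroed and removed from the library size
    expect_message(
        r4 <- toFPKM(counts2, c(t1 = 0, t2 = 1000), factors = c(1, 1)),
        "effective length 0")
    expect_equal(unname(r4$fpkm["t1", ]), c(0, 0))
    expect_equal(unname(r4$fpkm["t2", "s1"]), 8 * 1e9 / (1000 * 8))

    # all-zero sample yields an all-zero column, not a division error
    counts3 <- matrix(c(5, 3, 0, 0), ncol = 2,
                      dimnames = list(c("t1", "t2"), c("s1", "s2")))
    r5 <- toFPKM(counts3, c(t1 = 500, t2 = 500), factors = c(1, 1))
    expect_equal(unname(r5$fpkm[, "s2"]), c(0, 0))
})

test_that("a sample-wide count rescaling is absorbed by its size factor", {
    set.seed(29)
    counts <- matrix(stats::rnbinom(300 * 3, mu = 100, size = 10) + 1,
                     ncol = 3, dimnames = list(paste0("t", 1:300),
                                               paste0("s", 1:3)))
    eff <- stats::setNames(stats::runif(300, 500, 2000), rownames(counts))
    base <- toFPKM(counts, eff)
    scaled <- counts
    scaled[, 2] <- counts[, 2] * 3
    expect_equal(toFPKM(scaled, eff)$fpkm, base$fpkm, tolerance = 1e-12)
})

test_that("equal distribution splits a member's FPKM across its groups", {
    fpkm <- matrix(c(10, 0, 0), ncol = 1,
                   dimnames = list(c("M", "X", "Y"), "s1"))
    s <- mkSFPG(list(X = c("M", "X"), Y = c("M", "Y")))
    ed <- recalcED(fpkm, s)
    expect_equal(unname(ed[, 1]), c(5, 5))  # 10 split equally over 2 groups
    expect_equal(attr(ed, "method"), "ED")

    singleton <- mkSFPG(list(M = "M"))
    expect_equal(unname(recalcED(fpkm, singleton)[, 1]), 10)

    # three mutually similar transcripts, per-seed groups, fpkm (3,6,9)
    fpkm3 <- matrix(c(3, 6, 9), ncol = 1,
                    dimnames = list(c("A", "B", "C"), "s1"))
    abc <- lapply(1:3, function(i) c("A", "B", "C"))
    names(abc) <- c("A", "B", "C")
    expect_equal(unname(recalcED(fpkm3, mkSFPG(abc))[, 1]), rep(6, 3))
})

test_that("group-size distribution weights groups by their size", {
    fpkm <- matrix(c(10, 0, 0, 0), ncol = 1,
                   dimnames = list(c("M", "X", "Y", "Z"), "s1"))
    s <- mkSFPG(list(X = c("M", "X"), Y = c("M", "Y", "Z")))
    gd <- recalcGD(fpkm, s)
    expect_equal(unname(gd["X", 1]), 4)  # 10 * 2 / 5
    expect_equal(unname(gd["Y", 1]), 6)  # 10 * 3 / 5
    expect_equal(attr(gd, "method"), "GD")

    one <- mkSFPG(list(X = c("M", "X")))
    expect_equal(unname(recalcGD(fpkm, one)["X", 1]), 10)

    # equal-sized groups degenerate to equal distribution
    eq <- mkSFPG(list(X = c("M", "X"), Z = c("M", "Z")))
    expect_equal(as.numeric(recalcGD(fpkm, eq)),
                 as.numeric(recalcED(fpkm, eq)))
})

test_that("redistribution demands an expression row and membership for every member", {
    fpkm <- matrix(5, 1, 1, dimnames = list("M", "s1"))
    s <- mkSFPG(list(X = c("M", "X")))
    expect_error(recalcED(fpkm, s), "without an expression row")
})

test_that("passthrough rows complete the output and collisions are errors", {
    fpkm <- matrix(c(4, 6, 3), ncol = 1,
                   dimnames = list(c("A", "B", "N1"), "s1"))
    s <- mkSFPG(list(A = c("A", "B"), B = c("A", "B")))
    gd <- recalcGD(fpkm, s)
    out <- assembleOutput(gd, fpkm, "N1")
    expect_equal(nrow(out), 3L)
    expect_equal(unname(out["N1", 1]), 3)
    expect_equal(sum(out[, 1]), sum(fpkm[, 1]))

    expect_equal(nrow(assembleOutput(gd, fpkm, character())), 2L)
    expect_error(assembleOutput(gd, fpkm, "A"), "collide")
    expect_error(assembleOutput(gd, fpkm, "ZZ"), "without an expression row")
})

test_that("permuting transcript input order only permutes FPKM rows", {
    set.seed(37)
    counts <- matrix(stats::rnbinom(40 * 3, mu = 50, size = 5) + 1, ncol = 3,
                     dimnames = list(paste0("t", 1:40), paste0("s", 1:3)))
    eff <- stats::setNames(stats::runif(40, 500, 1500), rownames(counts))
    ord <- sample(rownames(counts))
    a <- toFPKM(counts, eff)$fpkm
    b <- toFPKM(counts[ord, ], eff)$fpkm
    expect_equal(b, a[ord, ])
})
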