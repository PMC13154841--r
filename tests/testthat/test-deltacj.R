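test_that("MAPQ weights follow the error-probability transform", {
    expect_equal(mapqWeight(0), 0)
    expect_equal(mapqWeight(10), 0.9)
    expect_equal(mapqWeight(20), 0.99)
    expect_error(mapqWeight(-1), "non-negative")
})

test_that("junction probability reflects relative mappability", {
    expect_equal(junctionProbability(0.8, 0.8), 0.5)
    expect_equal(junctionProbability(1.0, 0.470), 1 / 1.470)
    expect_equal(junctionProbability(1.0, 0.0), 1.0)
    expect_true(is.na(junctionProbability(0, 0)))
    expect_true(is.na(junctionProbability(NA, 0.5)))
})

test_that("deltaCJ measures one-sidedness of junction support", {
    expect_equal(deltaCJstat(22, 22), 0)
    expect_equal(deltaCJstat(28, 0), 1)
    expect_equal(deltaCJstat(3, 1), 0.5)
    expect_true(is.na(deltaCJstat(0, 0)))
    set.seed(1)
    k <- matrix(sample(0:30, 60, TRUE), ncol = 2)
    d <- deltaCJstat(k[, 1], k[, 2])
    expect_true(all(d >= 0 & d <= 1, na.rm = TRUE))
    expect_equal(d == 0, k[, 1] == k[, 2])
})

test_that("raw symmetric tail reproduces the closed-form sums", {
    expect_equal(symmetricTailRaw(3, 6), 1.3125)   # even-N double counting
    expect_equal(symmetricTailRaw(3, 7), 1)
    expect_equal(symmetricTailRaw(0, 2), 0.5)
    expect_error(symmetricTailRaw(4, 7), "n/2")
})

test_that("symmetric tail equals exhaustive assignment enumeration", {
    for (n in c(2, 5, 8, 11, 12)) {
        for (k in unique(c(0, 1, n %/% 3, n %/% 2))) {
            expect_equal(symmetricTailRaw(k, n), 2 * enumTailP(k, n),
                         info = sprintf("k=%d n=%d", k, n))
        }
    }
})

test_that("capped probability applies the even-N midpoint rule", {
    expect_equal(symmetricP(3, 6), 1)
    expect_equal(symmetricP(22, 44), 1)
    expect_equal(symmetricP(1, 9), 2 * 0.5^9 * 10)   # 0.0390625
    ## non-decreasing in k for fixed n
    for (n in c(7, 10, 13)) {
        ps <- vapply(0:(n %/% 2), symmetricP, numeric(1), n = n)
        expect_true(all(diff(ps) >= 0))
    }
})

test_that("mappability-adjusted probability generalises the symmetric one", {
    ## p_L = 0.5 reduces to the symmetric test for all N <= 12
    for (n in 1:12) {
        for (kL in 0:n) {
            expect_equal(adjustedP(kL, n - kL, 0.5),
                         min(1, ifelse(n %% 2 == 0 && min(kL, n - kL) == n / 2,
                                       1, 2 * enumTailP(min(kL, n - kL), n))),
                         info = sprintf("kL=%d n=%d", kL, n))
        }
    }
    ## fully one-sided split against an uneven expectation
    expect_equal(adjustedP(28, 0, 0.680), 2 * 0.68^28, tolerance = 1e-10)
    ## balanced counts at their expectation cap at 1
    expect_equal(adjustedP(5, 5, 0.5), 1)
    expect_equal(adjustedP(7, 3, 0.7), 1)
    ## degenerate expectations
    expect_equal(adjustedP(3, 2, 1), 0)   # reads on the impossible side
    expect_equal(adjustedP(3, 0, 1), 1)
    expect_error(adjustedP(0, 0, 0.5), "positive")
})

test_that("minimum-N derivation matches direct evaluation", {
    r05 <- minReadsForSignificance(0.05)
    expect_equal(r05$nContinuous, 8.58, tolerance = 0.01 / 8.58)
    expect_equal(r05$nMin, 9L)
    ## direct evaluation around the integer threshold
    f <- function(n) 2 * (n + 1) * 0.5^n
    expect_gt(f(8), 0.05)
    expect_lt(f(9), 0.05)
    r01 <- minReadsForSignificance(0.01)
    expect_equal(r01$nMin, 12L)
    expect_gt(f(11), 0.01)
    expect_lt(f(12), 0.01)
})

test_that("BH adjustment is step-up, order-preserving and capped", {
    expect_equal(bhAdjust(0.02), 0.02)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    set.seed(3)
    p <- runif(50)
    adj <- bhAdjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("evidence collection weights, deduplicates and ceilings reads", {
    circle <- circles("chr1", 1000, 4000)
    mkSrc <- function(left = 0, right = 0, mapq = 60) {
        rows <- data.frame(chrom = character(), start = integer(),
                           end = integer(), name = character(),
                           mapq = numeric())
        if (left > 0)
            rows <- rbind(rows, data.frame(chrom = "chr1", start = 995,
                                           end = 1015,
                                           name = paste0("L", 1:left),
                                           mapq = mapq))
        if (right > 0)
            rows <- rbind(rows, data.frame(chrom = "chr1", start = 3995,
                                           end = 4015,
                                           name = paste0("R", 1:right),
                                           mapq = mapq))
        FixtureAlignments(rows)
    }
    ev <- collectEvidence(mkSrc(left = 3), circle)
    expect_equal(ev$kL, 3L); expect_equal(ev$kR, 0L); expect_equal(ev$N, 3L)

    none <- collectEvidence(mkSrc(), circle)
    expect_equal(none$N, 0L)

    ## one MAPQ-3 read per side: w ~ 0.4988 each, ceiling to 1
    low <- collectEvidence(mkSrc(left = 1, right = 1, mapq = 3), circle)
    expect_equal(low$kL, 1L)
    expect_equal(low$kR, 1L)

    ## duplicate identifiers within a window count once
    dup <- FixtureAlignments(data.frame(chrom = "chr1",
                                        start = c(995, 1000),
                                        end = c(1010, 1015),
                                        name = "same", mapq = 60))
    evd <- collectEvidence(dup, circle)
    expect_equal(evd$kL, 1L)
})

test_that("reads spanning both windows side with the larger overlap", {
    circle <- circles("chr1", 1000, 1030)   # short circle: windows adjoin
    src <- FixtureAlignments(data.frame(
        chrom = "chr1",
        start = c(1001, 981),
        end = c(1020, 1050),
        name = c("leftHeavy", "spanner"),
        mapq = 60))
    ## both reads fall in both windows ([981,1020] and [1011,1050]):
    ## leftHeavy overlaps the left window by 20 bases, the right by 10, so
    ## it counts left; spanner covers both windows fully (tie) and is
    ## side-uninformative, contributing to neither sum
    ev <- collectEvidence(src, circle, nOffset = 20L)
    expect_equal(ev$kL, 1L)
    expect_equal(ev$kR, 0L)
})

test_that("junction screen integrates mappability and BH correction", {
    ## two circles: one balanced, one fully one-sided with poor right-side
    ## mappability explaining part of the skew
    circs <- circles("chr1", c(1000, 5000), c(3000, 7000))
    rows <- rbind(
        data.frame(chrom = "chr1", start = 990, end = 1010,
                   name = paste0("a", 1:15), mapq = 60),
        data.frame(chrom = "chr1", start = 2990, end = 3010,
                   name = paste0("b", 1:15), mapq = 60),
        data.frame(chrom = "chr1", start = 4990, end = 5010,
                   name = paste0("c", 1:28), mapq = 60))
    mapp <- MappabilityFixture(list(chr1 = c(rep(1, 6970), rep(0.47, 30))))
    res <- deltaCJ(circs, FixtureAlignments(rows), mapp)
    expect_equal(res$kL, c(15L, 28L))
    expect_equal(res$kR, c(15L, 0L))
    expect_equal(res$deltaCJ, c(0, 1))
    expect_equal(res$p[1], 1)
    ## right region of circle 2 has mean mappability 0.47 -> pL ~ 0.68
    expect_equal(res$pL[2], 1 / 1.47, tolerance = 1e-6)
    expect_lt(res$pAdj[2], 0.05)
    expect_true(res$significant[2] && !res$significant[1])
})

test_that("cohort metrics tally power, imbalance and significance", {
    mk <- function(N, d, pAdj) data.frame(N = N, deltaCJ = d, pAdj = pAdj)
    allGood <- mk(rep(20, 10), rep(0, 10), rep(1, 10))
    cm <- cohortMetrics(allGood)
    expect_equal(cm$propNge9, 1)
    expect_equal(cm$meanDeltaCJ, 0)
    expect_equal(cm$medianDeltaCJ, 0)
    expect_equal(cm$propSignificant, 0)

    lowN <- mk(rep(4, 5), rep(0.5, 5), rep(0.2, 5))
    cmLow <- cohortMetrics(lowN)
    expect_equal(cmLow$propNge9, 0)
    expect_true(is.na(cmLow$meanDeltaCJ))

    mixed <- mk(c(10, 10, 4, 12), c(0.1, 0.3, 1, 0.5), c(0.01, 0.2, 1, 0.04))
    cmM <- cohortMetrics(mixed)
    expect_equal(cmM$propNge9, 0.75)
    expect_equal(cmM$meanDeltaCJ, mean(c(0.1, 0.3, 0.5)))
    expect_equal(cmM$medianDeltaCJ, 0.3)
    expect_equal(cmM$propSignificant, 0.5)
})

test_that("cohort comparison is a difference of mean imbalances", {
    a <- data.frame(deltaCJ = c(0.1, 0.3))
    b <- data.frame(deltaCJ = c(0.2, 0.3))
    expect_equal(deltaDeltaCJ(a, a), 0)
    expect_equal(deltaDeltaCJ(data.frame(deltaCJ = rep(0, 4)),
                              data.frame(deltaCJ = rep(1, 4))), -1)
    expect_equal(deltaDeltaCJ(a, b), -0.05)
    expect_error(deltaDeltaCJ(a, a[0, , drop = FALSE]), "non-empty")
})
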