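test_that("benchmark reproduces the precision/recall/F definitions", {
    truth <- circles("chr1", (1:10) * 5000, (1:10) * 5000 + 800)
    exact <- benchmarkCircles(truth, truth)
    expect_equal(exact@precision, 1)
    expect_equal(exact@recall, 1)
    expect_equal(exact@fScore, 1)

    ## 8 predictions, 6 matching truth
    pred <- c(truth[1:6], circles("chr1", c(100, 200), c(400, 900)))
    b <- benchmarkCircles(pred, truth)
    expect_equal(b@tp, 6L); expect_equal(b@fp, 2L); expect_equal(b@fn, 4L)
    expect_equal(b@precision, 0.75)
    expect_equal(b@recall, 0.6)
    expect_equal(b@fScore, 2 * 0.75 * 0.6 / 1.35)

    empty <- benchmarkCircles(truth[0], truth)
    expect_equal(empty@precision, 0)
    expect_equal(empty@recall, 0)
    expect_equal(empty@fScore, 0)
    expect_error(benchmarkCircles(truth, truth[0]), "non-empty")
})

test_that("benchmark metrics stay in range and agree with brute force", {
    for (seed in 1:4) {
        set.seed(seed)
        ts <- sample.int(8e4, 40)
        truth <- circles("chr1", ts, ts + sample(300:900, 40, TRUE))
        ## predictions: jittered truth subset plus noise calls
        keep <- sample.int(40, 25)
        ps <- ts[keep] + sample(-25:25, 25, TRUE)
        pred <- c(circles("chr1", pmax(0, ps),
                          pmax(0, ps) + GenomicRanges::width(truth)[keep] +
                              sample(-25:25, 25, TRUE)),
                  {ns <- sample.int(8e4, 15)
                   circles("chr1", ns, ns + 500)})
        b <- benchmarkCircles(pred, truth)
        oracle <- bruteBenchmark(pred, truth)
        expect_equal(b@tp, oracle$tp)
        expect_equal(b@fp, oracle$fp)
        expect_equal(b@fn, oracle$fn)
        expect_true(b@precision >= 0 && b@precision <= 1)
        expect_true(b@fScore <= max(b@precision, b@recall) + 1e-12)
    }
})

test_that("offset ratio separates exact from loosely matched calls", {
    truth <- circles("chr1", (1:10) * 3000, (1:10) * 3000 + 500)
    expect_equal(offsetRatio(truth, truth), 1)
    shifted <- GenomicRanges::shift(truth, 5)
    expect_equal(offsetRatio(shifted, truth), 0)
    mix <- c(truth[1:9], GenomicRanges::shift(truth[10], 5))
    expect_equal(offsetRatio(mix, truth), 0.9)
    expect_equal(offsetRatio(truth[0], truth), 0)
})

test_that("length KS statistic matches closed-form ECDF gaps", {
    expect_equal(lengthKS(rep(500, 50), rep(500, 50))$statistic, 0)
    expect_equal(lengthKS(rep(300, 40), rep(900, 40))$statistic, 1)
    ## {100x300, 100x800} vs {100x300} restricted to [175, 1000]: D = 0.5
    ks <- lengthKS(c(rep(300, 100), rep(800, 100)), rep(300, 100),
                   lengthRange = c(175, 1000))
    expect_equal(ks$statistic, 0.5)
    ## the range restriction really removes out-of-range lengths
    expect_equal(lengthKS(c(rep(300, 10), rep(5000, 90)), rep(300, 10),
                          lengthRange = c(175, 1000))$statistic, 0)
    expect_error(lengthKS(rep(50, 10), rep(500, 10),
                          lengthRange = c(175, 1000)), "range")
})

test_that("Yates chi-square matches the cross-cohort circle-sharing table", {
    ## 3 of 67,390 unfiltered ATAC-seq circles vs 642 of 15,489 Circle-Seq
    ## circles detected by 4 of 5 tools
    tab <- matrix(c(3, 67390 - 3, 642, 15489 - 642), nrow = 2, byrow = TRUE)
    expect_equal(chisqYates(tab), 2790.67, tolerance = 0.5 / 2790.67)
    expect_equal(chisqYates(tab),
                 unname(stats::chisq.test(tab, correct = TRUE)$statistic))
    ## proportional table: correction clamps at zero
    expect_equal(chisqYates(matrix(10, 2, 2)), 0)
    prop <- matrix(c(20, 40, 10, 20), 2, byrow = TRUE)
    expect_equal(chisqYates(prop), 0)
    expect_error(chisqYates(matrix(c(0, 0, 1, 1), 2)), "marginal")
})
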