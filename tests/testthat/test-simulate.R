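test_that("pair count inverts the coverage equation with a ceiling", {
    expect_equal(readsForCoverage(30, 3000, 150), 300L)
    expect_equal(readsForCoverage(5, 175, 150), 3L)   # ceil(875/300)
    expect_equal(readsForCoverage(1, 300, 150), 1L)
    expect_equal(readsForCoverage(0.001, 200, 150), 1L)  # never 0
    expect_error(readsForCoverage(0, 100, 150), "positive")
})

test_that("coordinate sampling honours the length distribution bounds", {
    lens <- c(chr1 = 50000L, chr2 = 20000L)
    pFix <- SimulationParams(distKind = "uniform", minLen = 500,
                             maxLen = 500)
    gr <- sampleCircleCoords(lens, 50, pFix, seed = 3)
    expect_true(all(GenomicRanges::width(gr) == 500))
    expect_true(all(GenomicRanges::end(gr) <=
                        lens[as.character(GenomeInfoDb::seqnames(gr))]))
    expect_length(sampleCircleCoords(lens, 0, pFix), 0)
    tiny <- c(chr1 = 100L)
    expect_error(sampleCircleCoords(tiny, 5, pFix), "minimum length")
})

test_that("lognormal lengths match a direct Monte-Carlo oracle", {
    p <- SimulationParams()   # s=1, scale=1000, truncated to [175, 10000]
    gr <- sampleCircleCoords(c(chr1 = 1e6L), 3000, p, seed = 21)
    drawn <- GenomicRanges::width(gr)
    ## oracle: loc + scale*exp(s*Z) with rejection outside the bounds
    set.seed(99)
    mc <- round(1000 * exp(stats::rnorm(3e4)))
    mc <- mc[mc >= 175 & mc <= 10000][1:3000]
    expect_true(all(drawn >= 175 & drawn <= 10000))
    ks <- suppressWarnings(stats::ks.test(drawn, mc))
    expect_gt(ks$p.value, 0.01)
    ## median of the truncated lognormal stays near the scale parameter
    expect_lt(abs(median(drawn) - median(mc)), 100)
})

test_that("chromosomes are drawn proportionally to their length", {
    lens <- c(chr1 = 90000L, chr2 = 10000L)
    p <- SimulationParams(distKind = "uniform", minLen = 300, maxLen = 300)
    gr <- sampleCircleCoords(lens, 1000, p, seed = 8)
    frac <- mean(as.character(GenomeInfoDb::seqnames(gr)) == "chr1")
    expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 1000) + 0.01)
})

test_that("Kimura mutation respects rate, kappa and the alphabet", {
    seq <- randomGenome(c(x = 10000L), seed = 2)[["x"]]
    expect_identical(mutateSequence(seq, 0), seq)
    ## kappa -> Inf: every base goes to its transition partner
    flipped <- mutateSequence("ACGT", 1, kappa = 1e12, seed = 1)
    expect_identical(flipped, "GTAC")
    ## observed substitutions within 3 SD of binomial(n, rate)
    long <- randomGenome(c(x = 1e5L), seed = 3)[["x"]]
    mut <- mutateSequence(long, 0.01, seed = 4)
    nDiff <- sum(strsplit(long, "")[[1]] != strsplit(mut, "")[[1]])
    expect_lt(abs(nDiff - 1000), 3 * sqrt(1e5 * 0.01 * 0.99))
    ## N bases are never touched
    expect_identical(mutateSequence("NNNN", 1, seed = 5), "NNNN")
})

test_that("sequencing errors hit the expected fraction of bases", {
    seq <- randomGenome(c(x = 1e6L), seed = 6)[["x"]]
    expect_identical(applySequencingError(seq, 0), seq)
    err <- applySequencingError(seq, 0.001, seed = 7)
    nDiff <- sum(strsplit(seq, "")[[1]] != strsplit(err, "")[[1]])
    expect_lt(abs(nDiff - 1000), 3 * sqrt(1e6 * 0.001 * 0.999))
    allHit <- applySequencingError(substr(seq, 1, 5000), 1, seed = 8)
    expect_false(any(strsplit(substr(seq, 1, 5000), "")[[1]] ==
                         strsplit(allHit, "")[[1]]))
})

test_that("read pairs are classified by their relation to the junction", {
    circ <- randomGenome(c(x = 10000L), seed = 10)[["x"]]
    p <- SimulationParams(seqErrorRate = 0, mutationRate = 0)
    rds <- simulateCircleReads(circ, "c1", p, seed = 11, nPairs = 2000)
    len <- 10000L; rl <- 150L; ins <- 500L
    s <- rds$fragStart
    ## fragment fully inside the linear coordinates -> concordant
    expect_true(all(rds$class[s + ins <= len] == "concordant"))
    ## read 1 starting 75 bp before the junction crosses it -> split
    expect_true(all(rds$class[s > len - rl & s < len] == "split"))
    ## junction between the mates -> discordant
    between <- s + rl <= len & s + ins - rl >= len
    expect_true(all(rds$class[between] == "discordant"))
})

test_that("reads reproduce the requested coverage and are reproducible", {
    circ <- randomGenome(c(x = 3000L), seed = 12)[["x"]]
    p <- SimulationParams(coverage = 30)
    rds <- simulateCircleReads(circ, "c1", p, seed = 13)
    bases <- sum(nchar(rds$seq1)) + sum(nchar(rds$seq2))
    expect_lt(abs(bases / 3000 - 30) / 30, 0.05)
    ## byte-identical under a fixed seed
    again <- simulateCircleReads(circ, "c1", p, seed = 13)
    expect_identical(rds, again)
    expect_error(simulateCircleReads(substr(circ, 1, 100), "c1", p),
                 "shorter")
})

test_that("linear reads stay inside the region and cover it evenly", {
    reg <- randomGenome(c(x = 5000L), seed = 14)[["x"]]
    p <- SimulationParams(seqErrorRate = 0, mutationRate = 0)
    rds <- simulateLinearReads(reg, "r1", p, seed = 15, nPairs = 5000)
    expect_true(all(rds$class == "linear"))
    expect_true(all(rds$fragStart >= 0 & rds$fragStart <= 5000 - 500))
    ## interior coverage approximately uniform: compare depth quartiles
    depth <- integer(5000)
    for (s in rds$fragStart) {
        depth[(s + 1):(s + 150)] <- depth[(s + 1):(s + 150)] + 1L
        depth[(s + 351):(s + 500)] <- depth[(s + 351):(s + 500)] + 1L
    }
    interior <- depth[700:4300]
    expect_lt(stats::sd(interior) / mean(interior), 0.2)
    ## region of exactly one insert: every fragment starts at 0
    one <- simulateLinearReads(substr(reg, 1, 500), "r2", p, nPairs = 10)
    expect_true(all(one$fragStart == 0))
    expect_error(simulateLinearReads(substr(reg, 1, 400), "r3", p),
                 "insert")
})

test_that("junction enrichment raises the split and discordant fraction", {
    circ <- randomGenome(c(x = 8000L), seed = 16)[["x"]]
    frac <- function(ncj, seed) {
        p <- SimulationParams(nearCJFraction = ncj, seqErrorRate = 0,
                              mutationRate = 0)
        r <- simulateCircleReads(circ, "c", p, seed = seed, nPairs = 5000)
        mean(r$class %in% c("split", "discordant"))
    }
    expect_gt(frac(0.5, 17), frac(0, 17) + 0.1)
})

test_that("read-set simulation yields truth plus matching reads", {
    g <- randomGenome(c(chr1 = 60000L, chr2 = 30000L), seed = 18)
    p <- SimulationParams(minLen = 300, maxLen = 2000, scale = 700)
    rs <- simulateReadSet(g, 12, p, seed = 19)
    expect_length(rs$truth, 12)
    expect_true(all(GenomicRanges::width(rs$truth) >= 300 &
                        GenomicRanges::width(rs$truth) <= 2000))
    expect_setequal(unique(rs$reads$circle), names(rs$truth))
    ## fixed seed reproduces byte-identical output
    again <- simulateReadSet(g, 12, p, seed = 19)
    expect_identical(rs, again)
})

test_that("joining read sets preserves pairing and counts", {
    g <- randomGenome(c(x = 5000L), seed = 20)
    p <- SimulationParams()
    a <- simulateCircleReads(g[["x"]], "c", p, seed = 1, nPairs = 10)
    b <- simulateLinearReads(g[["x"]], "l", p, seed = 2, nPairs = 5)
    j <- joinReadSets(a, b)
    expect_equal(nrow(j), 15)
    expect_equal(nrow(joinReadSets(a[0, ], b)), 5)
    bad <- a; bad$qual1[1] <- "II"
    expect_error(joinReadSets(bad, b), "mismatch")
})
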