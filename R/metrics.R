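## One-to-one greedy assignment of predictions to truth circles: candidate
## pairs matching under the threshold are ranked by start-coordinate offset
## (then end offset, then index) and consumed greedily so a truth circle is
## claimed by at most one prediction and vice versa.
.assignMatches <- function(predicted, truth, threshold) {
    if (length(predicted) == 0L || length(truth) == 0L)
        return(data.frame(pred = integer(), truth = integer(),
                          dStart = integer(), dEnd = integer()))
    ps <- GenomicRanges::start(predicted); pe <- GenomicRanges::end(predicted)
    ts <- GenomicRanges::start(truth); te <- GenomicRanges::end(truth)
    pc <- as.character(GenomeInfoDb::seqnames(predicted))
    tc <- as.character(GenomeInfoDb::seqnames(truth))
    ## candidate pairs via an expanded overlap query, then exact filtering
    exp <- GenomicRanges::resize(GenomicRanges::granges(truth),
                                 GenomicRanges::width(truth) + 2L * threshold,
                                 fix = "center")
    hits <- GenomicRanges::findOverlaps(GenomicRanges::granges(predicted),
                                        exp)
    p <- S4Vectors::queryHits(hits); tr <- S4Vectors::subjectHits(hits)
    okc <- pc[p] == tc[tr] & abs(ps[p] - ts[tr]) <= threshold &
        abs(pe[p] - te[tr]) <= threshold
    p <- p[okc]; tr <- tr[okc]
    if (!length(p))
        return(data.frame(pred = integer(), truth = integer(),
                          dStart = integer(), dEnd = integer()))
    dS <- abs(ps[p] - ts[tr]); dE <- abs(pe[p] - te[tr])
    o <- order(dS, dE, p, tr)
    p <- p[o]; tr <- tr[o]; dS <- dS[o]; dE <- dE[o]
    usedP <- logical(length(predicted)); usedT <- logical(length(truth))
    keep <- logical(length(p))
    for (i in seq_along(p)) {
        if (!usedP[p[i]] && !usedT[tr[i]]) {
            keep[i] <- TRUE; usedP[p[i]] <- TRUE; usedT[tr[i]] <- TRUE
        }
    }
    data.frame(pred = p[keep], truth = tr[keep],
               dStart = dS[keep], dEnd = dE[keep])
}

#' Benchmark predicted circles against simulated ground truth
#'
#' Matches predictions to truth circles one-to-one under the endpoint
#' threshold (greedy, nearest start first) and computes
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and
#' `F = 2 * precision * recall / (precision + recall)`. TP counts truth
#' circles claimed by a prediction, FN the unmatched truth, FP the
#' predictions matching no truth circle. Degenerate ratios (no predictions,
#' or precision + recall = 0) are reported as 0.
#'
#' @param predicted,truth `GRanges` of circles (see [circles()]); `truth`
#'   must be non-empty.
#' @param threshold endpoint matching threshold in bp (default 20).
#' @return a [BenchmarkReport].
#' @examples
#' truth <- circles("chr1", c(100, 1000, 5000), c(600, 1900, 5700))
#' pred  <- circles("chr1", c(103, 4000), c(598, 4800))
#' benchmarkCircles(pred, truth)
#' @export
benchmarkCircles <- function(predicted, truth, threshold = 20L) {
    threshold <- as.integer(threshold)
    if (length(truth) == 0L) stop("truth set must be non-empty")
    m <- .assignMatches(predicted, truth, threshold)
    tp <- nrow(m)
    fp <- length(predicted) - tp
    fn <- length(truth) - tp
    precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
    recall <- tp / (tp + fn)
    f <- if (precision + recall > 0) {
        2 * precision * recall / (precision + recall)
    } else 0
    offr <- if (tp > 0L) sum(m$dStart <= 1L & m$dEnd <= 1L) / tp else 0
    new("BenchmarkReport", tp = as.integer(tp), fp = as.integer(fp),
        fn = as.integer(fn), precision = precision, recall = recall,
        fScore = f, offsetRatio = offr, threshold = threshold)
}

#' Junction-coordinate precision ratio
#'
#' The fraction of truth circles recovered with both junction coordinates
#' within 1 bp, among those recovered at the full matching threshold. A
#' ratio near 1 means circles are detected essentially coordinate-exact; low
#' ratios mean detections rely on the looser threshold.
#'
#' @inheritParams benchmarkCircles
#' @return a fraction in `[0, 1]` (0 when nothing matches at the threshold).
#' @export
offsetRatio <- function(predicted, truth, threshold = 20L) {
    m <- .assignMatches(predicted, truth, as.integer(threshold))
    if (nrow(m) == 0L) return(0)
    sum(m$dStart <= 1L & m$dEnd <= 1L) / nrow(m)
}

#' Compare circle length distributions
#'
#' Two-sample Kolmogorov-Smirnov test between predicted and true circle
#' lengths, restricted to a length range — the full simulated range, or a
#' short-circle subrange where detection bias concentrates.
#'
#' @param predictedLengths,truthLengths numeric vectors of circle lengths
#'   (bp), e.g. `width()` of circle `GRanges`.
#' @param lengthRange inclusive `c(min, max)` restriction applied to both
#'   samples before testing (default the full simulated range
#'   `c(175, 10000)`).
#' @return list with `statistic` (the KS D) and `p.value`.
#' @export
lengthKS <- function(predictedLengths, truthLengths,
                     lengthRange = c(175, 10000)) {
    p <- predictedLengths[predictedLengths >= lengthRange[1] &
                              predictedLengths <= lengthRange[2]]
    t <- truthLengths[truthLengths >= lengthRange[1] &
                          truthLengths <= lengthRange[2]]
    if (length(p) == 0L || length(t) == 0L)
        stop("no lengths left in range [", lengthRange[1], ", ",
             lengthRange[2], "]")
    ks <- suppressWarnings(stats::ks.test(p, t))
    list(statistic = unname(ks$statistic), p.value = unname(ks$p.value))
}

#' Yates-corrected chi-square statistic for a 2x2 table
#'
#' Continuity-corrected chi-square
#' `sum((max(|O - E| - 0.5, 0))^2 / E)` with expected counts from the row
#' and column marginals. The correction term is clamped at zero so a
#' perfectly proportional table scores 0.
#'
#' @param tab a 2x2 matrix of non-negative counts.
#' @return the corrected chi-square statistic (numeric).
#' @examples
#' chisqYates(matrix(c(3, 67387, 642, 14847), nrow = 2, byrow = TRUE))
#' @export
chisqYates <- function(tab) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
    if (any(tab < 0)) stop("counts must be non-negative")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("zero marginal")
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
}
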