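#' MAPQ-derived read weight
#'
#' Converts a mapping quality to the probability that the alignment is
#' correct, `w = 1 - 10^(-MAPQ/10)`, used to weight each read's contribution
#' to the junction-side counts.
#'
#' @param mapq non-negative mapping quality (vectorised).
#' @return weights in `[0, 1)`.
#' @examples
#' mapqWeight(c(0, 10, 20, 60))
#' @export
mapqWeight <- function(mapq) {
    if (any(mapq < 0)) stop("MAPQ must be non-negative")
    1 - 10^(-mapq / 10)
}

#' Expected left-side probability from junction mappability
#'
#' Converts the mean mappabilities of the two 30-nt regions just inside a
#' circle's junction boundaries into the expected probability that a
#' junction-spanning read is assigned to the left side:
#' `p_L = M_L / (M_L + M_R)`. When both mappabilities are zero or missing
#' there is no information and `NA` is returned; callers fall back to the
#' symmetric `p_L = 0.5`.
#'
#' @param mL,mR mean mappability of the left/right inside-junction region,
#'   in `[0, 1]` (or `NA`).
#' @return `p_L` in `[0, 1]`, or `NA` when undefined.
#' @examples
#' junctionProbability(0.8, 0.8)     # 0.5
#' junctionProbability(1.0, 0.470)   # 0.6803...
#' @export
junctionProbability <- function(mL, mR) {
    if (is.na(mL) || is.na(mR)) return(NA_real_)
    if (mL < 0 || mR < 0) stop("mappability must be non-negative")
    if (mL + mR == 0) return(NA_real_)
    mL / (mL + mR)
}

#' Junction imbalance statistic
#'
#' `deltaCJ = |k_L - k_R| / N` with `N = k_L + k_R`: 0 when reads support
#' both sides of the circular junction equally, 1 when all support is
#' one-sided (a hallmark of misdetected circles). Undefined (`NA`) when no
#' reads support either side.
#'
#' @param kL,kR effective read counts on the left/right junction side
#'   (vectorised).
#' @return values in `[0, 1]`, `NA` where `k_L + k_R == 0`.
#' @examples
#' deltaCJstat(22, 22)   # 0
#' deltaCJstat(28, 0)    # 1
#' @export
deltaCJstat <- function(kL, kR) {
    if (any(kL < 0 | kR < 0)) stop("counts must be non-negative")
    n <- kL + kR
    ifelse(n > 0, abs(kL - kR) / n, NA_real_)
}

#' Symmetric doubled binomial tail, uncapped
#'
#' Exact evaluation of `2 * 0.5^N * sum_{i=0}^{k} choose(N, i)` — the
#' probability of a side-assignment at least as extreme as `k` out of `N`
#' junction reads when both sides are equally likely, doubled because the
#' labelling of sides is arbitrary. At the midpoint of an even `N` the
#' doubling counts `P(X = N/2)` twice and the raw value exceeds 1 (for
#' example `k = 3, N = 6` gives 1.3125); [symmetricP()] applies the cap.
#'
#' @param k smaller side count, `0 <= k <= n/2`.
#' @param n total junction reads.
#' @return the uncapped tail probability (may exceed 1).
#' @export
symmetricTailRaw <- function(k, n) {
    if (k < 0 || n < 0 || k > n / 2)
        stop("need 0 <= k <= n/2")
    2 * 0.5^n * sum(choose(n, 0:k))
}

#' Symmetric two-sided junction probability
#'
#' [symmetricTailRaw()] capped at 1; by the midpoint rule a balanced even
#' split (`k = N/2`) is reported as exactly 1 — midpoints are irrelevant for
#' flagging outliers.
#'
#' @inheritParams symmetricTailRaw
#' @return a probability in `[0, 1]`.
#' @examples
#' symmetricP(3, 6)    # 1 (midpoint rule)
#' symmetricP(1, 9)    # 0.0390625
#' @export
symmetricP <- function(k, n) {
    if (n > 0 && n %% 2 == 0 && k == n / 2) return(1)
    min(1, symmetricTailRaw(k, n))
}

#' Mappability-adjusted two-sided junction probability
#'
#' Two-sided binomial tail for the observed left/right junction split when
#' the expected left-side probability `p_L` differs from 0.5 (unequal
#' mappability). The tail is evaluated on the deficit side — the side whose
#' observed count falls below its expectation `N * p` — doubled, and capped
#' at 1; with `p_L = 0.5` this reduces exactly to [symmetricP()]. Degenerate
#' expectations (`p_L` of 0 or 1) give probability 0 when reads appear on
#' the impossible side and 1 otherwise.
#'
#' @param kL,kR observed left/right effective read counts.
#' @param pL expected left-side probability from [junctionProbability()].
#' @return a probability in `[0, 1]`.
#' @examples
#' adjustedP(28, 0, junctionProbability(1.0, 0.470))
#' @export
adjustedP <- function(kL, kR, pL) {
    if (kL < 0 || kR < 0) stop("counts must be non-negative")
    n <- kL + kR
    if (n == 0) stop("N must be positive")
    if (is.na(pL)) pL <- 0.5
    if (pL <= 0 || pL >= 1) {
        impossible <- (pL <= 0 && kL > 0) || (pL >= 1 && kR > 0)
        return(if (impossible) 0 else 1)
    }
    if (pL == 0.5) return(symmetricP(min(kL, kR), n))
    ## deficit side: observed count below its expectation
    if (kL / n < pL) {
        tail <- stats::pbinom(kL, n, pL)
    } else {
        tail <- stats::pbinom(kR, n, 1 - pL)
    }
    min(1, 2 * tail)
}

#' Minimum junction reads for a detectable imbalance
#'
#' Solves `2 (N + 1) 0.5^N = alpha` for continuous `N` — the point past
#' which even the most nearly extreme split (one read on one side) has a
#' doubled symmetric tail below `alpha` — and reports the smallest integer
#' `N` strictly satisfying the inequality. With `alpha = 0.05` the root is
#' about 8.58, so at least 9 junction reads are needed before a skew can be
#' called significant.
#'
#' @param alpha significance level in (0, 1).
#' @return list with `nContinuous` (the root, to 1e-6) and `nMin` (smallest
#'   integer with `2 (N + 1) 0.5^N < alpha`).
#' @examples
#' minReadsForSignificance(0.05)
#' @export
minReadsForSignificance <- function(alpha = 0.05) {
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    f <- function(n) 2 * (n + 1) * 0.5^n - alpha
    ## 2(N+1)0.5^N is decreasing for N >= 1/log(2) - 1; root is unique there
    root <- stats::uniroot(f, c(1, 200), tol = 1e-9)$root
    nMin <- ceiling(root)
    if (f(nMin) >= 0) nMin <- nMin + 1  # strict inequality
    list(nContinuous = root, nMin = as.integer(nMin))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of junction
#' probabilities; output order matches input order.
#'
#' @param p probabilities in `[0, 1]` (`NA` allowed, passed through).
#' @return adjusted probabilities.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

## Split window reads into left-only / right-only / both, honoring the
## larger-overlap rule for reads seen in both windows (ties and unknown
## extents are side-uninformative and dropped).
.splitSharedReads <- function(lw, rw, lwin, rwin) {
    shared <- intersect(lw$name, rw$name)
    keepL <- lw[!(lw$name %in% shared), , drop = FALSE]
    keepR <- rw[!(rw$name %in% shared), , drop = FALSE]
    for (nm in shared) {
        li <- lw[match(nm, lw$name), , drop = FALSE]
        ri <- rw[match(nm, rw$name), , drop = FALSE]
        if (is.na(li$start) || is.na(ri$start)) next
        ovL <- min(li$end, lwin[2]) - max(li$start, lwin[1]) + 1
        ovR <- min(ri$end, rwin[2]) - max(ri$start, rwin[1]) + 1
        if (ovL > ovR) keepL <- rbind(keepL, li)
        else if (ovR > ovL) keepR <- rbind(keepR, ri)
        ## tie: contributes to neither side
    }
    list(left = keepL, right = keepR)
}

#' Collect junction evidence for one circle
#'
#' Gathers the per-side effective read counts and mappability context that
#' feed the deltaCJ statistic. Windows of `nOffset` bases up- and downstream
#' are placed on each junction coordinate (the circle's BED start and end);
#' unique reads per window are weighted by [mapqWeight()] and each side's
#' weighted sum is ceilinged to an integer (a positive sum always yields at
#' least 1; an empty side stays 0). Reads appearing in both windows count
#' toward the side with the larger window overlap; exact ties are
#' side-uninformative and dropped. Mean mappability is taken over the 30-nt
#' regions immediately inside each boundary (for circles shorter than 60 bp
#' both regions collapse to the whole circle).
#'
#' @param source an alignment source implementing [junctionReads()].
#' @param circle a length-1 `GRanges` (see [circles()]).
#' @param mappability optional track implementing [trackMean()]; when
#'   `NULL` or without data, `p_L` falls back to 0.5.
#' @param nOffset window half-width in bases (default 20).
#' @return list with `kL`, `kR`, `N`, `mL`, `mR`, `pL` and
#'   `mappabilityMissing` (TRUE when the 0.5 fallback was used).
#' @export
collectEvidence <- function(source, circle, mappability = NULL,
                            nOffset = 20L) {
    stopifnot(length(circle) == 1L)
    chrom <- as.character(GenomeInfoDb::seqnames(circle))
    jl <- bedStart(circle)          # left junction coordinate (BED)
    jr <- bedEnd(circle)            # right junction coordinate
    lwin <- c(max(1L, jl - nOffset + 1L), jl + nOffset)  # 1-based windows
    rwin <- c(max(1L, jr - nOffset + 1L), jr + nOffset)
    lw <- .uniqueReads(junctionReads(source, chrom, lwin[1], lwin[2]))
    rw <- .uniqueReads(junctionReads(source, chrom, rwin[1], rwin[2]))
    sides <- .splitSharedReads(lw, rw, lwin, rwin)
    kL <- .ceilWeight(sides$left$mapq)
    kR <- .ceilWeight(sides$right$mapq)
    mL <- mR <- NA_real_
    if (!is.null(mappability)) {
        w <- GenomicRanges::width(circle)
        if (w >= 60L) {
            mL <- trackMean(mappability, chrom, jl + 1L, jl + 30L)
            mR <- trackMean(mappability, chrom, jr - 29L, jr)
        } else {
            mL <- trackMean(mappability, chrom, jl + 1L, jr)
            mR <- mL
        }
    }
    pL <- junctionProbability(mL, mR)
    missing <- is.na(pL)
    if (missing) pL <- 0.5
    list(kL = kL, kR = kR, N = kL + kR, mL = mL, mR = mR, pL = pL,
         mappabilityMissing = missing)
}

.uniqueReads <- function(df) {
    if (is.null(df$start)) df$start <- NA_integer_
    if (is.null(df$end)) df$end <- NA_integer_
    df[!duplicated(df$name), , drop = FALSE]
}

.ceilWeight <- function(mapq) {
    if (length(mapq) == 0L) return(0L)
    as.integer(ceiling(sum(mapqWeight(mapq))))
}

#' Junction-imbalance screen over a circle set
#'
#' Runs [collectEvidence()], the deltaCJ statistic and its binomial
#' significance test over every circle in a set, then applies
#' Benjamini-Hochberg correction across the set (one adjustment family per
#' invocation). Circles with no junction reads get `NA` statistics.
#'
#' @param circleSet a `GRanges` of circles (see [circles()]).
#' @param source an alignment source implementing [junctionReads()].
#' @param mappability optional track implementing [trackMean()].
#' @param nOffset junction window half-width (default 20).
#' @param alpha significance level applied to the adjusted probabilities
#'   (default 0.05).
#' @return a `data.frame` with one row per circle: `chrom`, `start`, `end`
#'   (BED convention), `kL`, `kR`, `N`, `mL`, `mR`, `pL`, `deltaCJ`, `p`,
#'   `pAdj`, `significant`, `mappabilityMissing`.
#' @export
deltaCJ <- function(circleSet, source, mappability = NULL, nOffset = 20L,
                    alpha = 0.05) {
    n <- length(circleSet)
    if (n == 0L) stop("empty circle set")
    rows <- lapply(seq_len(n), function(i) {
        ev <- collectEvidence(source, circleSet[i], mappability, nOffset)
        d <- deltaCJstat(ev$kL, ev$kR)
        p <- if (ev$N > 0) adjustedP(ev$kL, ev$kR, ev$pL) else NA_real_
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(circleSet[i])),
                   start = bedStart(circleSet[i]),
                   end = bedEnd(circleSet[i]),
                   kL = ev$kL, kR = ev$kR, N = ev$N,
                   mL = ev$mL, mR = ev$mR, pL = ev$pL,
                   deltaCJ = d, p = p,
                   mappabilityMissing = ev$mappabilityMissing,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$pAdj <- bhAdjust(out$p)
    out$significant <- !is.na(out$pAdj) & out$pAdj < alpha
    out
}

#' Cohort-level circle-quality metrics
#'
#' Summarises a [deltaCJ()] result table into the three detection-quality
#' metrics: the proportion of circles with enough junction reads for the
#' imbalance test to have power (`N >= 9`, from
#' [minReadsForSignificance()] at alpha 0.05), the mean and median deltaCJ
#' over those circles, and the proportion of circles whose adjusted
#' probability falls below `alpha`. Circles with no junction reads (`N == 0`)
#' are excluded from the denominators.
#'
#' @param results a `data.frame` from [deltaCJ()].
#' @param nMin minimum junction reads for the selected-circle summary
#'   (default 9).
#' @param alpha significance level (default 0.05).
#' @return list with `propNge9`, `meanDeltaCJ`, `medianDeltaCJ`,
#'   `propSignificant` (`NA` summaries when no circle reaches `nMin`).
#' @export
cohortMetrics <- function(results, nMin = 9L, alpha = 0.05) {
    if (nrow(results) == 0L) stop("empty result set")
    def <- results[!is.na(results$N) & results$N > 0L, , drop = FALSE]
    if (nrow(def) == 0L) stop("no circle has junction reads")
    sel <- def[def$N >= nMin, , drop = FALSE]
    list(propNge9 = nrow(sel) / nrow(def),
         meanDeltaCJ = if (nrow(sel)) mean(sel$deltaCJ) else NA_real_,
         medianDeltaCJ = if (nrow(sel)) stats::median(sel$deltaCJ)
                         else NA_real_,
         propSignificant = mean(def$pAdj < alpha, na.rm = TRUE))
}

#' Difference in mean junction imbalance between two cohorts
#'
#' `deltaDeltaCJ = mean(deltaCJ, reference) - mean(deltaCJ, other)`;
#' negative values mean the reference cohort (e.g. a Rosette consensus) is
#' the more balanced one.
#'
#' @param reference,other `data.frame`s from [deltaCJ()] (or any frames
#'   with a `deltaCJ` column).
#' @return a single numeric difference.
#' @export
deltaDeltaCJ <- function(reference, other) {
    if (nrow(reference) == 0L || nrow(other) == 0L)
        stop("cohorts must be non-empty")
    mean(reference$deltaCJ, na.rm = TRUE) - mean(other$deltaCJ, na.rm = TRUE)
}
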