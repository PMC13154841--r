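## shared fixture builders; everything is generated in code at test time

randomGenome <- function(lens, seed = 1L) {
    set.seed(seed)
    vapply(lens, function(l)
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
              collapse = ""), "")
}

## random per-tool circle sets on one chromosome
randomToolSets <- function(nTools, nCircles, seed = 1L, chromLen = 1e6) {
    set.seed(seed)
    out <- list()
    for (t in seq_len(nTools)) {
        st <- sort(sample.int(chromLen - 5000L, nCircles))
        len <- sample(200:2000, nCircles, replace = TRUE)
        out[[paste0("tool", t)]] <-
            circles("chr1", st, st + len,
                    splitReads = sample(0:20, nCircles, replace = TRUE),
                    tool = paste0("tool", t))
    }
    out
}

## exhaustive left/right assignment oracle: P(#left <= k) over all 2^n
## equally likely side assignments, counted bit by bit (no choose())
enumTailP <- function(k, n) {
    if (n == 0) return(as.numeric(k >= 0))
    counts <- vapply(0:(2^n - 1), function(x) {
        sum(bitwAnd(x, 2^(0:(n - 1))) > 0)
    }, numeric(1))
    mean(counts <= k)
}

## brute-force benchmark oracle: greedy one-to-one matching by start offset
bruteBenchmark <- function(pred, truth, threshold = 20L) {
    pc <- as.character(GenomeInfoDb::seqnames(pred))
    tc <- as.character(GenomeInfoDb::seqnames(truth))
    ps <- GenomicRanges::start(pred); pe <- GenomicRanges::end(pred)
    ts <- GenomicRanges::start(truth); te <- GenomicRanges::end(truth)
    pairs <- expand.grid(p = seq_along(pred), t = seq_along(truth))
    ok <- pc[pairs$p] == tc[pairs$t] &
        abs(ps[pairs$p] - ts[pairs$t]) <= threshold &
        abs(pe[pairs$p] - te[pairs$t]) <= threshold
    pairs <- pairs[ok, , drop = FALSE]
    pairs$dS <- abs(ps[pairs$p] - ts[pairs$t])
    pairs$dE <- abs(pe[pairs$p] - te[pairs$t])
    pairs <- pairs[order(pairs$dS, pairs$dE, pairs$p, pairs$t), ,
                   drop = FALSE]
    usedP <- usedT <- integer(0); tp <- 0L
    for (i in seq_len(nrow(pairs))) {
        if (!(pairs$p[i] %in% usedP) && !(pairs$t[i] %in% usedT)) {
            tp <- tp + 1L
            usedP <- c(usedP, pairs$p[i]); usedT <- c(usedT, pairs$t[i])
        }
    }
    list(tp = tp, fp = length(pred) - tp, fn = length(truth) - tp)
}
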