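#' Filtering strategies for predicted circles
#'
#' Four strategies for reducing false-positive circle calls before
#' benchmarking or combination:
#' \describe{
#'   \item{`filterSplit()`}{keeps circles supported by at least `minSplit`
#'     split reads. Circles without split-read information (all `NA`, as for
#'     tools that do not report it) pass through unchanged — the filter is
#'     inapplicable, not failed.}
#'   \item{`filterDuplicates()`}{removes overlapping circles. Two circles
#'     overlap when their regions share at least one base on the same
#'     chromosome. Among overlapping circles the one with the highest
#'     split-read support is kept; without split information the longest
#'     wins; remaining ties go to the smallest coordinates. Resolution is
#'     greedy in that priority order, so the output is overlap-free and
#'     deterministic for chains of mutually overlapping calls.}
#'   \item{`filterBoth()`}{applies `filterSplit()` first, then
#'     `filterDuplicates()`.}
#'   \item{`filterNone()`}{identity; included so a strategy name can always
#'     be mapped to a function.}
#' }
#' All four are idempotent.
#'
#' @param x a `GRanges` of circles (see [circles()]).
#' @param minSplit minimum split-read support (default 2).
#' @return a filtered `GRanges` (subset of the input, original order kept).
#' @examples
#' x <- circles("chr1", c(100, 400, 2000), c(500, 900, 2400),
#'              splitReads = c(5, 3, 1))
#' filterSplit(x)        # drops the 1-split circle
#' filterDuplicates(x)   # drops the overlapping 3-split circle
#' filterBoth(x)
#' @name filters
NULL

#' @rdname filters
#' @export
filterSplit <- function(x, minSplit = 2L) {
    sr <- S4Vectors::mcols(x)$split_reads
    if (is.null(sr) || all(is.na(sr))) return(x)
    x[is.na(sr) | sr >= minSplit]
}

#' @rdname filters
#' @export
filterDuplicates <- function(x) {
    if (length(x) < 2L) return(x)
    sr <- S4Vectors::mcols(x)$split_reads
    sr[is.na(sr)] <- -1L
    prio <- order(-sr, -GenomicRanges::width(x),
                  as.character(GenomeInfoDb::seqnames(x)),
                  GenomicRanges::start(x), GenomicRanges::end(x))
    ov <- GenomicRanges::findOverlaps(x, drop.self = TRUE)
    adj <- split(S4Vectors::subjectHits(ov),
                 factor(S4Vectors::queryHits(ov), levels = seq_along(x)))
    keep <- logical(length(x))
    for (i in prio)
        if (!any(keep[adj[[i]]])) keep[i] <- TRUE
    x[keep]
}

#' @rdname filters
#' @export
filterBoth <- function(x, minSplit = 2L) {
    filterDuplicates(filterSplit(x, minSplit = minSplit))
}

#' @rdname filters
#' @export
filterNone <- function(x) x

#' Look up a filtering strategy by name
#'
#' @param strategy one of `"unfilter"`, `"split"`, `"duplicates"`, `"both"`.
#' @return the corresponding filter function.
#' @export
filterStrategy <- function(strategy = c("unfilter", "split", "duplicates",
                                        "both")) {
    switch(match.arg(strategy),
           unfilter = filterNone,
           split = filterSplit,
           duplicates = filterDuplicates,
           both = filterBoth)
}
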