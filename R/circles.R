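#' Construct a set of circle calls
#'
#' Builds a [GenomicRanges::GRanges] holding predicted or simulated circular
#' elements. Coordinates are supplied in BED convention (0-based, half-open)
#' and stored internally 1-based inclusive as usual for `GRanges`; the two
#' junction coordinates of a circle are its BED `start` and `end`.
#'
#' @param chrom chromosome (sequence) names.
#' @param start,end BED coordinates: 0-based inclusive start, exclusive end.
#' @param splitReads optional split-read support counts (`NA` when the
#'   detection tool reports none).
#' @param tool optional source tool label, recycled.
#' @return a `GRanges` with metadata columns `split_reads` and `tool`.
#' @examples
#' circles("chr1", c(100, 2000), c(500, 2600), splitReads = c(5, 2),
#'         tool = "toolA")
#' @export
circles <- function(chrom, start, end, splitReads = NA_integer_,
                    tool = NA_character_) {
    start <- as.numeric(start); end <- as.numeric(end)
    if (any(start < 0)) stop("negative start coordinate")
    if (any(end <= start)) stop("circle end must exceed start")
    sr <- suppressWarnings(as.integer(splitReads))
    if (any(!is.na(sr) & sr < 0)) stop("negative split-read count")
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start + 1, end = end))
    S4Vectors::mcols(gr)$split_reads <- rep_len(sr, length(gr))
    S4Vectors::mcols(gr)$tool <- rep_len(as.character(tool), length(gr))
    gr
}

bedStart <- function(gr) GenomicRanges::start(gr) - 1L
bedEnd <- function(gr) GenomicRanges::end(gr)

#' Test whether circles are the same call under an endpoint threshold
#'
#' Two circles are considered the same when they lie on the same chromosome
#' and both junction coordinates differ by at most `threshold` base pairs —
#' the matching rule used throughout clustering, combination and
#' benchmarking. Vectorised over pairs (`query` and `subject` are recycled).
#'
#' @param query,subject `GRanges` of circles (see [circles()]).
#' @param threshold maximum per-endpoint coordinate difference in bp
#'   (default 20).
#' @return logical vector.
#' @examples
#' a <- circles("chr1", 100, 500)
#' b <- circles("chr1", 119, 481)
#' circlesMatch(a, b)             # TRUE: both offsets <= 20
#' circlesMatch(a, b, threshold = 10)
#' @export
circlesMatch <- function(query, subject, threshold = 20L) {
    if (threshold < 0) stop("threshold must be non-negative")
    n <- max(length(query), length(subject))
    q <- rep_len(seq_along(query), n)
    s <- rep_len(seq_along(subject), n)
    as.character(GenomeInfoDb::seqnames(query))[q] ==
        as.character(GenomeInfoDb::seqnames(subject))[s] &
        abs(GenomicRanges::start(query)[q] -
            GenomicRanges::start(subject)[s]) <= threshold &
        abs(GenomicRanges::end(query)[q] -
            GenomicRanges::end(subject)[s]) <= threshold
}

## Priority used to pick a cluster representative and to order duplicate
## removal: split support desc, length desc, then (chrom, start, end) asc.
## Returns the index of the best circle among idx.
.bestCircle <- function(gr, idx) {
    sr <- S4Vectors::mcols(gr)$split_reads[idx]
    sr[is.na(sr)] <- -1L
    o <- order(-sr, -GenomicRanges::width(gr)[idx],
               as.character(GenomeInfoDb::seqnames(gr))[idx],
               GenomicRanges::start(gr)[idx],
               GenomicRanges::end(gr)[idx])
    idx[o[1L]]
}

.sortCircleOrder <- function(gr) {
    order(as.character(GenomeInfoDb::seqnames(gr)),
          GenomicRanges::start(gr), GenomicRanges::end(gr),
          S4Vectors::mcols(gr)$tool)
}

#' Cluster circle calls from multiple tools
#'
#' Groups circles that represent the same call under the endpoint
#' `threshold` into [CircleClusters]. Clustering is representative-anchored
#' rather than transitive: circles are processed in (chrom, start, end, tool)
#' order and each joins the first existing cluster whose current
#' representative it matches, otherwise it seeds a new cluster. The
#' representative is the member with the highest split-read support (ties:
#' longest, then smallest coordinates). Anchoring bounds the coordinate
#' spread within a cluster to the threshold around the representative, which
#' transitive chaining would not.
#'
#' @param toolSets either a named list of `GRanges` (one per tool; names are
#'   used as tool labels) or a single `GRanges` whose `tool` column is set.
#' @param threshold endpoint matching threshold in bp (default 20).
#' @return a [CircleClusters] object.
#' @examples
#' a <- circles("chr1", c(100, 5000), c(500, 6000), tool = "A")
#' b <- circles("chr1", 105, 498, tool = "B")
#' cl <- clusterCircles(list(A = a, B = b))
#' clusterSupport(cl)
#' @export
clusterCircles <- function(toolSets, threshold = 20L) {
    threshold <- as.integer(threshold)
    if (threshold < 0L) stop("threshold must be non-negative")
    gr <- .poolToolSets(toolSets)
    if (length(gr) == 0L)
        return(new("CircleClusters", members = gr,
                   representatives = gr, support = integer(),
                   threshold = threshold))
    ord <- .sortCircleOrder(gr)
    cluster <- integer(length(gr))
    repIdx <- integer(0)          # current representative per cluster
    memberIdx <- list()
    for (i in ord) {
        hit <- 0L
        if (length(repIdx)) {
            m <- which(circlesMatch(gr[i], gr[repIdx], threshold))
            if (length(m)) hit <- m[1L]
        }
        if (hit > 0L) {
            memberIdx[[hit]] <- c(memberIdx[[hit]], i)
            cluster[i] <- hit
            repIdx[hit] <- .bestCircle(gr, memberIdx[[hit]])
        } else {
            memberIdx[[length(memberIdx) + 1L]] <- i
            repIdx <- c(repIdx, i)
            cluster[i] <- length(memberIdx)
        }
    }
    S4Vectors::mcols(gr)$cluster <- cluster
    support <- vapply(memberIdx, function(ix) {
        length(unique(S4Vectors::mcols(gr)$tool[ix]))
    }, integer(1))
    new("CircleClusters", members = gr, representatives = gr[repIdx],
        support = support, threshold = threshold)
}

.poolToolSets <- function(toolSets) {
    if (is.list(toolSets)) {
        if (length(toolSets) && is.null(names(toolSets)))
            names(toolSets) <- paste0("tool", seq_along(toolSets))
        pooled <- lapply(names(toolSets), function(nm) {
            g <- toolSets[[nm]]
            if (!methods::is(g, "GRanges"))
                stop("each tool set must be a GRanges")
            if (is.null(S4Vectors::mcols(g)$split_reads))
                S4Vectors::mcols(g)$split_reads <- NA_integer_
            S4Vectors::mcols(g)$tool <- nm
            S4Vectors::mcols(g) <-
                S4Vectors::mcols(g)[, c("split_reads", "tool")]
            g
        })
        if (length(pooled) == 0L)
            return(circles(character(0), numeric(0), numeric(0)))
        return(do.call(c, pooled))
    }
    if (!methods::is(toolSets, "GRanges"))
        stop("toolSets must be a GRanges or a named list of GRanges")
    if (is.null(S4Vectors::mcols(toolSets)$split_reads))
        S4Vectors::mcols(toolSets)$split_reads <- NA_integer_
    if (is.null(S4Vectors::mcols(toolSets)$tool))
        S4Vectors::mcols(toolSets)$tool <- NA_character_
    toolSets
}
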