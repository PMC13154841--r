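#' Combine circle calls from several detection tools
#'
#' Implements the five consensus strategies over threshold-clustered circles.
#' With `n` tools and a cluster supported by `s` distinct tools:
#' \describe{
#'   \item{union}{all circles detected by any tool (`s >= 1`).}
#'   \item{unique}{circles detected by exactly one tool (`s == 1`).}
#'   \item{intersect}{circles detected by all tools (`s == n`).}
#'   \item{double}{circles detected by at least two but not all tools
#'     (`2 <= s < n`) — the union minus unique and intersect.}
#'   \item{rosette}{circles detected by at least two tools (`s >= 2`) in a
#'     combination of three or more tools; the consensus that balances
#'     precision against recall.}
#' }
#' Each selected cluster is reported by its representative circle (highest
#' split-read support, then longest). By construction the union is the
#' disjoint union of unique, double and intersect, and
#' `intersect <= rosette <= union`.
#'
#' @param toolSets named list of `GRanges`, one per tool (see
#'   [clusterCircles()]), or an existing [CircleClusters] object.
#' @param strategy combination strategy name.
#' @param threshold endpoint matching threshold in bp (default 20).
#' @param nTools number of tools; inferred from `toolSets` when it is a
#'   list, required when passing pre-built clusters.
#' @return a [CombinationResult]; its `circles` slot holds the selected
#'   representatives with a `support` metadata column.
#' @examples
#' a <- circles("chr1", c(100, 900), c(500, 1600), tool = "A")
#' b <- circles("chr1", c(102, 5000), c(503, 5800), tool = "B")
#' cc <- circles("chr1", 99, 498, tool = "C")
#' combineCircles(list(A = a, B = b, C = cc), "rosette")
#' @export
combineCircles <- function(toolSets,
                           strategy = c("union", "rosette", "intersect",
                                        "double", "unique"),
                           threshold = 20L, nTools = NULL) {
    strategy <- match.arg(strategy)
    if (methods::is(toolSets, "CircleClusters")) {
        cl <- toolSets
        if (is.null(nTools))
            stop("nTools is required when passing pre-built clusters")
    } else {
        if (!is.list(toolSets))
            stop("toolSets must be a named list of GRanges per tool")
        nTools <- length(toolSets)
        cl <- clusterCircles(toolSets, threshold = threshold)
    }
    nTools <- as.integer(nTools)
    if (nTools < 2L) stop("combination requires at least 2 tools")
    if (strategy == "rosette" && nTools < 3L)
        stop("the rosette strategy requires a combination of at least 3 tools")
    s <- clusterSupport(cl)
    sel <- switch(strategy,
                  union = s >= 1L,
                  unique = s == 1L,
                  intersect = s == nTools,
                  double = s >= 2L & s < nTools,
                  rosette = s >= 2L)
    out <- representatives(cl)[sel]
    S4Vectors::mcols(out)$support <- s[sel]
    new("CombinationResult", strategy = strategy, nTools = nTools,
        circles = out, clusters = cl)
}

#' @describeIn combineCircles selected representative circles.
#' @param x a `CombinationResult`.
#' @export
combinedCircles <- function(x) {
    stopifnot(methods::is(x, "CombinationResult"))
    x@circles
}

#' Per-cluster tool membership table
#'
#' Summarises a clustering as one row per cluster with its representative
#' coordinates, support, and one logical column per tool — the input for
#' UpSet-style intersection plots.
#'
#' @param clusters a [CircleClusters] object.
#' @return a `data.frame` with columns `chrom`, `start`, `end` (BED
#'   convention), `support`, then one logical column per tool label.
#' @export
supportTable <- function(clusters) {
    stopifnot(methods::is(clusters, "CircleClusters"))
    rep <- representatives(clusters)
    mem <- clusterMembers(clusters)
    tools <- sort(unique(S4Vectors::mcols(mem)$tool))
    out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(rep)),
                      start = bedStart(rep), end = bedEnd(rep),
                      support = clusterSupport(clusters),
                      stringsAsFactors = FALSE)
    for (tl in tools)
        out[[tl]] <- vapply(seq_len(length(rep)), function(i) {
            any(S4Vectors::mcols(mem)$tool == tl &
                    S4Vectors::mcols(mem)$cluster == i, na.rm = TRUE)
        }, logical(1))
    out
}
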