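#' @import methods
#' @importFrom stats median p.adjust pbinom uniroot ks.test setNames runif rbinom
#' @importFrom utils read.table write.table head
NULL

#' Query reads overlapping a genomic window
#'
#' Generic contract used by the junction-imbalance statistic: given a
#' chromosome and a window, return one row per alignment overlapping the
#' window, with the read name, its MAPQ, and (when known) the aligned
#' start/end. Implementations exist for in-memory read placements
#' ([FixtureAlignments]) and coordinate-sorted indexed BAM files
#' ([BamAlignments]).
#'
#' @param x an alignment source.
#' @param chrom chromosome name.
#' @param start,end window bounds, 1-based inclusive.
#' @return a `data.frame` with columns `name`, `mapq`, `start`, `end`
#'   (`start`/`end` may be `NA` when the source does not track extents).
#' @export
setGeneric("junctionReads", function(x, chrom, start, end)
    standardGeneric("junctionReads"))

#' Mean track value over an interval
#'
#' Generic contract for mappability tracks: the mean signal over a 1-based
#' inclusive interval, in `[0, 1]`. Returns `NA` (distinct from 0) where the
#' track has no data.
#'
#' @param x a mappability track.
#' @param chrom chromosome name.
#' @param start,end interval bounds, 1-based inclusive.
#' @return a single numeric value in `[0, 1]`, or `NA`.
#' @export
setGeneric("trackMean", function(x, chrom, start, end)
    standardGeneric("trackMean"))

#' @rdname CircleClusters-class
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname CircleClusters-class
#' @export
setGeneric("clusterSupport", function(x) standardGeneric("clusterSupport"))

#' @rdname CircleClusters-class
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
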