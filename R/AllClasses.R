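#' Clustered multi-tool circle calls
#'
#' Groups circles reported by several detection tools into clusters of calls
#' considered identical under the endpoint matching threshold. Each cluster
#' carries one representative circle (highest split-read support, ties broken
#' by length then coordinates) and a support count equal to the number of
#' distinct tools contributing members.
#'
#' @slot members a [GenomicRanges::GRanges] of all input circles, with
#'   metadata columns `split_reads`, `tool` and `cluster` (1-based cluster
#'   index).
#' @slot representatives a `GRanges` with one representative per cluster.
#' @slot support integer vector, distinct tools per cluster.
#' @slot threshold the endpoint matching threshold (bp) used.
#'
#' @aliases representatives clusterSupport clusterMembers
#' @export
setClass("CircleClusters",
    representation(members = "GRanges",
                   representatives = "GRanges",
                   support = "integer",
                   threshold = "integer"))

setValidity("CircleClusters", function(object) {
    msg <- NULL
    ncl <- length(object@representatives)
    if (length(object@support) != ncl)
        msg <- c(msg, "support length must equal number of clusters")
    cl <- object@members$cluster
    if (length(object@members) && (is.null(cl) ||
            any(cl < 1L) || any(cl > ncl)))
        msg <- c(msg, "member cluster indices out of range")
    if (length(object@members) &&
            !setequal(unique(cl), seq_len(ncl)))
        msg <- c(msg, "every cluster must have at least one member")
    if (object@threshold < 0L)
        msg <- c(msg, "threshold must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CircleClusters-class representative circle per cluster.
#' @param x a `CircleClusters` object.
#' @export
setMethod("representatives", "CircleClusters", function(x) x@representatives)

#' @describeIn CircleClusters-class distinct-tool support per cluster.
#' @export
setMethod("clusterSupport", "CircleClusters", function(x) x@support)

#' @describeIn CircleClusters-class all member circles with cluster index.
#' @export
setMethod("clusterMembers", "CircleClusters", function(x) x@members)

setMethod("show", "CircleClusters", function(object) {
    cat("CircleClusters with", length(object@representatives),
        "clusters from", length(object@members), "circles",
        sprintf("(threshold %d bp)\n", object@threshold))
    if (length(object@support)) {
        tab <- table(object@support)
        cat("  support:", paste(sprintf("%s tool(s): %d", names(tab), tab),
                                collapse = ", "), "\n")
    }
})

#' Simulation parameters for circular/linear read generation
#'
#' Holds every knob of the read simulator: the circle-length distribution,
#' fold-coverage, read and insert lengths, the per-base sequencing-error and
#' mutation rates, the transition/transversion ratio of the two-parameter
#' Kimura substitution model, and the optional junction-enrichment fraction.
#'
#' @slot distKind `"uniform"` or `"lognormal"` circle length distribution.
#' @slot minLen,maxLen circle length bounds (bp).
#' @slot s,loc,scale lognormal shape, location and scale (median) parameters.
#' @slot coverage requested fold-coverage per circle.
#' @slot readLength,insertLength read and insert lengths (bp).
#' @slot seqErrorRate per-base sequencing error probability.
#' @slot mutationRate per-base mutation probability (Kimura two-parameter).
#' @slot kappa transition/transversion rate ratio of the Kimura model.
#' @slot nearCJFraction fraction of fragments forced to start within one
#'   insert length upstream of the circular junction (0 = uniform).
#'
#' @export
setClass("SimulationParams",
    representation(distKind = "character",
                   minLen = "numeric", maxLen = "numeric",
                   s = "numeric", loc = "numeric", scale = "numeric",
                   coverage = "numeric",
                   readLength = "integer", insertLength = "integer",
                   seqErrorRate = "numeric", mutationRate = "numeric",
                   kappa = "numeric", nearCJFraction = "numeric"))

setValidity("SimulationParams", function(object) {
    msg <- NULL
    if (!object@distKind %in% c("uniform", "lognormal"))
        msg <- c(msg, "distKind must be 'uniform' or 'lognormal'")
    if (object@minLen < 1 || object@maxLen < object@minLen)
        msg <- c(msg, "need 1 <= minLen <= maxLen")
    if (object@distKind == "lognormal" && (object@s <= 0 || object@scale <= 0))
        msg <- c(msg, "lognormal needs s > 0 and scale > 0")
    if (object@coverage <= 0) msg <- c(msg, "coverage must be > 0")
    if (object@readLength > object@insertLength)
        msg <- c(msg, "readLength must not exceed insertLength")
    for (r in c("seqErrorRate", "mutationRate", "nearCJFraction")) {
        v <- slot(object, r)
        if (v < 0 || v > 1) msg <- c(msg, paste(r, "must be in [0, 1]"))
    }
    if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' @param distKind,minLen,maxLen,s,loc,scale,coverage,readLength,insertLength
#'   see slot descriptions.
#' @param seqErrorRate,mutationRate,kappa,nearCJFraction see slot descriptions.
#' @return `SimulationParams()` returns a validated parameter object.
#' @rdname SimulationParams-class
#' @export
SimulationParams <- function(distKind = "lognormal",
                             minLen = 175, maxLen = 10000,
                             s = 1, loc = 0, scale = 1000,
                             coverage = 30,
                             readLength = 150L, insertLength = 500L,
                             seqErrorRate = 0.001, mutationRate = 0.01,
                             kappa = 2, nearCJFraction = 0) {
    new("SimulationParams", distKind = distKind,
        minLen = as.numeric(minLen), maxLen = as.numeric(maxLen),
        s = s, loc = loc, scale = scale, coverage = coverage,
        readLength = as.integer(readLength),
        insertLength = as.integer(insertLength),
        seqErrorRate = seqErrorRate, mutationRate = mutationRate,
        kappa = kappa, nearCJFraction = nearCJFraction)
}

setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams:", object@distKind,
        sprintf("[%g, %g] bp", object@minLen, object@maxLen))
    if (object@distKind == "lognormal")
        cat(sprintf(" (s=%g, loc=%g, scale=%g)", object@s, object@loc,
                    object@scale))
    cat(sprintf("\n  coverage x%g, read %d bp, insert %d bp\n",
                object@coverage, object@readLength, object@insertLength))
    cat(sprintf("  error %g, mutation %g (kappa=%g), near-CJ fraction %g\n",
                object@seqErrorRate, object@mutationRate, object@kappa,
                object@nearCJFraction))
})

#' Result of a multi-tool combination strategy
#'
#' @slot strategy one of `"union"`, `"rosette"`, `"intersect"`, `"double"`,
#'   `"unique"`.
#' @slot nTools number of tools combined.
#' @slot circles `GRanges` of selected cluster representatives, with a
#'   `support` metadata column.
#' @slot clusters the underlying [CircleClusters] object.
#' @export
setClass("CombinationResult",
    representation(strategy = "character", nTools = "integer",
                   circles = "GRanges", clusters = "CircleClusters"))

setValidity("CombinationResult", function(object) {
    msg <- NULL
    if (!object@strategy %in%
            c("union", "rosette", "intersect", "double", "unique"))
        msg <- c(msg, "unknown strategy")
    if (object@strategy == "rosette" && object@nTools < 3L)
        msg <- c(msg, "rosette requires at least 3 tools")
    if (object@nTools < 2L) msg <- c(msg, "need at least 2 tools")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CombinationResult", function(object) {
    cat(sprintf("CombinationResult '%s' over %d tools: %d circle(s)\n",
                object@strategy, object@nTools, length(object@circles)))
})

#' Benchmark metrics for one prediction set against simulated truth
#'
#' @slot tp,fp,fn true-positive, false-positive, false-negative counts.
#' @slot precision,recall,fScore the usual detection metrics in `[0, 1]`
#'   (reported as 0 in degenerate cases).
#' @slot offsetRatio fraction of matched truth circles recovered with both
#'   endpoints within 1 bp, relative to matches at the full threshold.
#' @slot threshold endpoint matching threshold (bp).
#' @export
setClass("BenchmarkReport",
    representation(tp = "integer", fp = "integer", fn = "integer",
                   precision = "numeric", recall = "numeric",
                   fScore = "numeric", offsetRatio = "numeric",
                   threshold = "integer"))

setValidity("BenchmarkReport", function(object) {
    msg <- NULL
    if (any(c(object@tp, object@fp, object@fn) < 0L))
        msg <- c(msg, "counts must be non-negative")
    for (r in c("precision", "recall", "fScore", "offsetRatio")) {
        v <- slot(object, r)
        if (length(v) && !is.na(v) && (v < 0 || v > 1))
            msg <- c(msg, paste(r, "must be in [0, 1]"))
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "BenchmarkReport", function(object) {
    cat(sprintf(paste0("BenchmarkReport (threshold %d bp): TP=%d FP=%d ",
                       "FN=%d\n  precision=%.4f recall=%.4f F=%.4f ",
                       "offsetRatio=%.4f\n"),
                object@threshold, object@tp, object@fp, object@fn,
                object@precision, object@recall, object@fScore,
                object@offsetRatio))
})

#' In-memory alignment source
#'
#' A deterministic test and simulation double for the alignment contract used
#' by [deltaCJ()]: read placements are held as a table of
#' (chrom, start, end, name, mapq) rows and window queries return the
#' overlapping rows. A split read wrapping the circular junction is
#' represented by two rows sharing one read name; per-window read
#' de-duplication downstream handles the shared identifier.
#'
#' @slot reads a `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `mapq` (1-based inclusive coordinates).
#' @export
setClass("FixtureAlignments", representation(reads = "data.frame"))

setValidity("FixtureAlignments", function(object) {
    need <- c("chrom", "start", "end", "name", "mapq")
    if (!all(need %in% names(object@reads)))
        return(paste("reads must have columns",
                     paste(need, collapse = ", ")))
    if (nrow(object@reads) && any(object@reads$end < object@reads$start))
        return("read end before start")
    if (nrow(object@reads) && any(object@reads$mapq < 0))
        return("negative MAPQ")
    TRUE
})

#' @param reads a `data.frame` of read placements; see slots.
#' @return `FixtureAlignments()` returns a validated source.
#' @rdname FixtureAlignments-class
#' @export
FixtureAlignments <- function(reads = data.frame(chrom = character(),
                                                 start = integer(),
                                                 end = integer(),
                                                 name = character(),
                                                 mapq = numeric())) {
    new("FixtureAlignments", reads = reads)
}

setMethod("show", "FixtureAlignments", function(object) {
    cat("FixtureAlignments with", nrow(object@reads), "read placement(s) on",
        length(unique(object@reads$chrom)), "sequence(s)\n")
})

#' BAM-backed alignment source
#'
#' Adapter implementing the [junctionReads()] contract over a
#' coordinate-sorted, indexed BAM file via Rsamtools/GenomicAlignments.
#'
#' @slot path path to the BAM file (index alongside).
#' @export
setClass("BamAlignments", representation(path = "character"))

#' @param path path to an indexed BAM file.
#' @return `BamAlignments()` returns the adapter object.
#' @rdname BamAlignments-class
#' @export
BamAlignments <- function(path) {
    if (!file.exists(path)) stop("BAM file not found: ", path)
    new("BamAlignments", path = path)
}

#' In-memory mappability track
#'
#' Per-chromosome per-base values in `[0, 1]`; positions beyond a vector's
#' length have no data and yield `NA` from [trackMean()].
#'
#' @slot values named list of numeric vectors, one per chromosome; value `i`
#'   is the mappability of base `i` (1-based).
#' @export
setClass("MappabilityFixture", representation(values = "list"))

setValidity("MappabilityFixture", function(object) {
    v <- unlist(object@values, use.names = FALSE)
    if (length(v) && (min(v, na.rm = TRUE) < 0 || max(v, na.rm = TRUE) > 1))
        return("mappability values must lie in [0, 1]")
    TRUE
})

#' @param values named list of per-base numeric vectors.
#' @return `MappabilityFixture()` returns a validated track.
#' @rdname MappabilityFixture-class
#' @export
MappabilityFixture <- function(values = list()) {
    new("MappabilityFixture", values = values)
}

#' bigWig-backed mappability track
#'
#' Adapter implementing the [trackMean()] contract over a bigWig file (for
#' example a UCSC 50-mer mappability multi-track) via rtracklayer.
#'
#' @slot path path to the bigWig file.
#' @export
setClass("BigWigMappability", representation(path = "character"))

#' @param path path to a bigWig file.
#' @return `BigWigMappability()` returns the adapter object.
#' @rdname BigWigMappability-class
#' @export
BigWigMappability <- function(path) {
    if (!file.exists(path)) stop("bigWig file not found: ", path)
    new("BigWigMappability", path = path)
}
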