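#' @describeIn FixtureAlignments-class reads overlapping a window.
#' @param x the source object.
#' @param chrom,start,end window, 1-based inclusive.
#' @export
setMethod("junctionReads", "FixtureAlignments",
    function(x, chrom, start, end) {
        r <- x@reads
        hit <- r$chrom == chrom & r$start <= end & r$end >= start
        r[hit, c("name", "mapq", "start", "end"), drop = FALSE]
    })

#' @describeIn BamAlignments-class reads overlapping a window, extents from
#'   the CIGAR-aware alignment.
#' @param x the source object.
#' @param chrom,start,end window, 1-based inclusive.
#' @export
setMethod("junctionReads", "BamAlignments",
    function(x, chrom, start, end) {
        which <- GenomicRanges::GRanges(chrom,
                                        IRanges::IRanges(start, end))
        param <- Rsamtools::ScanBamParam(which = which, what = "mapq")
        aln <- GenomicAlignments::readGAlignments(x@path, param = param,
                                                  use.names = TRUE)
        data.frame(name = names(aln),
                   mapq = S4Vectors::mcols(aln)$mapq,
                   start = BiocGenerics::start(aln),
                   end = BiocGenerics::end(aln),
                   stringsAsFactors = FALSE)
    })

#' @describeIn MappabilityFixture-class mean per-base value over the
#'   clipped interval; `NA` when the track has no data there.
#' @param x the track object.
#' @param chrom,start,end interval, 1-based inclusive.
#' @export
setMethod("trackMean", "MappabilityFixture",
    function(x, chrom, start, end) {
        v <- x@values[[chrom]]
        if (is.null(v)) return(NA_real_)
        start <- max(1L, start); end <- min(length(v), end)
        if (start > end) return(NA_real_)
        vals <- v[start:end]
        if (all(is.na(vals))) return(NA_real_)
        mean(vals, na.rm = TRUE)
    })

#' @describeIn BigWigMappability-class coverage-weighted mean bigWig signal
#'   over the interval; `NA` where the file has no data.
#' @param x the track object.
#' @param chrom,start,end interval, 1-based inclusive.
#' @export
setMethod("trackMean", "BigWigMappability",
    function(x, chrom, start, end) {
        win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
        gr <- tryCatch(rtracklayer::import(x@path, which = win,
                                           format = "BigWig"),
                       error = function(e) NULL)
        if (is.null(gr) || length(gr) == 0L) return(NA_real_)
        gr <- IRanges::restrict(gr, start = start, end = end)
        w <- GenomicRanges::width(gr)
        if (sum(w) == 0L) return(NA_real_)
        sum(gr$score * w) / sum(w)
    })
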