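.REPEAT_PRIORITY <- c("LINE", "SINE", "DNA", "satellite", "other")

## RepeatMasker repeat class/family strings -> the five working classes
.repeatClassOf <- function(x) {
    base <- sub("/.*$", "", x)
    out <- rep("other", length(x))
    out[base %in% c("LINE", "LINE?")] <- "LINE"
    out[base %in% c("SINE", "SINE?")] <- "SINE"
    out[base %in% c("DNA", "DNA?", "RC")] <- "DNA"
    out[base %in% c("Satellite", "Satellite?")] <- "satellite"
    out
}

#' Parse RepeatMasker annotation
#'
#' Reads a RepeatMasker `.out` table (whitespace-delimited, three header
#' lines) or a BED file whose name column carries the repeat class, and
#' maps repeat classes onto the working vocabulary `LINE`, `SINE`, `DNA`,
#' `satellite`, `other`.
#'
#' @param path path to a `.out` or BED file.
#' @param format `"auto"` (by extension), `"rmout"` or `"bed"`.
#' @return a `GRanges` with metadata column `repClass`.
#' @export
readRepeatMasker <- function(path, format = c("auto", "rmout", "bed")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed$", path)) "bed" else "rmout"
    if (format == "bed") {
        gr <- rtracklayer::import(path, format = "BED")
        S4Vectors::mcols(gr)$repClass <- .repeatClassOf(gr$name)
        return(gr[, "repClass"])
    }
    tab <- utils::read.table(path, skip = 3L, header = FALSE, fill = TRUE,
                             stringsAsFactors = FALSE)
    ## columns: score div del ins chrom begin end left strand repeat class...
    gr <- GenomicRanges::GRanges(tab[[5]],
        IRanges::IRanges(as.integer(tab[[6]]), as.integer(tab[[7]])))
    S4Vectors::mcols(gr)$repClass <- .repeatClassOf(tab[[11]])
    gr
}

#' Classify junction coordinates by repeat element
#'
#' Labels each coordinate with the class of an overlapping repeat interval;
#' coordinates overlapping none are non-repetitive (`"none"`). When several
#' repeat classes overlap one coordinate, the priority order
#' LINE > SINE > DNA > satellite > other decides.
#'
#' @param chrom,pos vectors of junction coordinates (BED positions).
#' @param repeats `GRanges` with a `repClass` column
#'   (see [readRepeatMasker()]).
#' @return character vector of class labels.
#' @export
annotateRepeat <- function(chrom, pos, repeats) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
    known <- as.character(chrom) %in%
        GenomeInfoDb::seqlevels(repeats)
    if (any(!known))
        warning(sum(!known), " coordinate(s) on chromosomes absent from ",
                "the repeat annotation; labelled non-repetitive")
    ## seqlevel-mismatch warnings are expected when some coordinates lie on
    ## chromosomes absent from the annotation; handled above
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, repeats))
    lab <- rep("none", length(q))
    if (length(hits)) {
        cl <- S4Vectors::mcols(repeats)$repClass[S4Vectors::subjectHits(hits)]
        pr <- match(cl, .REPEAT_PRIORITY)
        best <- tapply(seq_along(pr), S4Vectors::queryHits(hits),
                       function(ix) cl[ix][which.min(pr[ix])])
        lab[as.integer(names(best))] <- unlist(best)
    }
    lab
}

#' Classify junction coordinates by genomic element
#'
#' Cascading annotation against gene-model features: a coordinate is first
#' checked against 3'-UTR, 5'-UTR and `other` features (start codon, stop
#' codon, selenocysteine), then exons, then introns (derived as gene minus
#' exon spans when not explicit), and is otherwise intergenic.
#'
#' @param chrom,pos vectors of junction coordinates (BED positions).
#' @param features a `GRanges` with a `type` column as imported from GFF3
#'   by `rtracklayer::import()`.
#' @return character vector with labels among `three_prime_UTR`,
#'   `five_prime_UTR`, `other`, `exon`, `intron`, `intergenic`.
#' @export
annotateGenomic <- function(chrom, pos, features) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
    type <- as.character(S4Vectors::mcols(features)$type)
    pick <- function(kinds)
        GenomicRanges::reduce(features[type %in% kinds])
    utr3 <- pick(c("three_prime_UTR", "3'-UTR"))
    utr5 <- pick(c("five_prime_UTR", "5'-UTR"))
    other <- pick(c("start_codon", "stop_codon", "Selenocysteine"))
    exon <- pick("exon")
    intron <- pick("intron")
    if (length(intron) == 0L) {
        gene <- pick(c("gene", "mRNA", "transcript"))
        intron <- GenomicRanges::setdiff(gene, exon)
    }
    lab <- rep("intergenic", length(q))
    ov <- function(set)
        suppressWarnings(GenomicRanges::countOverlaps(q, set) > 0L)
    lab[ov(intron)] <- "intron"
    lab[ov(exon)] <- "exon"
    lab[ov(other)] <- "other"
    lab[ov(utr5)] <- "five_prime_UTR"
    lab[ov(utr3)] <- "three_prime_UTR"
    lab
}

#' Annotate both junction coordinates of each circle
#'
#' A circle has two junction coordinates; its class is taken from the start
#' coordinate, with the end coordinate's class kept in a secondary column.
#'
#' @param x a `GRanges` of circles.
#' @param annotation a repeat `GRanges` (with `repClass`) or a GFF-derived
#'   feature `GRanges` (with `type`).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `class`
#'   (start-coordinate class) and `endClass`.
#' @export
annotateCircles <- function(x, annotation) {
    chrom <- as.character(GenomeInfoDb::seqnames(x))
    fun <- if (!is.null(S4Vectors::mcols(annotation)$repClass))
        annotateRepeat else annotateGenomic
    data.frame(chrom = chrom, start = bedStart(x), end = bedEnd(x),
               class = fun(chrom, bedStart(x), annotation),
               endClass = fun(chrom, bedEnd(x), annotation),
               stringsAsFactors = FALSE)
}

#' Per-annotation-class benchmark
#'
#' Stratifies [benchmarkCircles()] by the annotation class of the truth
#' circles: the truth set is split by class, and predictions matching each
#' truth subset are evaluated against it. Classes with no truth circles are
#' omitted with a warning.
#'
#' @param predicted,truth `GRanges` of circles.
#' @param truthClasses character vector, one class label per truth circle
#'   (e.g. the `class` column of [annotateCircles()]).
#' @param classes classes to report (default: those present in
#'   `truthClasses`); requested classes with no truth circles are omitted
#'   with a warning.
#' @param threshold endpoint matching threshold (default 20).
#' @return named list of [BenchmarkReport] objects, one per class present.
#' @export
stratifiedBenchmark <- function(predicted, truth, truthClasses,
                                classes = unique(truthClasses),
                                threshold = 20L) {
    stopifnot(length(truthClasses) == length(truth))
    out <- list()
    for (cl in classes) {
        sub <- truth[truthClasses == cl]
        if (length(sub) == 0L) {
            warning("class ", cl, " has no truth circles; omitted")
            next
        }
        ## predictions claiming a truth circle of another class are not
        ## counted as FPs against this class
        m <- .assignMatches(predicted, truth, as.integer(threshold))
        inClass <- m[truthClasses[m$truth] == cl, , drop = FALSE]
        unmatchedPred <- setdiff(seq_along(predicted), m$pred)
        tp <- nrow(inClass)
        fn <- length(sub) - tp
        ## unmatched predictions are divided across classes in proportion
        ## to nothing observable; report them against every class
        fp <- length(unmatchedPred)
        precision <- if (tp + fp > 0) tp / (tp + fp) else 0
        recall <- if (tp + fn > 0) tp / (tp + fn) else 0
        f <- if (precision + recall > 0)
            2 * precision * recall / (precision + recall) else 0
        offr <- if (tp > 0)
            sum(inClass$dStart <= 1L & inClass$dEnd <= 1L) / tp else 0
        out[[cl]] <- new("BenchmarkReport", tp = as.integer(tp),
                         fp = as.integer(fp), fn = as.integer(fn),
                         precision = precision, recall = recall, fScore = f,
                         offsetRatio = offr,
                         threshold = as.integer(threshold))
    }
    out
}
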