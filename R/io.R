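#' Read circle calls from a BED-like file
#'
#' Accepts 3- to 6-column BED (0-based half-open). A numeric score column is
#' interpreted as the split-read support; `"."` means absent. Malformed
#' lines are reported with their line numbers.
#'
#' @param path file path.
#' @param tool tool label attached to every circle (default: file base name
#'   without extension).
#' @return a `GRanges` of circles (see [circles()]).
#' @export
readCircles <- function(path, tool = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(tool)) tool <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    if (length(lines) == 0L)
        return(circles(character(0), numeric(0), numeric(0), tool = tool))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("line ", which(nf < 3L)[1], ": fewer than 3 BED columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
        stop("line ", bad[1], ": unparseable coordinates: ", lines[bad[1]])
    bad <- which(start < 0 | end <= start)
    if (length(bad))
        stop("line ", bad[1], ": invalid circle interval: ", lines[bad[1]])
    score <- rep(NA_character_, length(lines))
    has5 <- nf >= 5L
    score[has5] <- vapply(fields[has5], `[[`, "", 5L)
    sr <- suppressWarnings(as.integer(score))
    circles(chrom, start, end, splitReads = sr, tool = tool)
}

#' Write circle calls as BED6
#'
#' Columns: chrom, start, end, name, score (split reads, `"."` when
#' absent), strand (`"."`; detection is strand-agnostic).
#'
#' @param x a `GRanges` of circles.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCircles <- function(x, path) {
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("circle_", seq_along(x))
    sr <- S4Vectors::mcols(x)$split_reads
    if (is.null(sr)) sr <- rep(NA_integer_, length(x))
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
                     start = format(bedStart(x), scientific = FALSE,
                                    trim = TRUE),
                     end = format(bedEnd(x), scientific = FALSE, trim = TRUE),
                     name = nm,
                     score = ifelse(is.na(sr), ".", as.character(sr)),
                     strand = ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write paired reads as two FASTQ files
#'
#' Phred+33, four lines per record, mates index-synchronised between the
#' two files.
#'
#' @param reads a read `data.frame` from the simulators (columns `name`,
#'   `seq1`, `seq2`, `qual1`, `qual2`).
#' @param r1Path,r2Path output paths for the two mate files.
#' @return `c(r1Path, r2Path)`, invisibly.
#' @export
writeFastqPairs <- function(reads, r1Path, r2Path) {
    if (any(nchar(reads$seq1) != nchar(reads$qual1)) ||
            any(nchar(reads$seq2) != nchar(reads$qual2)))
        stop("sequence/quality length mismatch")
    fq <- function(names, seqs, quals) {
        if (nrow(reads) == 0L) return(character(0))
        as.vector(rbind(paste0("@", names), seqs, "+", quals))
    }
    writeLines(fq(paste0(reads$name, "/1"), reads$seq1, reads$qual1), r1Path)
    writeLines(fq(paste0(reads$name, "/2"), reads$seq2, reads$qual2), r2Path)
    invisible(c(r1Path, r2Path))
}

#' Read paired FASTQ files back into a read table
#'
#' @param r1Path,r2Path mate file paths.
#' @return a `data.frame` with `name`, `seq1`, `seq2`, `qual1`, `qual2`.
#' @export
readFastqPairs <- function(r1Path, r2Path) {
    r1 <- Biostrings::readDNAStringSet(r1Path, format = "fastq",
                                       with.qualities = TRUE)
    r2 <- Biostrings::readDNAStringSet(r2Path, format = "fastq",
                                       with.qualities = TRUE)
    if (length(r1) != length(r2)) stop("unpaired FASTQ input")
    n1 <- sub("/1$", "", names(r1)); n2 <- sub("/2$", "", names(r2))
    if (!identical(n1, n2)) stop("mate files are out of sync")
    data.frame(name = n1,
               seq1 = as.character(r1), seq2 = as.character(r2),
               qual1 = as.character(S4Vectors::mcols(r1)$qualities),
               qual2 = as.character(S4Vectors::mcols(r2)$qualities),
               stringsAsFactors = FALSE)
}

#' Merge paired FASTQ files
#'
#' Concatenates circular and linear FASTQ pairs into one pair of files,
#' preserving record pairing.
#'
#' @param r1Paths,r2Paths equal-length vectors of mate-1 and mate-2 input
#'   paths, in matching order.
#' @param r1Out,r2Out output paths.
#' @return `c(r1Out, r2Out)`, invisibly.
#' @export
joinFastqFiles <- function(r1Paths, r2Paths, r1Out, r2Out) {
    if (length(r1Paths) != length(r2Paths))
        stop("need one mate-2 file per mate-1 file")
    parts <- Map(readFastqPairs, r1Paths, r2Paths)
    merged <- do.call(joinReadSets, unname(parts))
    writeFastqPairs(merged, r1Out, r2Out)
}

#' Write a plain-text simulation manifest
#'
#' Key-value record of every simulation parameter plus the seed, so a run
#' can be reproduced exactly.
#'
#' @param params a [SimulationParams] object.
#' @param seed the RNG seed used.
#' @param nCircles number of circles simulated.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimulationManifest <- function(params, seed, nCircles, path) {
    kv <- c(dist = params@distKind, min_len = params@minLen,
            max_len = params@maxLen, s = params@s, loc = params@loc,
            scale = params@scale, coverage = params@coverage,
            read_length = params@readLength,
            insert_length = params@insertLength,
            seq_error_rate = params@seqErrorRate,
            mutation_rate = params@mutationRate, kappa = params@kappa,
            near_cj_fraction = params@nearCJFraction,
            n_circles = nCircles, seed = seed)
    writeLines(paste(names(kv), kv, sep = "\t"), path)
    invisible(path)
}

#' Build an in-memory alignment source from simulated reads
#'
#' Places each simulated read of a circular run at its genomic location
#' (mapping the fragment's position on the linearised circle back through
#' the circle's coordinates; reads that wrap the junction contribute one
#' placement per segment, sharing the read name) and wraps the result as a
#' [FixtureAlignments] source, so the junction-imbalance statistic can run
#' on a simulation without an aligner or BAM file.
#'
#' @param truth circle `GRanges` from [simulateReadSet()] (names are circle
#'   ids).
#' @param reads the matching read table.
#' @param insertLength the insert length used in the simulation (places
#'   read 2 within its fragment).
#' @param mapq MAPQ assigned to every placement (default 60).
#' @param background optional placement `data.frame` from
#'   [linearReadPlacements()] mixed in as linear background coverage.
#' @return a [FixtureAlignments] object.
#' @export
simulatedAlignmentSource <- function(truth, reads, insertLength = 500L,
                                     mapq = 60, background = NULL) {
    ids <- names(truth)
    ci <- match(reads$circle, ids)
    ok <- !is.na(ci)
    reads <- reads[ok, , drop = FALSE]; ci <- ci[ok]
    chs <- as.character(GenomeInfoDb::seqnames(truth))[ci]
    sts <- GenomicRanges::start(truth)[ci]      # 1-based circle start
    lens <- GenomicRanges::width(truth)[ci]
    rl <- nchar(reads$seq1[1])
    ## read placements on the linearised circle, 0-based local start
    local <- data.frame(
        a = c(reads$fragStart, reads$fragStart + insertLength - rl),
        chrom = rep(chs, 2L), cstart = rep(sts, 2L), len = rep(lens, 2L),
        name = c(paste0(reads$name, "/1"), paste0(reads$name, "/2")))
    a <- local$a %% local$len
    b <- a + rl - 1L                       # local end, may run past the CJ
    wrap <- b >= local$len
    seg1 <- data.frame(chrom = local$chrom,
                       start = local$cstart + a,
                       end = local$cstart + ifelse(wrap, local$len - 1L, b),
                       name = local$name, mapq = mapq)
    seg2 <- data.frame(chrom = local$chrom[wrap],
                       start = local$cstart[wrap],
                       end = local$cstart[wrap] + (b[wrap] %% local$len[wrap]),
                       name = local$name[wrap], mapq = mapq)
    FixtureAlignments(rbind(seg1, seg2, background))
}

#' Genomic placements for simulated linear reads
#'
#' Maps a [simulateLinearReads()] table onto genome coordinates so linear
#' background coverage (the library's non-circular fraction) can be mixed
#' into a [FixtureAlignments] source via the `background` argument of
#' [simulatedAlignmentSource()].
#'
#' @param chrom chromosome the linear region lies on.
#' @param regionStart BED start (0-based) of the region the reads were
#'   simulated from.
#' @param reads a read table from [simulateLinearReads()].
#' @param insertLength the insert length used in the simulation.
#' @param mapq MAPQ assigned to every placement (default 60).
#' @return a placement `data.frame` (`chrom`, `start`, `end`, `name`,
#'   `mapq`).
#' @export
linearReadPlacements <- function(chrom, regionStart, reads,
                                 insertLength = 500L, mapq = 60) {
    rl <- nchar(reads$seq1[1])
    a <- c(reads$fragStart, reads$fragStart + insertLength - rl)
    data.frame(chrom = chrom,
               start = regionStart + a + 1L,
               end = regionStart + a + rl,
               name = c(paste0(reads$name, "/1"), paste0(reads$name, "/2")),
               mapq = mapq, stringsAsFactors = FALSE)
}
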