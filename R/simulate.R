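.BASES <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Read pairs needed for a requested coverage
#'
#' Inverts the simulator's coverage definition
#' `coverage = n_pairs * read_length * 2 / circle_length` and takes the
#' ceiling, so the realized coverage is never below the request and every
#' circle receives at least one pair.
#'
#' @param coverage requested fold-coverage (> 0).
#' @param circleLength template length in bp.
#' @param readLength read length in bp.
#' @return integer number of read pairs.
#' @examples
#' readsForCoverage(30, 3000, 150)   # 300
#' readsForCoverage(5, 175, 150)     # 3
#' @export
readsForCoverage <- function(coverage, circleLength, readLength) {
    if (coverage <= 0 || circleLength <= 0 || readLength <= 0)
        stop("all arguments must be positive")
    as.integer(ceiling(coverage * circleLength / (2 * readLength)))
}

## per-base substitution on a character matrix/vector of bases
.substituteBases <- function(bases, rate, chooser) {
    if (rate <= 0) return(bases)
    eligible <- bases %in% .BASES
    hit <- eligible & stats::runif(length(bases)) < rate
    if (any(hit)) bases[hit] <- chooser(bases[hit])
    bases
}

#' Mutate a sequence under the Kimura two-parameter model
#'
#' Each base is independently mutated with probability `rate`; a mutation is
#' a transition (A<->G, C<->T) with probability `kappa / (kappa + 2)` and
#' each of the two transversions with probability `1 / (kappa + 2)`. `N`
#' bases are never mutated and length is preserved.
#'
#' @param seq a single nucleotide string over `{A,C,G,T,N}`.
#' @param rate per-base mutation probability.
#' @param kappa transition/transversion rate ratio (default 2).
#' @param seed optional RNG seed.
#' @return the mutated string.
#' @export
mutateSequence <- function(seq, rate, kappa = 2, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
    bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    bases <- .substituteBases(bases, rate, function(b) .kimuraChoice(b, kappa))
    paste(bases, collapse = "")
}

.kimuraChoice <- function(b, kappa) {
    ## transition with prob kappa/(kappa+2), else one of the 2 transversions
    ti <- stats::runif(length(b)) < kappa / (kappa + 2)
    out <- character(length(b))
    out[ti] <- .TRANSITION[b[ti]]
    if (any(!ti)) {
        tv <- b[!ti]
        purine <- tv %in% c("A", "G")
        pick <- ifelse(stats::runif(length(tv)) < 0.5, 1L, 2L)
        out[!ti] <- ifelse(purine, c("C", "T")[pick], c("A", "G")[pick])
    }
    out
}

#' Apply uniform sequencing errors to a sequence
#'
#' Each base is replaced with probability `rate` by one of the three other
#' bases, uniformly. Length is preserved; `N` bases are untouched.
#'
#' @param seq a single nucleotide string.
#' @param rate per-base error probability.
#' @param seed optional RNG seed.
#' @return the string with errors applied.
#' @export
applySequencingError <- function(seq, rate, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
    bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    bases <- .substituteBases(bases, rate, .uniformError)
    paste(bases, collapse = "")
}

.uniformError <- function(b) {
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3)
    alt[cbind(sample.int(3L, length(b), replace = TRUE), match(b, .BASES))]
}

#' Sample circle coordinates on a genome
#'
#' Draws `n` circles: the chromosome is chosen with probability proportional
#' to its length, the circle length from the configured distribution
#' (uniform, or the three-parameter lognormal `loc + scale * exp(s * Z)`)
#' by rejection until it lies within `[minLen, maxLen]` and fits the
#' chromosome, and the start uniformly among positions where the circle
#' fits.
#'
#' @param genome named vector of chromosome lengths, or a named
#'   `DNAStringSet`/character vector of sequences.
#' @param n number of circles.
#' @param params a [SimulationParams] object.
#' @param seed optional RNG seed.
#' @return a `GRanges` of circles named `circle_1 ... circle_n`.
#' @export
sampleCircleCoords <- function(genome, n, params = SimulationParams(),
                               seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    lens <- .genomeLengths(genome)
    if (max(lens) < params@minLen)
        stop("no chromosome can host a circle of minimum length ",
             params@minLen)
    if (n == 0L)
        return(circles(character(0), numeric(0), numeric(0)))
    chrom <- character(n); st <- numeric(n); len <- numeric(n)
    for (i in seq_len(n)) {
        repeat {
            ch <- sample(names(lens), 1L, prob = lens)
            l <- .drawLength(params)
            if (!is.na(l) && l <= lens[[ch]]) break
        }
        chrom[i] <- ch; len[i] <- l
        st[i] <- sample.int(lens[[ch]] - l + 1L, 1L) - 1L
    }
    gr <- circles(chrom, st, st + len)
    names(gr) <- paste0("circle_", seq_len(n))
    gr
}

.genomeLengths <- function(genome) {
    if (methods::is(genome, "DNAStringSet")) {
        lens <- Biostrings::width(genome)
        names(lens) <- names(genome)
    } else if (is.character(genome)) {
        lens <- nchar(genome)
    } else {
        lens <- genome
    }
    if (is.null(names(lens)) || any(!nzchar(names(lens))))
        stop("genome sequences must be named")
    lens
}

## one length draw; NA when outside the truncation bounds (caller rejects)
.drawLength <- function(params) {
    l <- if (params@distKind == "uniform") {
        params@minLen + floor(stats::runif(1) *
                                  (params@maxLen - params@minLen + 1))
    } else {
        round(params@loc + params@scale * exp(params@s * stats::rnorm(1)))
    }
    if (l < params@minLen || l > params@maxLen) NA_real_ else l
}

#' Simulate paired-end reads from a circular template
#'
#' Fragments of `insertLength` bases start uniformly on the circularized
#' template (positions wrap across the junction); a `nearCJFraction` of
#' fragments is instead forced to start within one insert length upstream of
#' the junction. Read 1 is the first `readLength` bases of the fragment and
#' read 2 the reverse complement of its last `readLength` bases. The circle
#' sequence is first mutated once under the Kimura model (the biological
#' divergence of the simulated molecule), and sequencing errors are applied
#' to each read. Each pair is classified by its relation to the circular
#' junction: `split` when either read itself crosses the junction,
#' `discordant` when only the fragment spans it (the junction falls between
#' the mates), `concordant` otherwise.
#'
#' @param circleSeq the circle's nucleotide sequence (single string).
#' @param circleId identifier used in read names
#'   (`circleId|pairIndex|class`).
#' @param params a [SimulationParams] object.
#' @param seed optional RNG seed.
#' @param nPairs optional pair count override; default derives from
#'   `params@coverage` via [readsForCoverage()].
#' @return a `data.frame` with columns `name`, `seq1`, `seq2`, `qual1`,
#'   `qual2`, `class`, `fragStart` (0-based start on the linearised circle)
#'   and `circle`.
#' @export
simulateCircleReads <- function(circleSeq, circleId = "circle",
                                params = SimulationParams(), seed = NULL,
                                nPairs = NULL) {
    if (!is.null(seed)) set.seed(seed)
    len <- nchar(circleSeq)
    rl <- params@readLength; ins <- params@insertLength
    if (len < rl) stop("circle shorter than the read length")
    if (is.null(nPairs))
        nPairs <- readsForCoverage(params@coverage, len, rl)
    template <- mutateSequence(circleSeq, params@mutationRate, params@kappa)
    ## unroll the circle far enough to cover any fragment
    unrolled <- strrep(template, ceiling((len + ins) / len) + 1L)
    s <- sample.int(len, nPairs, replace = TRUE) - 1L
    if (params@nearCJFraction > 0) {
        forced <- stats::runif(nPairs) < params@nearCJFraction
        w <- min(ins, len)
        s[forced] <- len - w + sample.int(w, sum(forced), replace = TRUE) - 1L
    }
    seq1 <- substring(unrolled, s + 1L, s + rl)
    seq2 <- .revcomp(substring(unrolled, s + ins - rl + 1L, s + ins))
    cls <- .classifyPair(s, len, rl, ins)
    seq1 <- .errorReads(seq1, params@seqErrorRate)
    seq2 <- .errorReads(seq2, params@seqErrorRate)
    q <- strrep("I", rl)
    data.frame(name = sprintf("%s|%d|%s", circleId, seq_len(nPairs), cls),
               seq1 = seq1, seq2 = seq2, qual1 = q, qual2 = q,
               class = cls, fragStart = s, circle = circleId,
               stringsAsFactors = FALSE)
}

## does interval [a, b) on the unrolled template cross a junction (an
## interior multiple of len)?
.crosses <- function(a, b, len) ((b - 1L) %/% len) > (a %/% len)

.classifyPair <- function(s, len, rl, ins) {
    r1 <- .crosses(s, s + rl, len)
    r2 <- .crosses(s + ins - rl, s + ins, len)
    frag <- .crosses(s, s + ins, len)
    ifelse(r1 | r2, "split", ifelse(frag, "discordant", "concordant"))
}

.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## vectorised sequencing error over equal-length reads
.errorReads <- function(reads, rate) {
    if (rate <= 0 || length(reads) == 0L) return(reads)
    rl <- nchar(reads[1])
    bases <- unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE)
    bases <- .substituteBases(bases, rate, .uniformError)
    m <- matrix(bases, nrow = rl)
    apply(m, 2, paste, collapse = "")
}

#' Simulate paired-end reads from a linear template
#'
#' Fragment starts are uniform on `[0, L - insertLength]` so every pair is
#' concordant with the linear reference; used to mix background reads into
#' a circular simulation.
#'
#' @param regionSeq the region's nucleotide sequence (single string).
#' @param regionId identifier used in read names.
#' @param params a [SimulationParams] object.
#' @param seed optional RNG seed.
#' @param nPairs optional pair count override.
#' @return a `data.frame` as [simulateCircleReads()], `class` `"linear"`.
#' @export
simulateLinearReads <- function(regionSeq, regionId = "linear",
                                params = SimulationParams(), seed = NULL,
                                nPairs = NULL) {
    if (!is.null(seed)) set.seed(seed)
    len <- nchar(regionSeq)
    rl <- params@readLength; ins <- params@insertLength
    if (len < ins) stop("region shorter than the insert length")
    if (is.null(nPairs))
        nPairs <- readsForCoverage(params@coverage, len, rl)
    template <- mutateSequence(regionSeq, params@mutationRate, params@kappa)
    s <- sample.int(len - ins + 1L, nPairs, replace = TRUE) - 1L
    seq1 <- .errorReads(substring(template, s + 1L, s + rl),
                        params@seqErrorRate)
    seq2 <- .errorReads(.revcomp(substring(template, s + ins - rl + 1L,
                                           s + ins)),
                        params@seqErrorRate)
    q <- strrep("I", rl)
    data.frame(name = sprintf("%s|%d|linear", regionId, seq_len(nPairs)),
               seq1 = seq1, seq2 = seq2, qual1 = q, qual2 = q,
               class = "linear", fragStart = s, circle = NA_character_,
               stringsAsFactors = FALSE)
}

#' Simulate a full circular read set with ground truth
#'
#' Samples `nCircles` circle coordinates on the genome, extracts their
#' sequences, and simulates reads for each circle at the configured
#' coverage. The returned truth set and read table are the inputs to the
#' benchmarking and junction-imbalance modules; [writeFastqPairs()],
#' [writeCircles()] and [writeSimulationManifest()] persist them.
#'
#' @param genome a named `DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @param nCircles number of circles to simulate.
#' @param params a [SimulationParams] object.
#' @param seed optional RNG seed governing the whole run.
#' @return list with `truth` (a circle `GRanges` named by circle id) and
#'   `reads` (row-bound [simulateCircleReads()] tables).
#' @export
simulateReadSet <- function(genome, nCircles, params = SimulationParams(),
                            seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    seqs <- .genomeSequences(genome)
    truth <- sampleCircleCoords(genome, nCircles, params)
    reads <- lapply(seq_len(length(truth)), function(i) {
        ch <- as.character(GenomeInfoDb::seqnames(truth[i]))
        cseq <- substring(seqs[[ch]], GenomicRanges::start(truth[i]),
                          GenomicRanges::end(truth[i]))
        simulateCircleReads(cseq, names(truth)[i], params)
    })
    list(truth = truth, reads = do.call(rbind, reads))
}

.genomeSequences <- function(genome) {
    if (methods::is(genome, "DNAStringSet")) {
        out <- as.character(genome)
        names(out) <- names(genome)
        out
    } else if (is.character(genome)) {
        genome
    } else {
        stop("need sequences, not lengths, to simulate reads")
    }
}

#' Merge circular and linear read sets
#'
#' Row-binds read tables (e.g. circular plus linear background) while
#' checking that every record is a complete, consistent pair.
#'
#' @param ... read `data.frame`s as produced by the simulators.
#' @return one combined `data.frame`.
#' @export
joinReadSets <- function(...) {
    parts <- list(...)
    need <- c("name", "seq1", "seq2", "qual1", "qual2")
    for (p in parts) {
        if (!all(need %in% names(p))) stop("not a paired read table")
        if (any(nchar(p$seq1) != nchar(p$qual1)) ||
                any(nchar(p$seq2) != nchar(p$qual2)))
            stop("sequence/quality length mismatch")
    }
    do.call(rbind, parts)
}
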