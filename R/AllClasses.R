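#' @include AllGenerics.R
NULL

#' Base-called nanopore reads with per-base phred scores
#'
#' A `NanoporeReadSet` holds base-called reads (a [Biostrings::DNAStringSet]
#' over `{A,C,G,T,N}`) together with their decoded per-base phred scores
#' (an [IRanges::IntegerList], one integer in `[0, 93]` per base) and an
#' optional per-read link to a signal trace. Names are the read ids and are
#' required to be unique.
#'
#' @param sequences A `DNAStringSet` (or something coercible) named by read id.
#' @param phred An `IntegerList` (or list of integer vectors) of per-base
#'   phred scores, parallel to `sequences`.
#' @param signalRef Optional character vector of signal-trace ids (default:
#'   the read ids themselves; `NA` where no trace exists).
#' @param x,i A `NanoporeReadSet` and an index for subsetting.
#' @return `NanoporeReadSet()` returns a validated `NanoporeReadSet`.
#' @examples
#' rs <- NanoporeReadSet(Biostrings::DNAStringSet(c(r1 = "ACGT")),
#'                       phred = list(r1 = c(30L, 30L, 12L, 2L)))
#' readLengths(rs)
#' @aliases readIDs readSequences phredScores readLengths
#' @export NanoporeReadSet
#' @exportClass NanoporeReadSet
setClass("NanoporeReadSet",
    representation(
        sequences = "DNAStringSet",
        phred = "IntegerList",
        signalRef = "character"
    )
)

setValidity("NanoporeReadSet", function(object) {
    msg <- character()
    n <- length(object@sequences)
    ids <- names(object@sequences)
    if (n > 0 && (is.null(ids) || anyNA(ids) || any(ids == "")))
        msg <- c(msg, "all reads must be named by a read id")
    else if (n > 0 && anyDuplicated(ids))
        msg <- c(msg, "read ids must be unique")
    if (length(object@phred) != n)
        msg <- c(msg, "phred must be parallel to sequences")
    else if (!all(lengths(object@phred) == Biostrings::width(object@sequences)))
        msg <- c(msg, "each read needs exactly one phred value per base")
    if (length(object@phred)) {
        v <- unlist(object@phred, use.names = FALSE)
        if (length(v) && (min(v) < 0L || max(v) > 93L))
            msg <- c(msg, "phred values must lie in [0, 93]")
    }
    if (length(object@signalRef) != n)
        msg <- c(msg, "signalRef must be parallel to sequences")
    if (length(msg)) msg else TRUE
})

NanoporeReadSet <- function(sequences, phred, signalRef = NULL) {
    if (!is(sequences, "DNAStringSet"))
        sequences <- Biostrings::DNAStringSet(sequences)
    if (!is(phred, "IntegerList"))
        phred <- IRanges::IntegerList(lapply(phred, as.integer))
    if (is.null(signalRef))
        signalRef <- if (is.null(names(sequences))) rep(NA_character_,
            length(sequences)) else names(sequences)
    obj <- new("NanoporeReadSet", sequences = sequences,
               phred = unname(phred), signalRef = unname(signalRef))
    validObject(obj)
    obj
}

#' @rdname NanoporeReadSet-class
#' @export
setMethod("readIDs", "NanoporeReadSet", function(x) names(x@sequences))

#' @rdname NanoporeReadSet-class
#' @export
setMethod("readSequences", "NanoporeReadSet", function(x) x@sequences)

#' @rdname NanoporeReadSet-class
#' @export
setMethod("phredScores", "NanoporeReadSet",
    function(x) setNames(x@phred, names(x@sequences)))

#' @rdname NanoporeReadSet-class
#' @export
setMethod("readLengths", "NanoporeReadSet",
    function(x) setNames(Biostrings::width(x@sequences), names(x@sequences)))

#' @rdname NanoporeReadSet-class
#' @export
setMethod("length", "NanoporeReadSet", function(x) length(x@sequences))

#' @rdname NanoporeReadSet-class
#' @export
setMethod("[", "NanoporeReadSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, readIDs(x))
    initialize(x, sequences = x@sequences[i], phred = x@phred[i],
               signalRef = x@signalRef[i])
})

setMethod("show", "NanoporeReadSet", function(object) {
    cat("NanoporeReadSet with", length(object), "reads\n")
    if (length(object)) {
        w <- Biostrings::width(object@sequences)
        cat(sprintf("  read length: %d-%d (median %d)\n",
                    min(w), max(w), as.integer(median(w))))
        cat(sprintf("  with signal trace: %d\n", sum(!is.na(object@signalRef))))
    }
})

#' Split alignments of nanopore reads
#'
#' `SplitAlignments` stores, for every read, the primary plus supplementary
#' alignment segments that together describe its split mapping. Segments are
#' kept as one table with columns `read_id`, `chrom`, `ref_start`, `ref_end`,
#' `read_start`, `read_end`, `strand`, `is_primary`, `cigar`. Reference and
#' read intervals are 0-based half-open; read coordinates are in as-sequenced
#' orientation (reverse-strand segments have their clipping arithmetic
#' flipped), so split boundaries are comparable along the read as it passed
#' the pore. Within each read, segments are sorted by `read_start`.
#'
#' @param segments A data.frame of segments as described above.
#' @param seqlengths Named integer vector of reference sequence lengths.
#' @param x A `SplitAlignments` object.
#' @return `SplitAlignments()` returns a validated object.
#'   `alignmentSegments(x)` returns the segment table,
#'   `referenceLengths(x)` the named seqlengths vector.
#' @aliases alignmentSegments referenceLengths
#' @export SplitAlignments
#' @exportClass SplitAlignments
setClass("SplitAlignments",
    representation(segments = "data.frame", seqlengths = "integer")
)

.SEGMENT_COLS <- c("read_id", "chrom", "ref_start", "ref_end",
                   "read_start", "read_end", "strand", "is_primary", "cigar")

setValidity("SplitAlignments", function(object) {
    seg <- object@segments
    msg <- character()
    if (!all(.SEGMENT_COLS %in% names(seg)))
        return(paste("segments must have columns:",
                     paste(.SEGMENT_COLS, collapse = ", ")))
    if (nrow(seg)) {
        if (any(seg$ref_start >= seg$ref_end))
            msg <- c(msg, "ref_start must be < ref_end")
        if (any(seg$read_start >= seg$read_end))
            msg <- c(msg, "read_start must be < read_end")
        if (!all(seg$strand %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' or '-'")
        span <- vapply(seg$cigar, cigarRefSpan, integer(1), USE.NAMES = FALSE)
        if (any(span != seg$ref_end - seg$ref_start))
            msg <- c(msg, "reference span inconsistent with CIGAR")
        rspan <- vapply(seg$cigar, cigarReadSpan, integer(1), USE.NAMES = FALSE)
        if (any(rspan != seg$read_end - seg$read_start))
            msg <- c(msg, "read span inconsistent with CIGAR")
        ord <- unlist(lapply(split(seg$read_start, seg$read_id), is.unsorted),
                      use.names = FALSE)
        if (any(ord))
            msg <- c(msg, "segments must be sorted by read_start within read")
        if (is.null(names(object@seqlengths)) &&
            length(object@seqlengths) > 0)
            msg <- c(msg, "seqlengths must be named")
    }
    if (length(msg)) msg else TRUE
})

SplitAlignments <- function(segments, seqlengths = integer()) {
    segments <- segments[order(segments$read_id, segments$read_start), ,
                         drop = FALSE]
    rownames(segments) <- NULL
    obj <- new("SplitAlignments", segments = segments,
               seqlengths = setNames(as.integer(seqlengths),
                                     names(seqlengths)))
    validObject(obj)
    obj
}

#' @rdname SplitAlignments-class
#' @export
setMethod("alignmentSegments", "SplitAlignments", function(x) x@segments)

#' @rdname SplitAlignments-class
#' @export
setMethod("referenceLengths", "SplitAlignments", function(x) x@seqlengths)

#' @rdname SplitAlignments-class
#' @export
setMethod("readIDs", "SplitAlignments",
    function(x) unique(x@segments$read_id))

#' @rdname SplitAlignments-class
#' @export
setMethod("length", "SplitAlignments",
    function(x) length(unique(x@segments$read_id)))

setMethod("show", "SplitAlignments", function(object) {
    seg <- object@segments
    cat("SplitAlignments:", length(unique(seg$read_id)), "reads,",
        nrow(seg), "segments\n")
    split_n <- sum(table(seg$read_id) > 1)
    cat("  split reads:", split_n, "\n")
})

#' Raw nanopore signal traces with a signal-to-base index
#'
#' A `SignalTraceSet` holds, per read, the raw current samples (pA) and a
#' monotone non-decreasing `base_index` giving, for each called base, the
#' 0-based sample index at which its translocation begins. The last index is
#' at most the number of samples; when paired with a read, `base_index` has
#' one entry per called base. `sampleRate` (Hz) is carried as metadata only.
#'
#' @param samples A [IRanges::NumericList] (or list) of current samples,
#'   named by read id.
#' @param baseIndex An `IntegerList` (or list) of 0-based sample start
#'   indices, parallel to `samples`.
#' @param sampleRate Numeric vector of sampling rates in Hz (recycled).
#' @param x,i A `SignalTraceSet` and an index.
#' @aliases signalSamples baseIndex sampleRate
#' @export SignalTraceSet
#' @exportClass SignalTraceSet
setClass("SignalTraceSet",
    representation(
        samples = "NumericList",
        baseIndex = "IntegerList",
        sampleRate = "numeric",
        ids = "character"
    )
)

setValidity("SignalTraceSet", function(object) {
    msg <- character()
    n <- length(object@samples)
    if (length(object@baseIndex) != n || length(object@ids) != n ||
        length(object@sampleRate) != n)
        return("samples, baseIndex, sampleRate and ids must be parallel")
    if (anyDuplicated(object@ids))
        msg <- c(msg, "trace ids must be unique")
    if (n) {
        nondec <- !vapply(object@baseIndex, is.unsorted, logical(1))
        if (!all(nondec))
            msg <- c(msg, "base_index must be non-decreasing")
        last <- vapply(object@baseIndex,
                       function(b) if (length(b)) b[length(b)] else 0L,
                       integer(1))
        if (any(last > lengths(object@samples)))
            msg <- c(msg, "base_index exceeds the number of samples")
        if (any(unlist(lapply(object@baseIndex, function(b) any(b < 0L)))))
            msg <- c(msg, "base_index entries must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

SignalTraceSet <- function(samples, baseIndex, sampleRate = 4000) {
    ids <- names(samples)
    if (is.null(ids)) stop("signal traces must be named by read id")
    if (!is(samples, "NumericList")) samples <- IRanges::NumericList(samples)
    if (!is(baseIndex, "IntegerList"))
        baseIndex <- IRanges::IntegerList(lapply(baseIndex, as.integer))
    obj <- new("SignalTraceSet", samples = unname(samples),
               baseIndex = unname(baseIndex),
               sampleRate = rep_len(as.numeric(sampleRate), length(samples)),
               ids = ids)
    validObject(obj)
    obj
}

#' @rdname SignalTraceSet-class
#' @export
setMethod("readIDs", "SignalTraceSet", function(x) x@ids)

#' @rdname SignalTraceSet-class
#' @export
setMethod("signalSamples", "SignalTraceSet",
    function(x) setNames(x@samples, x@ids))

#' @rdname SignalTraceSet-class
#' @export
setMethod("baseIndex", "SignalTraceSet",
    function(x) setNames(x@baseIndex, x@ids))

#' @rdname SignalTraceSet-class
#' @export
setMethod("sampleRate", "SignalTraceSet",
    function(x) setNames(x@sampleRate, x@ids))

#' @rdname SignalTraceSet-class
#' @export
setMethod("length", "SignalTraceSet", function(x) length(x@ids))

#' @rdname SignalTraceSet-class
#' @export
setMethod("[", "SignalTraceSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, x@ids)
    initialize(x, samples = x@samples[i], baseIndex = x@baseIndex[i],
               sampleRate = x@sampleRate[i], ids = x@ids[i])
})

setMethod("show", "SignalTraceSet", function(object) {
    cat("SignalTraceSet with", length(object), "traces\n")
    if (length(object))
        cat(sprintf("  samples per trace: %d-%d\n",
                    min(lengths(object@samples)),
                    max(lengths(object@samples))))
})

#' Sample-wide phred score statistics
#'
#' Global location/scale of the per-base phred distribution of a sample,
#' used to derive the low-phred detection threshold
#' `global_median - sd_multiplier * global_sd`.
#'
#' @param globalMedian,globalSD Median and standard deviation (phred units).
#' @param nBases,nReads Number of pooled bases and reads they came from.
#' @export PhredStats
#' @exportClass PhredStats
setClass("PhredStats",
    representation(globalMedian = "numeric", globalSD = "numeric",
                   nBases = "numeric", nReads = "integer")
)

setValidity("PhredStats", function(object) {
    msg <- character()
    if (object@globalSD < 0) msg <- c(msg, "globalSD must be >= 0")
    if (object@nBases <= 0) msg <- c(msg, "nBases must be > 0")
    if (length(msg)) msg else TRUE
})

PhredStats <- function(globalMedian, globalSD, nBases = 1, nReads = 1L) {
    obj <- new("PhredStats", globalMedian = as.numeric(globalMedian),
               globalSD = as.numeric(globalSD), nBases = as.numeric(nBases),
               nReads = as.integer(nReads))
    validObject(obj)
    obj
}

#' @rdname PhredStats-class
#' @param x A `PhredStats` object.
#' @export
globalMedian <- function(x) x@globalMedian

#' @rdname PhredStats-class
#' @export
globalSD <- function(x) x@globalSD

setMethod("show", "PhredStats", function(object) {
    cat(sprintf(
        "PhredStats: median %.2f, sd %.3f (%g bases from %d reads)\n",
        object@globalMedian, object@globalSD, object@nBases, object@nReads))
})
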