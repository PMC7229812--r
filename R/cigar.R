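# CIGAR arithmetic. All walkers are authored here because the expected-base
# computation at inverted-duplicate junctions needs read-interval-restricted
# reference spans in as-sequenced orientation, which no single upstream
# helper provides; tests cross-check full-segment spans against
# GenomicAlignments.

.CIGAR_RE <- "(\\d+)([MIDNSHP=X])"

#' Parse a CIGAR string into operation lengths and codes
#'
#' @param cigar A single CIGAR string.
#' @return A data.frame with columns `len` (integer) and `op` (character),
#'   in stored (reference-orientation) order.
#' @examples
#' parseCigar("5S10M2D3M")
#' @export
parseCigar <- function(cigar) {
    stopifnot(is.character(cigar), length(cigar) == 1L)
    m <- gregexpr(.CIGAR_RE, cigar, perl = TRUE)[[1]]
    toks <- regmatches(cigar, list(m))[[1]]
    if (!length(toks) || sum(attr(m, "match.length")) != nchar(cigar))
        stop("malformed CIGAR string: ", cigar)
    data.frame(
        len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
        op = sub("^\\d+", "", toks),
        stringsAsFactors = FALSE
    )
}

# lightweight tokenizer shared by the span helpers (no data.frame overhead;
# these run once per alignment record)
.cigarOps <- function(cigar) {
    toks <- regmatches(cigar, gregexpr(.CIGAR_RE, cigar, perl = TRUE))[[1]]
    list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
         op = sub("^\\d+", "", toks))
}

#' @rdname parseCigar
#' @return `cigarRefSpan()`: reference bases consumed (`M/=/X/D/N`).
#' @export
cigarRefSpan <- function(cigar) {
    ops <- .cigarOps(cigar)
    sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
}

#' @rdname parseCigar
#' @return `cigarReadSpan()`: aligned read bases consumed (`M/=/X/I`),
#'   excluding clips.
#' @export
cigarReadSpan <- function(cigar) {
    ops <- .cigarOps(cigar)
    sum(ops$len[ops$op %in% c("M", "=", "X", "I")])
}

# Leading/trailing clip lengths (S or H) in stored orientation.
.cigarClips <- function(cigar) {
    ops <- parseCigar(cigar)
    lead <- 0L
    trail <- 0L
    i <- 1L
    while (i <= nrow(ops) && ops$op[i] %in% c("S", "H")) {
        lead <- lead + ops$len[i]
        i <- i + 1L
    }
    i <- nrow(ops)
    while (i >= 1L && ops$op[i] %in% c("S", "H")) {
        trail <- trail + ops$len[i]
        i <- i - 1L
    }
    c(leading = lead, trailing = trail)
}

# Full read length implied by a CIGAR (clips + aligned read bases).
.cigarReadLength <- function(cigar) {
    ops <- parseCigar(cigar)
    sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S", "H")])
}

# Reference bases consumed by the part of a segment's alignment that falls
# inside the as-sequenced read interval [rs, re). A deletion (D/N) sits
# between two read positions; it is counted only when that joint is strictly
# interior to the interval, so a region ending exactly at a deletion does not
# claim reference bases the pore had not yet traversed within it.
.refSpanForReadInterval <- function(cigar, strand, seg_read_start, rs, re) {
    ops <- parseCigar(cigar)
    if (strand == "-") ops <- ops[rev(seq_len(nrow(ops))), , drop = FALSE]
    pos <- seg_read_start - .cigarClips(cigar)[
        if (strand == "-") "trailing" else "leading"]
    # pos now tracks as-sequenced read coordinate from the segment's first
    # (possibly clipped) base.
    span <- 0L
    for (k in seq_len(nrow(ops))) {
        op <- ops$op[k]
        len <- ops$len[k]
        if (op %in% c("S", "H", "I")) {
            pos <- pos + len
        } else if (op %in% c("M", "=", "X")) {
            ov <- min(pos + len, re) - max(pos, rs)
            if (ov > 0) span <- span + ov
            pos <- pos + len
        } else if (op %in% c("D", "N")) {
            if (pos > rs && pos < re) span <- span + len
        }
    }
    as.integer(span)
}
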