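#' Read base-called nanopore reads from FASTQ
#'
#' Reads a 4-line-record FASTQ file (quality encoded Phred+33) into a
#' [NanoporeReadSet]. Read ids are the header up to the first whitespace;
#' record order is preserved. A record whose quality string length differs
#' from its sequence length is a hard error naming the record.
#'
#' @param path Path to a FASTQ file.
#' @return A [NanoporeReadSet].
#' @seealso [writeNanoporeFastq()]
#' @export
readNanoporeFastq <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0)
        return(NanoporeReadSet(Biostrings::DNAStringSet(),
                               IRanges::IntegerList()))
    .validateFastqRecords(path)
    tryCatch({
        seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                             with.qualities = TRUE)
        quals <- S4Vectors::mcols(seqs)$qualities
        ids <- sub("\\s.*$", "", names(seqs))
        names(seqs) <- ids
        phred <- .asciiToPhred(quals)
        v <- unlist(phred, use.names = FALSE)
        if (length(v) && (min(v) < 0L || max(v) > 93L))
            stop("quality characters outside the Phred+33 range")
        NanoporeReadSet(seqs, phred)
    }, error = function(e) .diagnoseFastq(path, conditionMessage(e)))
}

# Record-shape validation ahead of the parser (which trusts its input): a
# record whose quality length differs from its sequence length is a hard
# error naming the record.
.validateFastqRecords <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) %% 4L != 0L)
        stop("truncated FASTQ '", path, "': line count not a multiple of 4")
    if (!length(lines)) return(invisible())
    sl <- nchar(lines[seq.int(2L, length(lines), by = 4L)], type = "bytes")
    ql <- nchar(lines[seq.int(4L, length(lines), by = 4L)], type = "bytes")
    bad <- which(sl != ql)
    if (length(bad))
        stop("FASTQ record '",
             sub("^@", "", sub("\\s.*$", "", lines[4L * bad[1] - 3L])),
             "': sequence and quality lengths differ")
    invisible()
}

.diagnoseFastq <- function(path, parent_msg) {
    stop("failed to parse FASTQ '", path, "': ", parent_msg)
}

# Phred+33 decode of a BStringSet of quality strings -> IntegerList.
.asciiToPhred <- function(quals) {
    raw <- charToRaw(paste(as.character(quals), collapse = ""))
    vals <- as.integer(raw) - 33L
    IRanges::relist(vals,
        IRanges::PartitioningByWidth(Biostrings::width(quals)))
}

.phredToAscii <- function(phred) {
    vals <- unlist(phred, use.names = FALSE)
    all_chr <- rawToChar(as.raw(vals + 33L))
    ends <- cumsum(lengths(phred))
    starts <- ends - lengths(phred) + 1L
    substring(all_chr, starts, ends)
}

#' Write a NanoporeReadSet to FASTQ
#'
#' Phred+33 encoded, 4-line records, read order preserved. Round-trips
#' losslessly through [readNanoporeFastq()].
#'
#' @param x A [NanoporeReadSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNanoporeFastq <- function(x, path) {
    stopifnot(is(x, "NanoporeReadSet"))
    ids <- readIDs(x)
    if (!length(ids)) {
        file.create(path)
        return(invisible(path))
    }
    rec <- paste0("@", ids, "\n", as.character(readSequences(x)), "\n+\n",
                  .phredToAscii(x@phred))
    writeLines(rec, path)
    invisible(path)
}

#' Read split alignments from SAM/BAM
#'
#' Loads primary and supplementary alignments grouped by read name into a
#' [SplitAlignments] object. Secondary alignments (flag 0x100) and unmapped
#' records are excluded. Reference intervals are derived from POS and the
#' CIGAR; read intervals are reported 0-based half-open in as-sequenced
#' orientation: for a forward segment the interval starts at the leading
#' clip length, for a reverse segment at the trailing clip length, so split
#' boundaries are comparable along the read as it passed the pore.
#'
#' A SAM file must carry a header (it is converted to BAM internally); an
#' `SA` tag announcing more segments than are present in the file produces a
#' warning, and groups are built from the records actually present.
#'
#' @param path Path to a SAM or BAM file with header.
#' @return A [SplitAlignments].
#' @export
readSplitAlignments <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        bam <- tryCatch(
            Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE),
            error = function(e) stop("failed to parse SAM (missing or ",
                                     "invalid header?): ", conditionMessage(e))
        )
    }
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]
    if (!length(hdr$targets))
        stop("alignment file has no @SQ header lines")
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "strand", "pos", "cigar"),
        tag = "SA",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE))
    b <- Rsamtools::scanBam(bam, param = p)[[1]]
    n <- length(b$qname)
    if (n == 0)
        return(SplitAlignments(.emptySegments(), hdr$targets))
    cig <- b$cigar
    clips <- t(vapply(cig, .cigarClips, c(leading = 0L, trailing = 0L)))
    refspan <- vapply(cig, cigarRefSpan, integer(1), USE.NAMES = FALSE)
    readspan <- vapply(cig, cigarReadSpan, integer(1), USE.NAMES = FALSE)
    readlen <- clips[, 1] + clips[, 2] + readspan
    minus <- as.character(b$strand) == "-"
    read_start <- ifelse(minus, clips[, 2], clips[, 1])
    seg <- data.frame(
        read_id = b$qname,
        chrom = as.character(b$rname),
        ref_start = b$pos - 1L,
        ref_end = b$pos - 1L + refspan,
        read_start = as.integer(read_start),
        read_end = as.integer(read_start + readspan),
        strand = ifelse(minus, "-", "+"),
        is_primary = !bitwAnd(b$flag, 0x800L),
        cigar = unname(cig),
        stringsAsFactors = FALSE
    )
    .checkSATags(b, seg)
    SplitAlignments(seg, hdr$targets)
}

.emptySegments <- function() {
    data.frame(read_id = character(), chrom = character(),
               ref_start = integer(), ref_end = integer(),
               read_start = integer(), read_end = integer(),
               strand = character(), is_primary = logical(),
               cigar = character(), stringsAsFactors = FALSE)
}

# SA tags promise one extra record per ';'-terminated entry; warn when the
# file does not deliver them (groups are still built from what is present).
.checkSATags <- function(b, seg) {
    sa <- b$tag$SA
    if (is.null(sa)) return(invisible())
    promised <- ifelse(is.na(sa), 0L,
                       lengths(regmatches(sa, gregexpr(";", sa))))
    per_read <- tapply(promised, b$qname, max)
    present <- table(seg$read_id)
    ids <- names(per_read)[per_read + 1L > as.integer(present[names(per_read)])]
    if (length(ids))
        warning("SA tag announces segments absent from the file for read(s): ",
                paste(head(ids, 5), collapse = ", "),
                if (length(ids) > 5) ", ..." else "")
    invisible()
}

# Segments of one read, sorted by read_start.
.groupSegments <- function(aln, read_id) {
    seg <- alignmentSegments(aln)
    seg[seg$read_id == read_id, , drop = FALSE]
}

#' Read raw signal traces from the package's TSV dialect
#'
#' One block per read, blocks separated by a blank line:
#' line 1 `read_id<TAB>sample_rate_hz`, line 2 the comma-separated current
#' samples (pA), line 3 the comma-separated 0-based `base_index` (sample
#' index at which each called base's translocation begins). A non-monotone
#' `base_index` is a hard error.
#'
#' @param path Path to a signal TSV file.
#' @return A [SignalTraceSet].
#' @seealso [writeSignalTraces()]
#' @export
readSignalTraces <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    content <- nzchar(lines)
    grp <- cumsum(!content)  # blank lines separate blocks
    blocks <- split(lines[content], grp[content])
    samples <- list()
    bidx <- list()
    rate <- numeric()
    for (bl in blocks) {
        if (length(bl) != 3L)
            stop("malformed signal block (expected 3 lines): ",
                 substr(bl[1], 1, 40))
        hd <- strsplit(bl[1], "\t", fixed = TRUE)[[1]]
        id <- hd[1]
        s <- as.numeric(strsplit(bl[2], ",", fixed = TRUE)[[1]])
        b <- as.integer(strsplit(bl[3], ",", fixed = TRUE)[[1]])
        if (is.unsorted(b))
            stop("non-monotone base_index for read '", id, "'")
        samples[[id]] <- s
        bidx[[id]] <- b
        rate <- c(rate, as.numeric(hd[2]))
    }
    SignalTraceSet(samples, bidx, rate)
}

#' Write signal traces in the package's TSV dialect
#'
#' @param x A [SignalTraceSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSignalTraces <- function(x, path) {
    stopifnot(is(x, "SignalTraceSet"))
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(length(x))) {
        writeLines(c(
            paste0(x@ids[i], "\t", format(x@sampleRate[i], scientific = FALSE)),
            paste(as.character(x@samples[[i]]), collapse = ","),
            paste(x@baseIndex[[i]], collapse = ","),
            ""), con)
    }
    invisible(path)
}
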