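#' Extract inverted-duplicate boundary pairs from split alignments
#'
#' For every pair of read-adjacent alignment segments of a read that map to
#' the same chromosome in opposite orientations (the inversion signature),
#' emits the pair of reference coordinates flanking the read-internal split:
#' the reference position of the earlier segment's read-adjacent end (its
#' `ref_end` on `+`, `ref_start` on `-`) and of the later segment's
#' read-adjacent end (`ref_start` on `+`, `ref_end` on `-`). Same-strand or
#' cross-chromosome adjacencies are skipped silently.
#'
#' @param aln A [SplitAlignments].
#' @return A data.frame `read_id`, `chrom`, `coord_a`, `coord_b`,
#'   `strand_a`, `strand_b`, `read_split_pos` (read coordinate of the split,
#'   i.e. the earlier segment's `read_end`).
#' @export
extractBoundaryPairs <- function(aln) {
    stopifnot(is(aln, "SplitAlignments"))
    seg <- alignmentSegments(aln)
    empty <- data.frame(read_id = character(), chrom = character(),
                        coord_a = integer(), coord_b = integer(),
                        strand_a = character(), strand_b = character(),
                        read_split_pos = integer(), stringsAsFactors = FALSE)
    if (nrow(seg) < 2) return(empty)
    seg <- seg[order(seg$read_id, seg$read_start), , drop = FALSE]
    i <- which(seg$read_id[-nrow(seg)] == seg$read_id[-1])
    if (!length(i)) return(empty)
    a <- seg[i, ]
    b <- seg[i + 1L, ]
    keep <- a$chrom == b$chrom & a$strand != b$strand
    a <- a[keep, ]
    b <- b[keep, ]
    data.frame(
        read_id = a$read_id,
        chrom = a$chrom,
        coord_a = as.integer(ifelse(a$strand == "+", a$ref_end, a$ref_start)),
        coord_b = as.integer(ifelse(b$strand == "+", b$ref_start, b$ref_end)),
        strand_a = a$strand,
        strand_b = b$strand,
        read_split_pos = as.integer(a$read_end),
        stringsAsFactors = FALSE,
        row.names = NULL
    )
}

#' Greedy resolution of boundary pairs into junction calls
#'
#' Boundary pairs are binned at `tolerance` resolution per chromosome; the
#' most-supported bin (distinct reads; ties broken by leftmost coordinate,
#' then chromosome) seeds a cluster whose representative coordinates are the
#' bin medians. All remaining pairs with both coordinates within `tolerance`
#' of the seed's are absorbed, removed, and the procedure repeats. The call
#' position is the median of all member coordinates (both ends pooled). The
#' result is deterministic and invariant to input order.
#'
#' @param pairs Boundary-pair table from [extractBoundaryPairs()].
#' @param tolerance Clustering tolerance in bp (default 200).
#' @return A data.frame of junction calls sorted by `chrom`, `position`:
#'   `chrom`, `position`, `support` (# distinct reads), `depth_ratio`,
#'   `passed_depth` (NA until [depthEnrichment()]), plus a `members`
#'   list-column of the member boundary pairs.
#' @export
resolvePairsGreedy <- function(pairs, tolerance = 200L) {
    stopifnot(tolerance >= 0)
    calls <- list()
    if (nrow(pairs)) {
        # canonical order makes the procedure permutation-invariant
        pairs <- pairs[order(pairs$chrom, pairs$coord_a, pairs$coord_b,
                             pairs$read_id), , drop = FALSE]
        binw <- max(1L, as.integer(tolerance))
        left <- pairs
        while (nrow(left)) {
            bin <- paste(left$chrom, left$coord_a %/% binw,
                         left$coord_b %/% binw)
            supp <- tapply(left$read_id, bin, function(r) length(unique(r)))
            binmin <- tapply(pmin(left$coord_a, left$coord_b), bin, min)
            ord <- order(-as.vector(supp[names(supp)]),
                         as.vector(binmin[names(supp)]), names(supp))
            top <- names(supp)[ord[1]]
            seedrows <- left[bin == top, , drop = FALSE]
            seed_a <- median(seedrows$coord_a)
            seed_b <- median(seedrows$coord_b)
            absorb <- left$chrom == seedrows$chrom[1] &
                abs(left$coord_a - seed_a) <= tolerance &
                abs(left$coord_b - seed_b) <= tolerance
            members <- left[absorb, , drop = FALSE]
            rownames(members) <- NULL
            calls[[length(calls) + 1L]] <- list(
                chrom = members$chrom[1],
                position = as.integer(round(median(
                    c(members$coord_a, members$coord_b)))),
                support = length(unique(members$read_id)),
                members = members)
            left <- left[!absorb, , drop = FALSE]
        }
    }
    out <- data.frame(
        chrom = vapply(calls, `[[`, character(1), "chrom"),
        position = vapply(calls, `[[`, integer(1), "position"),
        support = vapply(calls, `[[`, integer(1), "support"),
        depth_ratio = rep(NA_real_, length(calls)),
        passed_depth = rep(NA, length(calls)),
        stringsAsFactors = FALSE
    )
    out$members <- lapply(calls, `[[`, "members")
    out <- out[order(out$chrom, out$position), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-base coverage track from split alignments
#'
#' Depth of aligned reference bases per chromosome, computed from primary
#' and supplementary segments (secondary and unmapped records were never
#' loaded). For inverted duplications the duplicated copy is carried by the
#' supplementary segment, so both contribute to the local depth signal; the
#' chromosome-wide median against which enrichment is measured is dominated
#' by primary alignments.
#'
#' @param aln A [SplitAlignments] with reference lengths.
#' @return A named list of [S4Vectors::Rle] coverage vectors, one per
#'   reference sequence.
#' @export
computeCoverage <- function(aln) {
    stopifnot(is(aln, "SplitAlignments"))
    seqlen <- referenceLengths(aln)
    if (!length(seqlen)) stop("alignments carry no reference lengths")
    seg <- alignmentSegments(aln)
    out <- lapply(names(seqlen), function(chr) {
        s <- seg[seg$chrom == chr, , drop = FALSE]
        IRanges::coverage(IRanges::IRanges(start = s$ref_start + 1L,
                                           end = s$ref_end),
                          width = seqlen[[chr]])
    })
    names(out) <- names(seqlen)
    out
}

#' Read-depth enrichment around junction calls
#'
#' A duplication elevates local read depth, so each call's mean depth over
#' `[position - flank, position + flank)` (truncated to the contig) is
#' compared with the chromosome-wide median depth.
#'
#' @param calls Junction-call table from [resolvePairsGreedy()].
#' @param coverage Coverage track from [computeCoverage()].
#' @param flank Half-window in bp (default 2000).
#' @param min_ratio Calls with `depth_ratio >= min_ratio` get
#'   `passed_depth = TRUE` (default 1.5).
#' @return The call table with `depth_ratio` and `passed_depth` filled in.
#' @export
depthEnrichment <- function(calls, coverage, flank = 2000L, min_ratio = 1.5) {
    if (!nrow(calls)) return(calls)
    for (i in seq_len(nrow(calls))) {
        chr <- calls$chrom[i]
        cov <- coverage[[chr]]
        if (is.null(cov)) stop("coverage track lacks chromosome ", chr)
        md <- median(cov)
        if (md == 0) stop("zero median depth on chromosome ", chr)
        lo <- max(1L, calls$position[i] - as.integer(flank) + 1L)
        hi <- min(length(cov), calls$position[i] + as.integer(flank))
        calls$depth_ratio[i] <- mean(S4Vectors::window(cov, lo, hi)) / md
    }
    calls$passed_depth <- calls$depth_ratio >= min_ratio
    calls
}

#' Call inverted-duplicate junctions
#'
#' Full composition: boundary-pair extraction, greedy resolution and depth
#' enrichment. All calls are retained with their `passed_depth` flag;
#' filtering is a report-time choice.
#'
#' @param aln A [SplitAlignments].
#' @param coverage Optional coverage track (computed from `aln` when NULL).
#' @param tolerance,flank,min_ratio See [resolvePairsGreedy()] and
#'   [depthEnrichment()].
#' @return A junction-call table sorted by `chrom`, `position`.
#' @export
callJunctions <- function(aln, coverage = NULL, tolerance = 200L,
                          flank = 2000L, min_ratio = 1.5) {
    pairs <- extractBoundaryPairs(aln)
    calls <- resolvePairsGreedy(pairs, tolerance = tolerance)
    if (!nrow(calls)) return(calls)
    if (is.null(coverage)) coverage <- computeCoverage(aln)
    depthEnrichment(calls, coverage, flank = flank, min_ratio = min_ratio)
}

#' Write junction calls to BED (plus companion TSV)
#'
#' BED: `chrom`, `position`, `position + 1`, name `IDJ_<n>`, score =
#' support. The companion TSV adds `depth_ratio`, `passed_depth` and the
#' supporting read ids.
#'
#' @param calls Junction-call table.
#' @param bed_path,tsv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
writeJunctionCalls <- function(calls, bed_path = NULL, tsv_path = NULL) {
    name <- sprintf("IDJ_%d", seq_len(nrow(calls)))
    if (!is.null(bed_path)) {
        bed <- data.frame(calls$chrom, calls$position, calls$position + 1L,
                          name, calls$support)
        write.table(bed, bed_path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    if (!is.null(tsv_path)) {
        tsv <- data.frame(
            name = name, chrom = calls$chrom, position = calls$position,
            support = calls$support,
            depth_ratio = round(calls$depth_ratio, 4),
            passed_depth = calls$passed_depth,
            read_ids = vapply(calls$members, function(m)
                paste(unique(m$read_id), collapse = ","), character(1)))
        write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(c(bed_path, tsv_path))
}
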