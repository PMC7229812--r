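#' Detect current-uplift intervals in a raw signal trace
#'
#' Inverted-duplicate junction failures co-occur with a sustained elevation
#' ("uplift") of the pore current. The trace is summarized by a centered
#' rolling median of `window` samples; the baseline is the median of that
#' series and the spread its unscaled median absolute deviation (the
#' rolling-median series is the statistic actually thresholded, and its MAD
#' is robust to the uplift samples themselves, which can be a third of a
#' junction read's trace). Uplift intervals are maximal runs where the
#' rolling median exceeds `baseline + mad_mult * spread`; runs separated by
#' fewer than `window` samples are merged.
#'
#' @param trace A [SignalTraceSet] (one or more traces).
#' @param window Rolling-median window in samples (default 250).
#' @param mad_mult Threshold multiplier (default 5).
#' @return A data.frame `read_id`, `sample_start`, `sample_end` (0-based
#'   half-open sample indices), `mean_current`, `baseline_current`. Traces
#'   shorter than `window` yield no intervals, with a warning.
#' @export
detectUplift <- function(trace, window = 250L, mad_mult = 5) {
    stopifnot(is(trace, "SignalTraceSet"))
    out <- list()
    short <- 0L
    for (i in seq_len(length(trace))) {
        x <- as.numeric(trace@samples[[i]])
        if (length(x) < window) {
            short <- short + 1L
            next
        }
        rm <- rollingMedian(x, window, align = "center")
        baseline <- median(rm)
        spread <- median(abs(rm - baseline))
        up <- rm > baseline + mad_mult * spread
        runs <- rle(up)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        k <- which(runs$values)
        if (!length(k)) next
        iv <- cbind(starts[k] - 1L, ends[k])  # 0-based half-open
        if (nrow(iv) > 1) {
            keep <- iv[1, , drop = FALSE]
            for (j in seq_len(nrow(iv))[-1]) {
                m <- nrow(keep)
                if (iv[j, 1] - keep[m, 2] < window)
                    keep[m, 2] <- iv[j, 2]
                else keep <- rbind(keep, iv[j, , drop = FALSE])
            }
            iv <- keep
        }
        out[[length(out) + 1L]] <- data.frame(
            read_id = trace@ids[i],
            sample_start = as.integer(iv[, 1]),
            sample_end = as.integer(iv[, 2]),
            mean_current = vapply(seq_len(nrow(iv)), function(j)
                mean(x[(iv[j, 1] + 1L):iv[j, 2]]), numeric(1)),
            baseline_current = baseline,
            stringsAsFactors = FALSE)
    }
    if (short > 0)
        warning(short, " trace(s) shorter than the window were skipped")
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(read_id = character(), sample_start = integer(),
                          sample_end = integer(), mean_current = numeric(),
                          baseline_current = numeric(),
                          stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}

#' Expected number of sequenced nucleotides for a read region
#'
#' The number of reference bases the molecule must have translocated while
#' the region `[read_start, read_end)` of the read was produced, derived
#' from the read's split alignment:
#'
#' * inside an aligned segment, the CIGAR-walked reference span of the
#'   sub-segment (deletions count: the molecule traversed them even though
#'   base-calling dropped them);
#' * across an unaligned gap between two aligned segments, the reference
#'   span implied by the flanking segments' read-adjacent reference
#'   coordinates (absolute difference), pro-rated if the region covers only
#'   part of the gap.
#'
#' Where consecutive segments overlap on the read (over-extended alignment
#' edges), the earlier segment takes precedence so each read base is counted
#' once.
#'
#' @param aln A [SplitAlignments].
#' @param read_id Which read.
#' @param read_start,read_end 0-based half-open read coordinates.
#' @return Integer number of expected bases.
#' @export
expectedBasesForRegion <- function(aln, read_id, read_start, read_end) {
    stopifnot(read_end > read_start)
    seg <- .groupSegments(aln, read_id)
    if (!nrow(seg)) stop("no alignments for read ", read_id)
    total <- 0
    covered <- 0L
    cursor <- -1L
    for (k in seq_len(nrow(seg))) {
        # precedence tiling: trim this segment to start after the previous
        eff_start <- max(seg$read_start[k], cursor)
        eff_end <- seg$read_end[k]
        if (k > 1L) {
            gap_lo <- cursor
            gap_hi <- seg$read_start[k]
            if (gap_hi > gap_lo) {
                gov <- min(gap_hi, read_end) - max(gap_lo, read_start)
                if (gov > 0) {
                    implied <- abs(.adjacentRefCoord(seg[k - 1L, ], "end") -
                                   .adjacentRefCoord(seg[k, ], "start"))
                    total <- total + implied * gov / (gap_hi - gap_lo)
                    covered <- covered + gov
                }
            }
        }
        if (eff_end > eff_start) {
            ov_lo <- max(eff_start, read_start)
            ov_hi <- min(eff_end, read_end)
            if (ov_hi > ov_lo) {
                total <- total + .refSpanForReadInterval(
                    seg$cigar[k], seg$strand[k], seg$read_start[k],
                    ov_lo, ov_hi)
                covered <- covered + (ov_hi - ov_lo)
            }
        }
        cursor <- max(cursor, seg$read_end[k])
    }
    if (covered < read_end - read_start)
        stop("region [", read_start, ",", read_end, ") of read ", read_id,
             " has no flanking alignment on both sides; expected bases ",
             "undefined")
    as.integer(round(total))
}

# Reference coordinate of a segment's read-adjacent end: `side = "end"` for
# the end facing higher read coordinates, `"start"` for the end facing lower
# read coordinates.
.adjacentRefCoord <- function(seg, side) {
    if (side == "end") {
        if (seg$strand == "+") seg$ref_end else seg$ref_start
    } else {
        if (seg$strand == "+") seg$ref_start else seg$ref_end
    }
}

#' Samples-per-base translocation-rate estimate for a read region
#'
#' Divides the number of sensor samples recorded while the region
#' translocated (difference of the signal-to-base index at the region
#' bounds, the end clamped to the trace length) by the expected number of
#' nucleotides from [expectedBasesForRegion()]. A lower samples-per-base
#' value means a faster translocation.
#'
#' @param trace A [SignalTraceSet] containing the read's trace.
#' @param aln A [SplitAlignments] containing the read's alignment.
#' @param read_id Which read.
#' @param read_start,read_end 0-based half-open read coordinates.
#' @return A one-row data.frame `read_id`, `read_start`, `read_end`,
#'   `expected_bases`, `n_samples`, `samples_per_base`.
#' @export
segmentRate <- function(trace, aln, read_id, read_start, read_end) {
    if (read_end <= read_start)
        stop("region of zero read length for read ", read_id)
    i <- match(read_id, trace@ids)
    if (is.na(i)) stop("no signal trace for read ", read_id)
    bidx <- trace@baseIndex[[i]]
    nsamp <- length(trace@samples[[i]])
    if (read_end > length(bidx))
        stop("base_index does not cover the region for read ", read_id)
    at <- function(k) if (k >= length(bidx)) nsamp else bidx[k + 1L]
    n_samples <- at(read_end) - at(read_start)
    expected <- expectedBasesForRegion(aln, read_id, read_start, read_end)
    if (expected == 0L)
        stop("zero expected bases for region [", read_start, ",", read_end,
             ") of read ", read_id)
    data.frame(read_id = read_id, read_start = as.integer(read_start),
               read_end = as.integer(read_end),
               expected_bases = expected, n_samples = as.integer(n_samples),
               samples_per_base = n_samples / expected,
               stringsAsFactors = FALSE)
}

#' Compare translocation rates between normal and low-phred regions
#'
#' For each read with at least one bounded low-phred region, pools the
#' samples and expected bases of its low-phred region(s) and of the
#' complementary normal-quality regions, yielding one samples-per-base pair
#' per read. Across reads, a one-sided sign test summarizes whether the
#' low-phred (uplifted) regions translocate faster (fewer samples per base)
#' than the normal regions.
#'
#' @param trace A [SignalTraceSet].
#' @param aln A [SplitAlignments].
#' @param regions Low-phred region table from [detectLowPhredRegions()]
#'   (bounded regions are used; unbounded ones are dropped).
#' @param read_lengths Named vector of read lengths (e.g.
#'   `readLengths(reads)`), needed to bound the trailing normal region.
#' @return A list with `per_read` (data.frame `read_id`, `normal_rate`,
#'   `low_rate`), `n_lower` (# reads with `low_rate < normal_rate`), and
#'   `sign_test_p` (one-sided binomial sign test; NA for < 1 usable read).
#' @export
compareRegionRates <- function(trace, aln, regions, read_lengths) {
    regions <- regions[regions$bounded, , drop = FALSE]
    ids <- intersect(unique(regions$read_id),
                     intersect(trace@ids, readIDs(aln)))
    rows <- list()
    for (id in ids) {
        reg <- regions[regions$read_id == id, , drop = FALSE]
        reg <- reg[order(reg$start), , drop = FALSE]
        L <- unname(read_lengths[[id]])
        low_iv <- cbind(reg$start, reg$end)
        norm_iv <- .complementIntervals(low_iv, L)
        rate_of <- function(iv) {
            tot_s <- 0
            tot_b <- 0
            for (j in seq_len(nrow(iv))) {
                r <- tryCatch(
                    segmentRate(trace, aln, id, iv[j, 1], iv[j, 2]),
                    error = function(e) NULL)
                if (!is.null(r)) {
                    tot_s <- tot_s + r$n_samples
                    tot_b <- tot_b + r$expected_bases
                }
            }
            if (tot_b == 0) NA_real_ else tot_s / tot_b
        }
        nr <- rate_of(norm_iv)
        lr <- rate_of(low_iv)
        if (!is.na(nr) && !is.na(lr))
            rows[[length(rows) + 1L]] <- data.frame(
                read_id = id, normal_rate = nr, low_rate = lr,
                stringsAsFactors = FALSE)
    }
    per_read <- do.call(rbind, rows)
    if (is.null(per_read))
        per_read <- data.frame(read_id = character(),
                               normal_rate = numeric(),
                               low_rate = numeric(), stringsAsFactors = FALSE)
    n <- nrow(per_read)
    n_lower <- sum(per_read$low_rate < per_read$normal_rate)
    p <- if (n >= 1)
        binom.test(n_lower, n, p = 0.5, alternative = "greater")$p.value
    else NA_real_
    list(per_read = per_read, n_lower = n_lower, sign_test_p = p)
}

# Complement of a set of disjoint sorted intervals within [0, L).
.complementIntervals <- function(iv, L) {
    out <- NULL
    prev <- 0L
    for (j in seq_len(nrow(iv))) {
        if (iv[j, 1] > prev) out <- rbind(out, c(prev, iv[j, 1]))
        prev <- max(prev, iv[j, 2])
    }
    if (prev < L) out <- rbind(out, c(prev, L))
    if (is.null(out)) matrix(integer(), ncol = 2) else out
}

#' Write uplift intervals and segment rates as TSV
#'
#' @param uplift Uplift table from [detectUplift()].
#' @param rates A data.frame of segment rates (any rows built from
#'   [segmentRate()], optionally with a `region_class` column).
#' @param uplift_path,rates_path Output paths (NULL to skip).
#' @return Invisibly, the paths written.
#' @export
writeSignalTables <- function(uplift = NULL, rates = NULL,
                              uplift_path = NULL, rates_path = NULL) {
    if (!is.null(uplift) && !is.null(uplift_path))
        write.table(uplift, uplift_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    if (!is.null(rates) && !is.null(rates_path))
        write.table(rates, rates_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    invisible(c(uplift_path, rates_path))
}
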