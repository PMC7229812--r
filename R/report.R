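#' Spearman rank correlation with tie handling
#'
#' Ranks both axes with average ranks for ties and computes the Pearson
#' correlation of the ranks. The p-value (two-sided) uses the
#' t-approximation with `n - 2` degrees of freedom for `n >= 10` and an
#' exact permutation null (all `n!` orderings) for `n < 10`. Zero variance
#' on either axis leaves the coefficient undefined and is an error, as is
#' `n < 3`.
#'
#' @param x,y Numeric vectors, or a two-column matrix/data.frame in `x`.
#' @return A list `rho`, `p_value`, `n`.
#' @examples
#' spearmanCorrelation(1:10, (1:10)^2)  # rho = 1
#' @export
spearmanCorrelation <- function(x, y = NULL) {
    if (is.null(y)) {
        y <- x[[2]]
        x <- x[[1]]
    }
    x <- as.numeric(x)
    y <- as.numeric(y)
    if (length(x) != length(y)) stop("x and y must have equal length")
    keep <- is.finite(x) & is.finite(y)
    if (!all(keep)) stop("x and y must be finite")
    n <- length(x)
    if (n < 3) stop("need at least 3 pairs")
    if (length(unique(x)) < 2 || length(unique(y)) < 2)
        stop("zero variance on one axis: rho undefined")
    rx <- rank(x)
    ry <- rank(y)
    rho <- cor(rx, ry)
    if (n >= 10) {
        tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- 2 * pt(-abs(tt), df = n - 2)
    } else {
        p <- .permutationP(rx, ry, rho)
    }
    list(rho = rho, p_value = max(p, .Machine$double.xmin), n = n)
}

# Exact permutation p-value: fraction of the n! orderings of y whose
# |rank correlation| reaches the observed one.
.permutationP <- function(rx, ry, rho_obs) {
    perms <- .allPerms(length(ry))
    mx <- rx - mean(rx)
    denom_x <- sqrt(sum(mx^2))
    hits <- 0L
    for (k in seq_len(nrow(perms))) {
        yy <- ry[perms[k, ]]
        my <- yy - mean(yy)
        r <- sum(mx * my) / (denom_x * sqrt(sum(my^2)))
        if (abs(r) >= abs(rho_obs) - 1e-12) hits <- hits + 1L
    }
    hits / nrow(perms)
}

.allPerms <- function(n) {
    if (n == 1L) return(matrix(1L))
    sub <- .allPerms(n - 1L)
    out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
    for (i in seq_len(n)) {
        rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
        out[rows, 1L] <- i
        out[rows, -1L] <- sub + (sub >= i)
    }
    out
}

#' Per-junction failure report
#'
#' For each junction call, finds the reads that span it (a read spans a
#' junction when one of its aligned segments covers the junction position
#' and one of its split boundaries lies within `tolerance` of it) and counts
#' how many of them failed: a spanning read fails when it has a low-phred
#' region whose read-coordinate interval, widened by `read_window` bases,
#' contains the read position of the split.
#'
#' @param calls Junction-call table from [callJunctions()].
#' @param aln A [SplitAlignments].
#' @param regions Low-phred region table from [detectLowPhredRegions()].
#' @param pairs Optional boundary-pair table (recomputed from `aln` when
#'   NULL).
#' @param tolerance Boundary-to-junction distance in bp (default 200).
#' @param read_window Low-region to split proximity in read bases
#'   (default 500).
#' @return A data.frame, one row per call: `chrom`, `position`, `support`,
#'   `depth_ratio`, `passed_depth`, `n_spanning`, `n_failed`,
#'   `fail_fraction` (NA when no read spans).
#' @export
buildJunctionReport <- function(calls, aln, regions, pairs = NULL,
                                tolerance = 200L, read_window = 500L) {
    if (is.null(pairs)) pairs <- extractBoundaryPairs(aln)
    seg <- alignmentSegments(aln)
    out <- calls[, c("chrom", "position", "support", "depth_ratio",
                     "passed_depth"), drop = FALSE]
    out$n_spanning <- 0L
    out$n_failed <- 0L
    out$fail_fraction <- NA_real_
    for (i in seq_len(nrow(calls))) {
        pos <- calls$position[i]
        chr <- calls$chrom[i]
        # the junction is a breakpoint between bases, so a segment whose
        # half-open end abuts it still covers it
        covering <- unique(seg$read_id[seg$chrom == chr &
                                       seg$ref_start <= pos &
                                       seg$ref_end >= pos])
        near <- pairs[pairs$chrom == chr &
                      (abs(pairs$coord_a - pos) <= tolerance |
                       abs(pairs$coord_b - pos) <= tolerance), ,
                      drop = FALSE]
        spanning <- intersect(covering, unique(near$read_id))
        failed <- 0L
        for (id in spanning) {
            split_pos <- near$read_split_pos[near$read_id == id]
            reg <- regions[regions$read_id == id, , drop = FALSE]
            if (nrow(reg) && any(vapply(split_pos, function(sp)
                any(reg$start - read_window <= sp &
                    reg$end + read_window >= sp), logical(1))))
                failed <- failed + 1L
        }
        out$n_spanning[i] <- length(spanning)
        out$n_failed[i] <- failed
        out$fail_fraction[i] <- if (length(spanning))
            failed / length(spanning) else NA_real_
    }
    out
}

#' Run the full junction-failure pipeline on files
#'
#' Orchestrates the four stages — phred scan, junction calling, signal
#' analysis (optional) and reporting — from a FASTQ file, a SAM/BAM file
#' and (optionally) a signal TSV, writing tabular outputs and a structured
#' run log under `out_dir`:
#' `phred_regions.tsv`, `length_pairs.tsv`, `junctions.bed`,
#' `junctions.tsv`, `junction_report.tsv`, `correlation.tsv`,
#' `uplift_intervals.tsv`, `segment_rates.tsv`, `run_log.json`.
#' Outputs are deterministic: rerunning on the same inputs reproduces them
#' byte for byte.
#'
#' @param fastq,alignments,signal Input paths (`signal` may be NULL).
#' @param out_dir Output directory (created if needed).
#' @param min_length,sd_multiplier,window Low-phred detection parameters.
#' @param stats_method Passed to [computePhredStats()].
#' @param tolerance,flank,min_ratio Junction-calling parameters.
#' @param uplift_window,mad_mult Uplift-detection parameters.
#' @return Invisibly, a list with all intermediate objects and result
#'   tables.
#' @export
runPipeline <- function(fastq, alignments, signal = NULL, out_dir,
                        min_length = 10L, sd_multiplier = 5, window = 10L,
                        stats_method = "pooled",
                        tolerance = 200L, flank = 2000L, min_ratio = 1.5,
                        uplift_window = 250L, mad_mult = 5) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log <- list()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    reads <- stage("scan", {
        r <- readNanoporeFastq(fastq)
        if (length(r) == 0) stop("no reads in ", fastq)
        r
    })
    stats <- stage("scan", computePhredStats(reads, method = stats_method))
    regions <- stage("scan", detectLowPhredRegions(
        reads, stats, min_length = min_length,
        sd_multiplier = sd_multiplier, window = window))
    pairs_len <- measureLengthPairs(regions)
    log$scan <- list(n_reads = length(reads),
                     n_bases = unname(sum(readLengths(reads))),
                     global_median = globalMedian(stats),
                     global_sd = globalSD(stats),
                     n_regions = nrow(regions),
                     n_unbounded = sum(!regions$bounded),
                     n_reads_with_region = length(unique(regions$read_id)),
                     n_length_pairs = nrow(pairs_len))

    aln <- stage("junctions", readSplitAlignments(alignments))
    bpairs <- extractBoundaryPairs(aln)
    calls <- stage("junctions", callJunctions(
        aln, tolerance = tolerance, flank = flank, min_ratio = min_ratio))
    log$junctions <- list(n_alignment_groups = length(aln),
                          n_boundary_pairs = nrow(bpairs),
                          n_calls = nrow(calls),
                          n_passed_depth = sum(calls$passed_depth))

    uplift <- NULL
    rates <- NULL
    if (!is.null(signal)) {
        traces <- stage("signal", readSignalTraces(signal))
        uplift <- stage("signal", detectUplift(
            traces, window = uplift_window, mad_mult = mad_mult))
        cmp <- stage("signal", compareRegionRates(
            traces, aln, regions, readLengths(reads)))
        rates <- cmp$per_read
        log$signal <- list(n_traces = length(traces),
                           n_uplift_intervals = nrow(uplift),
                           n_rate_pairs = nrow(rates),
                           n_low_slower_sampled = cmp$n_lower,
                           sign_test_p = cmp$sign_test_p)
    }

    report <- stage("report", buildJunctionReport(
        calls, aln, regions, pairs = bpairs, tolerance = tolerance))
    corr <- if (nrow(pairs_len) >= 3 &&
                length(unique(pairs_len$preceding_length)) > 1 &&
                length(unique(pairs_len$low_region_length)) > 1)
        spearmanCorrelation(pairs_len$preceding_length,
                            pairs_len$low_region_length)
    else list(rho = NA_real_, p_value = NA_real_, n = nrow(pairs_len))
    log$report <- list(spearman_rho = corr$rho, spearman_p = corr$p_value,
                       n_pairs = corr$n)

    out <- function(f) file.path(out_dir, f)
    write.table(regions, out("phred_regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pairs_len, out("length_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeJunctionCalls(calls, out("junctions.bed"), out("junctions.tsv"))
    write.table(report, out("junction_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(rho = corr$rho, p_value = corr$p_value,
                           n = corr$n),
                out("correlation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(uplift))
        writeSignalTables(uplift, rates, out("uplift_intervals.tsv"),
                          out("segment_rates.tsv"))
    jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(reads = reads, stats = stats, regions = regions,
                   length_pairs = pairs_len, alignments = aln,
                   calls = calls, report = report, correlation = corr,
                   uplift = uplift, rates = rates, log = log))
}
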