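#' Sample-wide phred statistics
#'
#' Computes the global location and scale of a sample's per-base phred
#' distribution, from which the low-phred detection threshold
#' `global_median - sd_multiplier * global_sd` is derived. The default pools
#' the per-base phred values of all reads: the median and the population
#' standard deviation (denominator `n`) of the pooled values. The
#' `"read_median"` alternative takes the median and population SD of the
#' per-read median phreds instead, which is far less sensitive to the
#' fraction of aberrant bases in the sample.
#'
#' @param reads A [NanoporeReadSet] with at least one base.
#' @param method `"pooled"` (default) or `"read_median"`.
#' @return A [PhredStats].
#' @examples
#' rs <- NanoporeReadSet(Biostrings::DNAStringSet(c(a = "ACGTA")),
#'                       phred = list(c(10L, 20L, 30L, 40L, 50L)))
#' computePhredStats(rs)  # median 30, sd sqrt(200)
#' @export
computePhredStats <- function(reads, method = c("pooled", "read_median")) {
    method <- match.arg(method)
    stopifnot(is(reads, "NanoporeReadSet"))
    if (length(reads) == 0 || sum(readLengths(reads)) == 0)
        stop("cannot compute phred statistics of an empty sample")
    n_bases <- sum(readLengths(reads))
    vals <- switch(method,
        pooled = as.numeric(unlist(reads@phred, use.names = FALSE)),
        read_median = vapply(reads@phred, function(p) median(as.numeric(p)),
                             numeric(1))
    )
    mu <- mean(vals)
    PhredStats(globalMedian = median(vals),
               globalSD = sqrt(mean((vals - mu)^2)),
               nBases = n_bases, nReads = length(reads))
}

#' Rolling phred profile of a read
#'
#' Median phred in a window anchored at each base (window length
#' `min(window, bases remaining)`), the profile used to visualize the
#' post-junction quality collapse.
#'
#' @param reads A [NanoporeReadSet].
#' @param read_id Which read (id or index).
#' @param window Window length (default 1000).
#' @return Numeric vector, one value per base.
#' @export
rollingPhredProfile <- function(reads, read_id = 1L, window = 1000L) {
    stopifnot(is(reads, "NanoporeReadSet"))
    if (is.character(read_id)) read_id <- match(read_id, readIDs(reads))
    phred <- as.numeric(reads@phred[[read_id]])
    rollingMedian(phred, window, align = "left")
}

#' Detect low-phred regions in reads
#'
#' Implements seed detection, expansion, merging and bounded/unbounded
#' classification of low-quality read intervals:
#'
#' 1. *Seeds*: maximal runs of at least `min_length` consecutive bases whose
#'    phred is strictly below the threshold
#'    `global_median - sd_multiplier * global_sd`. The default operates on
#'    the raw per-base values, so that a collapse shorter than `min_length`
#'    can never seed a region; `seed_mode = "window"` smooths with a
#'    centered `window`-base median first (more permissive at region edges,
#'    but a sub-`min_length` collapse can then spread over enough windowed
#'    positions to seed).
#' 2. *Expansion*: each seed is extended outward one base at a time on each
#'    side; a side halts when the median of the `window` bases immediately
#'    adjacent to it reaches the global median (or the read end).
#' 3. Overlapping expanded regions are merged.
#' 4. A region whose end touches the read end never recovered and is marked
#'    `bounded = FALSE`.
#'
#' @param reads A [NanoporeReadSet].
#' @param stats A [PhredStats] for the sample the reads belong to.
#' @param min_length Minimum seed run length in bases (default 10).
#' @param sd_multiplier Threshold is this many global SDs below the global
#'   median (default 5).
#' @param window Window length for seed medians and expansion halting
#'   (default 10).
#' @param seed_mode `"run"` (raw per-base values, default) or `"window"`
#'   (centered windowed median).
#' @return A data.frame with one row per region: `read_id`, `start`, `end`
#'   (0-based half-open read coordinates), `length`, `median_phred` (median
#'   over the final region), `bounded`. Reads shorter than `window` are
#'   skipped with a warning.
#' @export
detectLowPhredRegions <- function(reads, stats, min_length = 10L,
                                  sd_multiplier = 5, window = 10L,
                                  seed_mode = c("run", "window")) {
    stopifnot(is(reads, "NanoporeReadSet"), is(stats, "PhredStats"))
    seed_mode <- match.arg(seed_mode)
    threshold <- globalMedian(stats) - sd_multiplier * globalSD(stats)
    res <- vector("list", length(reads))
    ids <- readIDs(reads)
    short <- 0L
    for (i in seq_along(res)) {
        phred <- as.numeric(reads@phred[[i]])
        if (length(phred) < window) {
            short <- short + 1L
            next
        }
        # no windowed median can drop below the threshold unless some
        # individual base does
        if (min(phred) >= threshold) next
        reg <- .scanRead(phred, threshold, globalMedian(stats),
                         min_length, window, seed_mode)
        if (nrow(reg)) {
            reg$read_id <- ids[i]
            res[[i]] <- reg
        }
    }
    if (short > 0)
        warning(short, " read(s) shorter than the window were skipped")
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(read_id = character(), start = integer(),
                          end = integer(), length = integer(),
                          median_phred = numeric(), bounded = logical(),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[c("read_id", "start", "end", "length", "median_phred", "bounded")]
}

# Single-read worker. Coordinates are 0-based half-open.
.scanRead <- function(phred, threshold, halt_median, min_length, window,
                      seed_mode) {
    n <- length(phred)
    stat <- if (seed_mode == "window")
        rollingMedian(phred, window, align = "center") else phred
    below <- stat < threshold
    runs <- rle(below)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- which(runs$values & runs$lengths >= min_length)
    if (!length(k)) return(.emptyRegions())
    seeds <- cbind(starts[k] - 1L, ends[k])  # 0-based half-open
    out <- NULL
    for (j in seq_len(nrow(seeds))) {
        s <- seeds[j, 1]
        e <- seeds[j, 2]
        # a seed inside an already-expanded region re-derives the same
        # boundaries (expansion halts on the same adjacent windows), so it
        # can be skipped without changing the merged result
        if (!is.null(out) && any(s >= out[, 1] & e <= out[, 2])) next
        out <- rbind(out, .expandRegion(phred, s, e, window, halt_median))
    }
    # merge overlapping expanded regions
    out <- out[order(out[, 1]), , drop = FALSE]
    merged <- out[1, , drop = FALSE]
    for (j in seq_len(nrow(out))[-1]) {
        m <- nrow(merged)
        if (out[j, 1] <= merged[m, 2]) {
            merged[m, 2] <- max(merged[m, 2], out[j, 2])
        } else {
            merged <- rbind(merged, out[j, , drop = FALSE])
        }
    }
    data.frame(
        read_id = NA_character_,
        start = as.integer(merged[, 1]),
        end = as.integer(merged[, 2]),
        length = as.integer(merged[, 2] - merged[, 1]),
        median_phred = vapply(seq_len(nrow(merged)), function(j)
            median(phred[(merged[j, 1] + 1L):merged[j, 2]]), numeric(1)),
        bounded = merged[, 2] < length(phred),
        stringsAsFactors = FALSE
    )
}

.emptyRegions <- function() {
    data.frame(read_id = character(), start = integer(), end = integer(),
               length = integer(), median_phred = numeric(),
               bounded = logical(), stringsAsFactors = FALSE)
}

# Expand [s, e) outward one base at a time; a side halts when the median of
# the (up to) `window` bases immediately adjacent to it is at or above
# `halt_median`, or when the read edge is reached.
.expandRegion <- function(phred, s, e, window, halt_median) {
    n <- length(phred)
    while (s > 0L) {
        lo <- max(0L, s - window)
        if (median(phred[(lo + 1L):s]) >= halt_median) break
        s <- s - 1L
    }
    while (e < n) {
        hi <- min(n, e + window)
        if (median(phred[(e + 1L):hi]) >= halt_median) break
        e <- e + 1L
    }
    cbind(s, e)
}

#' Preceding-region / low-region length pairs
#'
#' For every bounded low-phred region, measures the pre-junction length
#' (read start to region start) and the low-region length (region width).
#' Unbounded regions never recover before the read end and are excluded, as
#' are regions starting at the very first base (no preceding sequence to
#' measure). Exclusions are reported in the `reason` attribute-free
#' `excluded` data.frame returned alongside when `keep_excluded = TRUE`.
#'
#' @param regions Region table from [detectLowPhredRegions()].
#' @param keep_excluded Also return the excluded rows and why.
#' @return A data.frame `read_id`, `preceding_length`, `low_region_length`,
#'   `junction_ref_pos` (NA until joined with junction calls); with
#'   `keep_excluded = TRUE`, a list with elements `pairs` and `excluded`.
#' @export
measureLengthPairs <- function(regions, keep_excluded = FALSE) {
    reason <- rep(NA_character_, nrow(regions))
    reason[!regions$bounded] <- "unbounded: never recovers before read end"
    reason[regions$bounded & regions$start == 0L] <-
        "no preceding sequence (region starts at read start)"
    ok <- is.na(reason)
    pairs <- data.frame(
        read_id = regions$read_id[ok],
        preceding_length = regions$start[ok],
        low_region_length = regions$end[ok] - regions$start[ok],
        junction_ref_pos = rep(NA_integer_, sum(ok)),
        stringsAsFactors = FALSE
    )
    if (!keep_excluded) return(pairs)
    list(pairs = pairs,
         excluded = cbind(regions[!ok, , drop = FALSE],
                          reason = reason[!ok]))
}
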