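# Independent oracles and fixture builders. Everything here is deliberately
# naive: straight loops, base-R medians, first-principles formulas.

# NanoporeReadSet from bare phred vectors (sequence content is irrelevant to
# the quality analyses)
phredReadSet <- function(phred_list) {
    ids <- names(phred_list)
    if (is.null(ids)) ids <- sprintf("p%03d", seq_along(phred_list))
    NanoporeReadSet(
        Biostrings::DNAStringSet(setNames(
            strrep("A", lengths(phred_list)), ids)),
        lapply(phred_list, as.integer))
}

# naive windowed medians (centered, truncated; even width = mean of the two
# central order statistics via stats::median)
naiveRollCenter <- function(x, w) {
    n <- length(x)
    left <- (w - 1L) %/% 2L
    right <- w %/% 2L
    vapply(seq_len(n), function(i)
        median(x[max(1L, i - left):min(n, i + right)]), numeric(1))
}

naiveRollLeft <- function(x, w) {
    n <- length(x)
    vapply(seq_len(n), function(i) median(x[i:min(n, i + w - 1L)]),
           numeric(1))
}

# Brute-force low-phred region finder: exhaustively enumerates every
# interval of >= min_length consecutive below-threshold bases, keeps the
# maximal ones, applies the expansion rule base by base, merges. Returns the
# same columns as detectLowPhredRegions (minus read_id).
oracleLowRegions <- function(phred, gmed, gsd, min_length = 10L,
                             sd_mult = 5, window = 10L) {
    n <- length(phred)
    thr <- gmed - sd_mult * gsd
    below <- phred < thr
    cs <- c(0L, cumsum(below))
    qual <- list()
    for (a in seq_len(max(0L, n - min_length + 1L))) {
        b <- a + min_length - 1L
        while (b <= n && cs[b + 1L] - cs[a] == b - a + 1L) {
            qual[[length(qual) + 1L]] <- c(a, b)
            b <- b + 1L
        }
    }
    empty <- data.frame(start = integer(), end = integer(),
                        length = integer(), median_phred = numeric(),
                        bounded = logical(), stringsAsFactors = FALSE)
    if (!length(qual)) return(empty)
    qm <- do.call(rbind, qual)
    maximal <- qm[(qm[, 1] == 1L | !below[pmax(qm[, 1] - 1L, 1L)]) &
                  (qm[, 2] == n | !below[pmin(qm[, 2] + 1L, n)]), ,
                  drop = FALSE]
    expand1 <- function(s, e) { # 0-based half-open
        while (s > 0L) {
            lo <- max(0L, s - window)
            if (median(phred[(lo + 1L):s]) >= gmed) break
            s <- s - 1L
        }
        while (e < n) {
            hi <- min(n, e + window)
            if (median(phred[(e + 1L):hi]) >= gmed) break
            e <- e + 1L
        }
        c(s, e)
    }
    ex <- t(apply(maximal, 1, function(r) expand1(r[1] - 1L, r[2])))
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    merged <- ex[1, , drop = FALSE]
    for (j in seq_len(nrow(ex))[-1]) {
        m <- nrow(merged)
        if (ex[j, 1] <= merged[m, 2])
            merged[m, 2] <- max(merged[m, 2], ex[j, 2])
        else merged <- rbind(merged, ex[j, , drop = FALSE])
    }
    data.frame(
        start = as.integer(merged[, 1]), end = as.integer(merged[, 2]),
        length = as.integer(merged[, 2] - merged[, 1]),
        median_phred = vapply(seq_len(nrow(merged)), function(j)
            median(phred[(merged[j, 1] + 1L):merged[j, 2]]), numeric(1)),
        bounded = merged[, 2] < n, stringsAsFactors = FALSE)
}

# First-principles Spearman: explicit rank table (counting comparisons, ties
# as average rank) and the Pearson sum formula on the ranks.
fpRank <- function(v)
    vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))

fpSpearman <- function(x, y) {
    rx <- fpRank(x)
    ry <- fpRank(y)
    mx <- rx - mean(rx)
    my <- ry - mean(ry)
    sum(mx * my) / sqrt(sum(mx^2) * sum(my^2))
}

# Naive uplift finder: full naive rolling median, per-position thresholding,
# naive run merge.
naiveUplift <- function(x, window = 250L, mad_mult = 5) {
    rm <- naiveRollCenter(x, window)
    baseline <- median(rm)
    spread <- median(abs(rm - baseline))
    up <- rm > baseline + mad_mult * spread
    iv <- NULL
    i <- 1L
    n <- length(up)
    while (i <= n) {
        if (up[i]) {
            j <- i
            while (j < n && up[j + 1L]) j <- j + 1L
            iv <- rbind(iv, c(i - 1L, j))
            i <- j + 1L
        } else i <- i + 1L
    }
    if (is.null(iv)) return(iv)
    merged <- iv[1, , drop = FALSE]
    for (j in seq_len(nrow(iv))[-1]) {
        m <- nrow(merged)
        if (iv[j, 1] - merged[m, 2] < window)
            merged[m, 2] <- iv[j, 2]
        else merged <- rbind(merged, iv[j, , drop = FALSE])
    }
    merged
}

# a manually assembled split alignment (CIGARs consistent with the
# coordinates by construction)
manualSplitAlignments <- function(segdf, seqlengths = c(chr1 = 300000L,
                                                        chr2 = 300000L)) {
    SplitAlignments(segdf, seqlengths)
}

# block-structured phred read: blocks = list(c(level, sd, length), ...)
blockPhred <- function(blocks) {
    unlist(lapply(blocks, function(b)
        as.integer(pmax(0, pmin(93, round(rnorm(b[3], b[1], b[2])))))))
}

# small simulation shared by several tests (cached per session)
.simCache <- new.env()
cachedSim <- function(key, maker) {
    if (is.null(.simCache[[key]])) .simCache[[key]] <- maker()
    .simCache[[key]]
}
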