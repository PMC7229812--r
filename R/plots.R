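#' Plot the rolling phred profile of a read
#'
#' Base-graphics view of the per-read quality collapse: the rolling median
#' phred along the read, with detected low-phred regions shaded.
#'
#' @param reads A [NanoporeReadSet].
#' @param read_id Read id or index.
#' @param regions Optional region table from [detectLowPhredRegions()].
#' @param window Profile window (default 1000).
#' @return Invisibly, the profile vector.
#' @export
plotPhredProfile <- function(reads, read_id = 1L, regions = NULL,
                             window = 1000L) {
    prof <- rollingPhredProfile(reads, read_id, window)
    id <- if (is.character(read_id)) read_id else readIDs(reads)[read_id]
    plot(seq_along(prof) - 1L, prof, type = "l", xlab = "read position (b)",
         ylab = sprintf("median phred (%d b window)", window), main = id)
    if (!is.null(regions)) {
        reg <- regions[regions$read_id == id, , drop = FALSE]
        if (nrow(reg))
            graphics::rect(reg$start, graphics::par("usr")[3], reg$end,
                           graphics::par("usr")[4],
                           col = grDevices::adjustcolor("red", 0.15),
                           border = NA)
    }
    invisible(prof)
}

#' Plot a raw signal trace with detected uplift intervals
#'
#' @param trace A [SignalTraceSet].
#' @param read_id Read id or index.
#' @param uplift Optional uplift table from [detectUplift()].
#' @param thin Plot every `thin`-th sample (default 25) to keep the device
#'   responsive on multi-megasample traces.
#' @return Invisibly, NULL.
#' @export
plotSignalTrace <- function(trace, read_id = 1L, uplift = NULL, thin = 25L) {
    i <- if (is.character(read_id)) match(read_id, readIDs(trace))
         else read_id
    x <- as.numeric(trace@samples[[i]])
    id <- readIDs(trace)[i]
    sel <- seq(1L, length(x), by = thin)
    plot(sel - 1L, x[sel], type = "l", col = "grey40",
         xlab = "sample index", ylab = "current (pA)", main = id)
    if (!is.null(uplift)) {
        up <- uplift[uplift$read_id == id, , drop = FALSE]
        if (nrow(up))
            graphics::rect(up$sample_start, graphics::par("usr")[3],
                           up$sample_end, graphics::par("usr")[4],
                           col = grDevices::adjustcolor("orange", 0.2),
                           border = NA)
    }
    invisible(NULL)
}
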