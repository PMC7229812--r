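#' Rolling median
#'
#' Windowed median used throughout the package. `align = "center"` centers a
#' window of `window` values on each position (offsets `-(window-1)/2` to
#' `+window/2`), truncating at both ends of the sequence; `align = "left"`
#' anchors the window at the position (length `min(window, n - i)`), so it
#' only shrinks at the end. Even windows yield the mean of the two central
#' order statistics.
#'
#' @param x Numeric vector.
#' @param window Window width (>= 1).
#' @param align `"center"` or `"left"`.
#' @return Numeric vector the same length as `x`.
#' @examples
#' rollingMedian(c(1, 1, 10, 1, 1), 3)
#' @export
rollingMedian <- function(x, window, align = c("center", "left")) {
    align <- match.arg(align)
    window <- as.integer(window)
    if (window < 1L) stop("window must be >= 1")
    x <- as.numeric(x)
    if (align == "center") roll_median_center(x, window)
    else roll_median_left(x, window)
}
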