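#' Otsu threshold of a sample of intensities
#'
#' Computes the threshold maximizing between-class variance over a binned
#' histogram of the supplied values. Works on arbitrary (float) intensity
#' samples, which allows thresholding restricted sub-histograms such as "all
#' pixels darker than the background mean" — the adaptive threshold used for
#' membrane detection.
#'
#' @param x numeric vector of intensities (non-finite values dropped).
#' @param levels number of histogram bins (default 256, i.e. 8-bit
#'   resolution over the sample range).
#' @param range optional length-2 numeric giving the histogram range;
#'   defaults to `range(x)`.
#' @return a single threshold `t`; the two classes are `x <= t` and `x > t`.
#'   `t` always lies strictly between the smallest and largest sample.
#' @details Errors with condition class `"pombeseg_degenerate_error"` when the
#'   histogram cannot be split (empty input, constant values, or all mass in
#'   one bin) — callers use this to detect blank fields and fall back.
#' @export
otsu_threshold <- function(x, levels = 256L, range = NULL) {
  x <- x[is.finite(x)]
  if (length(x) == 0L)
    ps_error("otsu_threshold: no finite values", "pombeseg_degenerate_error")
  if (is.null(range)) range <- base::range(x)
  if (!(range[2] > range[1]))
    ps_error("otsu_threshold: degenerate histogram (constant values)",
             "pombeseg_degenerate_error")
  levels <- as.integer(levels)
  br <- seq(range[1], range[2], length.out = levels + 1L)
  bin <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  h <- as.numeric(tabulate(bin, nbins = levels))
  mids <- (br[-1L] + br[-(levels + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  tot <- w[levels]; mtot <- m[levels]
  w0 <- w[-levels]; m0 <- m[-levels]
  valid <- w0 > 0 & w0 < tot
  if (!any(valid))
    ps_error("otsu_threshold: degenerate histogram (single occupied class)",
             "pombeseg_degenerate_error")
  # between-class variance: w0*w1*(mu0 - mu1)^2 == (mtot*w0 - m0*tot)^2/(w0*w1*tot^2)
  num <- (mtot * w0 - m0 * tot)^2
  den <- w0 * (tot - w0)
  score <- ifelse(valid, num / den, -Inf)
  k <- which.max(score)
  br[k + 1L]
}
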