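#' Write diagnostic overlay images for a pipeline run
#'
#' Writes `corrected.png` (the focus/contrast-corrected image),
#' `classes.png` (pixel classes: blue background, green interior, red
#' membrane) and `contours.png` (accepted contours in random colors over the
#' bright-field image, rejected contours in gray).
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param field the [field_images()] the pipeline ran on.
#' @param out_dir output directory.
#' @param seed seed for the contour colors.
#' @return invisibly, the written paths.
#' @export
write_debug_images <- function(result, field, out_dir, seed = 1L) {
  if (!requireNamespace("png", quietly = TRUE))
    ps_error("write_debug_images requires the 'png' package", "pombeseg_io_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  norm01 <- function(m) {
    r <- range(m)
    if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
  }
  p1 <- file.path(out_dir, "corrected.png")
  png::writePNG(norm01(result$corrected), p1)

  L <- result$cmap$labels
  rgb <- array(0, c(nrow(L), ncol(L), 3))
  rgb[, , 1] <- (L == CLASS_MEMBRANE) * 1
  rgb[, , 2] <- (L == CLASS_INTERIOR) * 1
  rgb[, , 3] <- (L == CLASS_BACKGROUND) * 1
  p2 <- file.path(out_dir, "classes.png")
  png::writePNG(rgb, p2)

  base <- norm01(field$trans)
  ov <- array(rep(base, 3), c(nrow(base), ncol(base), 3))
  draw <- function(v, col) {
    dv <- resample_closed(as.matrix(v[, 1:2]), spacing = 0.4)
    xi <- pmin(pmax(round(dv[, 1]), 0), ncol(base) - 1) + 1
    yi <- pmin(pmax(round(dv[, 2]), 0), nrow(base) - 1) + 1
    for (k in 1:3) ov[cbind(yi, xi, k)] <<- col[k]
  }
  with_local_seed(seed, {
    for (r in result$records) draw(r$contour, stats::runif(3, 0.2, 1))
    for (r in result$rejected) draw(r$contour, c(0.5, 0.5, 0.5))
  })
  p3 <- file.path(out_dir, "contours.png")
  png::writePNG(ov, p3)
  invisible(c(p1, p2, p3))
}
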