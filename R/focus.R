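#' Fit the bilinear focus plane
#'
#' In a tilted specimen, the defocus z at position (x, y) is modelled as the
#' plane `z = a + b*x + c*y`. The nucleus-minus-background intensity
#' difference in the bright-field channel is linearly related to z (for
#' moderate defocus), so nucleus centroids with `z_i = mean(nucleus_i) -
#' mu_B` are the fit samples.
#'
#' @param samples data.frame or matrix with columns x, y, z (>= 3 rows, not
#'   collinear in x, y).
#' @return list with `coeffs = c(a, b, c)`, `r2`, `n`, and the fit's
#'   coefficient standard errors.
#' @details Errors with class `"pombeseg_fit_error"` on fewer than 3 samples
#'   or a rank-deficient design; the pipeline then falls back to global
#'   correction only.
#' @export
fit_focus_plane <- function(samples) {
  s <- as.data.frame(samples)
  if (nrow(s) < 3L)
    ps_error("fit_focus_plane: need at least 3 samples", "pombeseg_fit_error")
  X <- cbind(1, s$x, s$y)
  if (qr(X)$rank < 3L)
    ps_error("fit_focus_plane: collinear sample positions", "pombeseg_fit_error")
  fit <- stats::lm(z ~ x + y, data = s)
  co <- unname(stats::coef(fit))
  # summary.lm warns on noiseless (numerically perfect) fits; harmless here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  se <- tryCatch(unname(sqrt(diag(stats::vcov(fit)))), error = function(e) rep(NA_real_, 3))
  list(coeffs = c(a = co[1], b = co[2], c = co[3]), r2 = r2, n = nrow(s), se = se)
}

#' Does the field have a focus gradient?
#'
#' True iff the fitted plane takes both signs within the frame (there is a
#' region to complement) and explains at least `min_r2` of the nucleus-z
#' variance (guards against noise-driven flips).
#'
#' @param samples plane-fit samples as in [fit_focus_plane()].
#' @param dims image `c(height, width)`.
#' @param min_r2 minimum R^2.
#' @return logical.
#' @export
detect_focus_gradient <- function(samples, dims, min_r2 = 0.3) {
  fit <- tryCatch(fit_focus_plane(samples),
                  pombeseg_fit_error = function(e) NULL)
  if (is.null(fit)) return(FALSE)
  co <- fit$coeffs
  if (co[["b"]] == 0 && co[["c"]] == 0) return(FALSE)
  # a plane's extrema over the frame are at its corners
  corners <- rbind(c(0, 0), c(dims[2] - 1, 0), c(0, dims[1] - 1),
                   c(dims[2] - 1, dims[1] - 1))
  z <- co[["a"]] + co[["b"]] * corners[, 1] + co[["c"]] * corners[, 2]
  both_signs <- min(z) < 0 && max(z) >= 0
  both_signs && is.finite(fit$r2) && fit$r2 >= min_r2
}

#' Complement intensities where the focus plane is negative
#'
#' Pixels on the negatively defocused side of the plane have inverted
#' contrast; reflecting their intensity about the background mean
#' (`j = 2*mu_B - i`) restores normal polarity. Pixels at the background
#' mean are fixed points, so intensity stays C0-continuous across the z = 0
#' line wherever the local intensity is near mu_B. The operation is an
#' involution.
#'
#' @param image numeric matrix.
#' @param plane coefficients `c(a, b, c)` of the fitted focus plane.
#' @param mu_B background mean intensity.
#' @return corrected matrix.
#' @export
complement_negative_region <- function(image, plane, mu_B) {
  z <- plane_values(plane, nrow(image), ncol(image))
  neg <- z < 0
  image[neg] <- 2 * mu_B - image[neg]
  image
}

#' Global linear contrast adjustment
#'
#' Affine map anchored at the background mean that rescales intensities so
#' the nucleus-minus-background contrast equals the target `delta`:
#' `I' = mu_B + (I - mu_B) * delta / (mu_N - mu_B)`. When `mu_N < mu_B`
#' (globally inverted contrast) the scale factor is negative and the map
#' also complements the image.
#'
#' @param image numeric matrix.
#' @param mu_N,mu_B nucleus and background means of `image`.
#' @param delta target contrast (intensity units).
#' @return adjusted matrix.
#' @details Errors with class `"pombeseg_validation_error"` when
#'   `mu_N == mu_B` (no usable contrast); the caller skips the adjustment.
#' @export
global_contrast_adjust <- function(image, mu_N, mu_B, delta) {
  if (mu_N == mu_B)
    ps_error("global_contrast_adjust: mu_N == mu_B, no contrast to normalise",
             "pombeseg_validation_error")
  mu_B + (image - mu_B) * delta / (mu_N - mu_B)
}

#' Run the full focus-gradient and contrast correction
#'
#' Step 1 (adaptive): if fluorescence-derived nucleus samples are available
#' and the mode allows it, fit the focus plane and complement the negative
#' region about mu_B. Step 2 (global): recompute the nucleus mean on the
#' corrected image and linearly adjust so the nucleus-background contrast
#' equals the configured target. Without usable fluorescence (mu_N == mu_B)
#' both steps are skipped.
#'
#' @param regions a `region_masks` from [detect_regions()].
#' @param config a [pipeline_config()].
#' @param delta target contrast; defaults from the config and field dynamic
#'   range via the caller.
#' @return list: `image` (corrected bright-field), `plane` (fitted
#'   coefficients or NULL), `complemented` (logical), `adjusted` (logical),
#'   `mu_N`, `mu_B` of the corrected image, `delta`.
#' @export
correct_focus <- function(regions, config = pipeline_config(), delta) {
  img <- regions$trans
  mu_B <- regions$mu_B
  plane <- NULL; complemented <- FALSE; adjusted <- FALSE
  mu_N <- regions$mu_N
  if (regions$fluorescence_used && config$focus_correction_mode != "off" &&
      nrow(regions$centroids) >= 3L) {
    samples <- data.frame(x = regions$centroids[, 1],
                          y = regions$centroids[, 2],
                          z = regions$nucleus_means - mu_B)
    do_it <- switch(config$focus_correction_mode,
                    on = TRUE,
                    auto = detect_focus_gradient(samples, dim(img), config$min_r2),
                    off = FALSE)
    fit <- tryCatch(fit_focus_plane(samples),
                    pombeseg_fit_error = function(e) NULL)
    if (!is.null(fit)) plane <- fit$coeffs
    if (do_it && !is.null(plane)) {
      img <- complement_negative_region(img, plane, mu_B)
      complemented <- TRUE
    }
  }
  if (regions$fluorescence_used) {
    mu_N <- mean(img[regions$nuclei])
    res <- tryCatch({
      out <- global_contrast_adjust(img, mu_N, mu_B, delta)
      list(img = out, ok = TRUE)
    }, pombeseg_validation_error = function(e) list(img = img, ok = FALSE))
    img <- res$img; adjusted <- res$ok
    if (adjusted) mu_N <- mu_B + delta
  }
  list(image = img, plane = plane, complemented = complemented,
       adjusted = adjusted, mu_N = mu_N, mu_B = mu_B, delta = delta)
}
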