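#' Local shading correction
#'
#' Subtracts the disk-kernel mean-filtered image from the image, flattening
#' slow illumination variation. The output mean is approximately zero for
#' slowly varying input, and the operation is invariant to adding a constant
#' offset.
#'
#' @param image numeric matrix.
#' @param radius disk kernel radius in px (default 40).
#' @return corrected matrix of the same shape.
#' @export
shading_correct <- function(image, radius = 40) {
  radius <- as.integer(radius)
  if (radius < 1L)
    ps_error("shading_correct: radius must be >= 1", "pombeseg_validation_error")
  if (nrow(image) < 2L * radius + 1L || ncol(image) < 2L * radius + 1L)
    ps_error(sprintf("shading_correct: image %dx%d smaller than kernel (radius %d)",
                     nrow(image), ncol(image), radius),
             "pombeseg_validation_error")
  image - mean_disk_filter(image, radius)
}

#' Detect the background region of a bright-field image
#'
#' Background pixels are flat (low-texture): the Sobel gradient-magnitude
#' image is thresholded by Otsu and the below-threshold mask is cleaned
#' morphologically; only components covering at least `min_frac` of the
#' frame are kept, which excludes enclosed low-gradient cell interiors from
#' the background.
#'
#' @param trans shading-corrected bright-field matrix.
#' @param min_frac minimum component area as a fraction of the frame.
#' @return logical background mask.
#' @details Errors with class `"pombeseg_degenerate_error"` when the
#'   gradient image has no contrast (blank field).
#' @export
detect_background <- function(trans, min_frac = 0.01) {
  gm <- sobel_magnitude(trans)
  t <- otsu_threshold(as.numeric(gm))
  low <- gm < t
  low <- as.matrix(EBImage::opening(low * 1, disc_brush(1))) > 0
  lab <- label8(low)
  if (max(lab) == 0L)
    ps_error("detect_background: no low-gradient region found",
             "pombeseg_degenerate_error")
  keep <- filter_components(lab, min_frac * length(trans))
  if (max(keep) == 0L) {
    # fall back to the largest component when the field is fragmented
    sz <- component_sizes(lab)
    keep <- matrix(0L, nrow(lab), ncol(lab))
    keep[lab == which.max(sz)] <- 1L
  }
  keep > 0L
}

#' Detect nuclei in fluorescence channels
#'
#' Each shading-corrected fluorescence channel is thresholded by Otsu;
#' channels are combined by mask union (two markers label the same nuclei,
#' and union is robust to one channel being dark). Components below
#' `min_area` are removed and centroids computed.
#'
#' @param fluor a matrix or list of matrices (shading-corrected).
#' @param min_area minimum nucleus area in px^2.
#' @return list with `mask` (logical), `labels` (integer matrix) and
#'   `centroids` (n x 2 matrix of 0-based x, y).
#' @details Errors with class `"pombeseg_degenerate_error"` if every channel
#'   has a degenerate (constant) histogram; the pipeline then falls back to
#'   the mu_N = mu_B mode.
#' @export
detect_nuclei <- function(fluor, min_area = 20) {
  if (is.matrix(fluor)) fluor <- list(fluor)
  if (length(fluor) == 0L)
    ps_error("detect_nuclei: no fluorescence channel", "pombeseg_validation_error")
  masks <- list(); errs <- 0L
  for (f in fluor) {
    m <- tryCatch(f > otsu_threshold(as.numeric(f)),
                  pombeseg_degenerate_error = function(e) NULL)
    if (is.null(m)) errs <- errs + 1L else masks <- c(masks, list(m))
  }
  if (length(masks) == 0L)
    ps_error("detect_nuclei: all fluorescence channels are degenerate",
             "pombeseg_degenerate_error")
  mask <- Reduce(`|`, masks)
  lab <- filter_components(label8(mask), min_area)
  list(mask = lab > 0L, labels = lab, centroids = component_centroids(lab))
}

#' Mean intensities over nucleus and background regions
#'
#' @param trans bright-field matrix (shading-corrected).
#' @param nucleus_mask,background_mask logical masks.
#' @return named numeric `c(mu_N, mu_B)`.
#' @export
region_means <- function(trans, nucleus_mask, background_mask) {
  if (!any(nucleus_mask))
    ps_error("region_means: empty nucleus mask", "pombeseg_validation_error")
  if (!any(background_mask))
    ps_error("region_means: empty background mask", "pombeseg_validation_error")
  c(mu_N = mean(trans[nucleus_mask]), mu_B = mean(trans[background_mask]))
}

# per-nucleus mean bright-field intensity (z samples for the plane fit)
nucleus_trans_means <- function(trans, labels) {
  n <- max(labels, 0L)
  if (n == 0L) return(numeric(0))
  as.numeric(tapply(trans[labels > 0L], labels[labels > 0L], mean))
}

#' Detect regions and summary statistics for one field
#'
#' Runs shading correction on every channel, background detection on the
#' bright-field channel, and nucleus detection on the fluorescence channels
#' (unless disabled). Nuclei are subtracted from the background mask so the
#' two regions are disjoint. When no usable fluorescence is present the
#' fallback mu_N = mu_B is applied and focus correction will be skipped.
#'
#' @param field a [field_images()].
#' @param config a [pipeline_config()].
#' @return object of class `region_masks`: corrected channels, masks,
#'   nucleus centroids and per-nucleus means, mu_N, mu_B, and a
#'   `fluorescence_used` flag.
#' @export
detect_regions <- function(field, config = pipeline_config()) {
  trans <- shading_correct(field$trans, config$shading_radius)
  background <- detect_background(trans)
  nuc <- NULL
  if (config$use_fluorescence && length(field$fluor) > 0L) {
    fl <- lapply(field$fluor, shading_correct, radius = config$shading_radius)
    nuc <- tryCatch(detect_nuclei(fl, config$min_nucleus_area),
                    pombeseg_degenerate_error = function(e) {
                      warning("degenerate fluorescence; falling back to mu_N = mu_B")
                      NULL
                    })
  }
  if (!is.null(nuc) && max(nuc$labels) > 0L) {
    background <- background & !nuc$mask
    if (!any(background))
      ps_error("detect_regions: empty background after nucleus removal",
               "pombeseg_validation_error")
    mu <- region_means(trans, nuc$mask, background)
    z_means <- nucleus_trans_means(trans, nuc$labels)
    structure(list(trans = trans, background = background,
                   nuclei = nuc$mask, nucleus_labels = nuc$labels,
                   centroids = nuc$centroids, nucleus_means = z_means,
                   mu_N = mu[["mu_N"]], mu_B = mu[["mu_B"]],
                   fluorescence_used = TRUE),
              class = "region_masks")
  } else {
    mu_B <- mean(trans[background])
    structure(list(trans = trans, background = background,
                   nuclei = matrix(FALSE, nrow(trans), ncol(trans)),
                   nucleus_labels = matrix(0L, nrow(trans), ncol(trans)),
                   centroids = matrix(numeric(0), 0, 2),
                   nucleus_means = numeric(0),
                   mu_N = mu_B, mu_B = mu_B,
                   fluorescence_used = FALSE),
              class = "region_masks")
  }
}
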