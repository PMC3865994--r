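#' Pixel class codes
#'
#' Integer codes of the four pixel classes used throughout the pipeline.
#' @export
CLASS_BACKGROUND <- 1L
#' @rdname CLASS_BACKGROUND
#' @export
CLASS_INTERIOR <- 2L
#' @rdname CLASS_BACKGROUND
#' @export
CLASS_MEMBRANE <- 3L
#' @rdname CLASS_BACKGROUND
#' @export
CLASS_AMBIGUOUS <- 4L

new_pixel_class_map <- function(labels, t_membrane = NA_real_,
                                t_interior = NA_real_, mu_B = NA_real_) {
  structure(list(labels = labels, t_membrane = t_membrane,
                 t_interior = t_interior, mu_B = mu_B),
            class = "pixel_class_map")
}

#' @export
print.pixel_class_map <- function(x, ...) {
  tb <- tabulate(x$labels, 4L)
  cat(sprintf(
    "<pixel_class_map> %dx%d: background %d, interior %d, membrane %d, ambiguous %d\n",
    nrow(x$labels), ncol(x$labels), tb[1], tb[2], tb[3], tb[4]))
  invisible(x)
}

#' Classify pixels into background / interior / membrane / ambiguous
#'
#' Membrane pixels fall below an adaptive (Otsu) threshold computed over the
#' sub-histogram of pixels darker than the background mean; interior pixels
#' exceed the nucleus mean (strictly). Background is taken from the supplied
#' mask. Precedence on overlap: background, then membrane, then interior;
#' everything else is ambiguous.
#'
#' @param image focus- and contrast-corrected bright-field matrix.
#' @param background_mask logical mask from [detect_background()].
#' @param mu_N nucleus mean of the corrected image (interior threshold), or
#'   `NULL` to derive the interior threshold from background statistics only
#'   (Otsu over pixels brighter than mu_B — the no-fluorescence mode).
#' @param mu_B background mean of the corrected image.
#' @return a `pixel_class_map` recording the thresholds used.
#' @export
classify_pixels <- function(image, background_mask, mu_N, mu_B) {
  dark <- image[image < mu_B]
  t_m <- tryCatch(otsu_threshold(dark),
                  pombeseg_degenerate_error = function(e) {
                    warning("no membrane-candidate pixels darker than the background; membrane set empty")
                    -Inf
                  })
  if (length(dark) == 0L) {
    warning("no pixels darker than the background mean; membrane set empty")
    t_m <- -Inf
  }
  if (is.null(mu_N)) {
    bright <- image[image > mu_B]
    t_i <- tryCatch(otsu_threshold(bright),
                    pombeseg_degenerate_error = function(e) Inf)
  } else {
    t_i <- mu_N
  }
  labels <- matrix(CLASS_AMBIGUOUS, nrow(image), ncol(image))
  labels[image > t_i] <- CLASS_INTERIOR
  labels[image < t_m] <- CLASS_MEMBRANE
  labels[background_mask] <- CLASS_BACKGROUND
  new_pixel_class_map(labels, t_membrane = t_m, t_interior = t_i, mu_B = mu_B)
}

#' Morphologically smooth the class regions
#'
#' Each of the background, interior and membrane masks is independently
#' closed then opened with a disk structuring element, and isolated single
#' pixels (no 8-neighbour of the same class) are removed. Pixels vacated by
#' smoothing become ambiguous; where the smoothed regions collide the
#' precedence is background > membrane > interior.
#'
#' @param cmap a `pixel_class_map`.
#' @param se_radius disk radius of the structuring element (default 1).
#' @return smoothed `pixel_class_map`.
#' @export
smooth_classes <- function(cmap, se_radius = 1) {
  # diamond (cross) structuring element: the minimal symmetric disk; a 3x3
  # box would erase 2-3 px membrane rings at diagonal orientations outright
  br <- EBImage::makeBrush(2L * as.integer(se_radius) + 1L, shape = "diamond")
  smooth1 <- function(mask) {
    m <- EBImage::opening(EBImage::closing(mask * 1, br), br) > 0
    nb <- as.matrix(EBImage::filter2(m * 1, matrix(1, 3, 3), boundary = "replicate")) - m
    m & nb >= 1  # drop pixels with no same-class 8-neighbour
  }
  L <- cmap$labels
  B <- smooth1(L == CLASS_BACKGROUND)
  M <- smooth1(L == CLASS_MEMBRANE)
  C <- smooth1(L == CLASS_INTERIOR)
  out <- matrix(CLASS_AMBIGUOUS, nrow(L), ncol(L))
  out[C] <- CLASS_INTERIOR
  out[M] <- CLASS_MEMBRANE
  out[B] <- CLASS_BACKGROUND
  cmap$labels <- out
  cmap
}

#' Resolve ambiguous pixels by iterated distance transforms
#'
#' Grows the background and interior regions into neighbouring ambiguous
#' pixels, with the membrane acting as a barrier (similar to a watershed).
#' Each iteration computes the Euclidean distance transforms D_b, D_c, D_m
#' of the current background, interior and membrane sets and reassigns each
#' ambiguous pixel x to background if `D_b(x) <= D_c(x)` and
#' `D_b(x) < D_m(x)` (ties go to background), or to interior if
#' `D_c(x) < D_b(x)` and `D_c(x) < D_m(x)`. Iteration stops when the
#' ambiguous set is unchanged; surviving ambiguous pixels (those closest to
#' membrane) exit as membrane. Only ambiguous pixels are ever relabelled,
#' and the ambiguous set is non-increasing, so termination is guaranteed.
#'
#' @param cmap a `pixel_class_map`.
#' @return `pixel_class_map` with no ambiguous pixels.
#' @export
resolve_ambiguous <- function(cmap) {
  L <- cmap$labels
  repeat {
    X <- L == CLASS_AMBIGUOUS
    if (!any(X)) break
    Db <- dist_to_set(L == CLASS_BACKGROUND)
    Dc <- dist_to_set(L == CLASS_INTERIOR)
    Dm <- dist_to_set(L == CLASS_MEMBRANE)
    to_b <- X & Db <= Dc & Db < Dm
    to_c <- X & Dc < Db & Dc < Dm
    if (!any(to_b) && !any(to_c)) break
    L[to_b] <- CLASS_BACKGROUND
    L[to_c] <- CLASS_INTERIOR
  }
  L[L == CLASS_AMBIGUOUS] <- CLASS_MEMBRANE
  cmap$labels <- L
  cmap
}

#' Initial snake contours from interior components
#'
#' Traces the boundary of every 8-connected interior component of at least
#' `min_area` px^2 and resamples it to approximately equal arc-length vertex
#' spacing.
#'
#' @param cmap resolved `pixel_class_map` (no ambiguous pixels).
#' @param min_area minimum component area (px^2).
#' @param spacing target vertex spacing (px).
#' @return list of contour matrices (columns x, y; closed implicitly), one
#'   per component, with the component id as attribute `"component"`.
#' @export
initial_contours <- function(cmap, min_area = 50, spacing = 2) {
  lab <- filter_components(label8(cmap$labels == CLASS_INTERIOR), min_area)
  n <- max(lab)
  if (n == 0L) return(list())
  oc <- EBImage::ocontour(lab)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    b <- oc[[i]]
    # ocontour returns 0-based (row-1, col-1) = (y, x)
    v <- cbind(x = b[, 2], y = b[, 1])
    v <- resample_closed(v, spacing = spacing)
    attr(v, "component") <- i
    out[[i]] <- v
  }
  out
}

#' Membrane edge map for the GVF field
#'
#' The binary indicator of the membrane class, smoothed with a small
#' Gaussian and rescaled so its maximum is 1 (all-zero when the membrane
#' set is empty).
#'
#' @param cmap resolved `pixel_class_map`.
#' @param sigma Gaussian sigma in px.
#' @return matrix `f` with values in `[0, 1]`.
#' @export
membrane_edge_map <- function(cmap, sigma = 1) {
  f <- gaussian_blur((cmap$labels == CLASS_MEMBRANE) * 1, sigma)
  mx <- max(f)
  if (mx > 0) f <- f / mx
  f[f < 0] <- 0
  f
}
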