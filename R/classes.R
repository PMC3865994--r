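#' Bundle registered channels for one field of view
#'
#' @param trans numeric matrix, transmitted-illumination (bright-field)
#'   intensities; rows are y, columns are x.
#' @param fluor list of 0..2 nuclear-fluorescence matrices registered to the
#'   same frame (e.g. CFP / YFP), each the same shape as `trans`.
#' @param dynamic_range nominal intensity dynamic range of the acquisition
#'   (255 for 8-bit, 65535 for 16-bit). Used to scale the default target
#'   contrast. Defaults to the observed range of `trans` (at least 1).
#' @return an object of class `field_images`. All channels are promoted to
#'   double; intensity complementation can push values outside the on-disk
#'   range, so integer storage is never kept internally.
#' @export
field_images <- function(trans, fluor = list(), dynamic_range = NULL) {
  if (!is.matrix(trans)) ps_error("trans must be a matrix", "pombeseg_validation_error")
  storage.mode(trans) <- "double"
  if (!all(is.finite(trans)))
    ps_error("trans contains non-finite values", "pombeseg_validation_error")
  if (is.matrix(fluor)) fluor <- list(fluor)
  fluor <- lapply(fluor, function(f) {
    if (!is.matrix(f)) ps_error("fluorescence channel must be a matrix",
                                "pombeseg_validation_error")
    if (!identical(dim(f), dim(trans)))
      ps_error(sprintf("channel shape mismatch: trans is %dx%d, fluorescence is %dx%d",
                       nrow(trans), ncol(trans), nrow(f), ncol(f)),
               "pombeseg_validation_error")
    storage.mode(f) <- "double"
    f
  })
  if (length(fluor) > 2L)
    ps_error("at most two fluorescence channels are supported",
             "pombeseg_validation_error")
  if (is.null(dynamic_range))
    dynamic_range <- max(diff(range(trans)), 1)
  structure(list(trans = trans, fluor = fluor, dynamic_range = dynamic_range),
            class = "field_images")
}

#' @export
print.field_images <- function(x, ...) {
  cat(sprintf("<field_images> %d x %d px, %d fluorescence channel(s), dynamic range %.4g\n",
              nrow(x$trans), ncol(x$trans), length(x$fluor), x$dynamic_range))
  invisible(x)
}

#' Pipeline configuration
#'
#' Holds all tunable parameters of the segmentation pipeline with their
#' defaults. Snake weights default to lambda1 = 1, lambda2 = 1,
#' alpha = 0.03, beta = 0.2 and mu_gvf = 0.8.
#'
#' @param shading_radius disk radius (px) of the mean filter used for local
#'   shading correction.
#' @param target_contrast target difference (intensity units) between the
#'   corrected nucleus and background means; `NULL` means
#'   `target_contrast_frac` times the input dynamic range.
#' @param target_contrast_frac fraction of the dynamic range used when
#'   `target_contrast` is `NULL`.
#' @param focus_correction_mode `"auto"` (complement only when a focus
#'   gradient is detected), `"on"`, or `"off"`.
#' @param min_cell_area minimum interior-component area (px^2) seeding a
#'   contour.
#' @param min_nucleus_area minimum nucleus component area (px^2).
#' @param se_radius disk radius of the structuring element for class
#'   smoothing.
#' @param contour_spacing target vertex spacing (px) of snake contours.
#' @param lambda1,lambda2 relative weights of internal and external snake
#'   energy.
#' @param alpha,beta snake tension and rigidity.
#' @param mu_gvf GVF regularization weight.
#' @param gvf_iters,gvf_dt GVF solver iterations and time step (default step
#'   is 90% of the stability bound `1/(4*mu_gvf)`).
#' @param snake_iters,snake_dt snake evolution iterations and time step.
#' @param resample_every resample contour vertices every this many snake
#'   iterations.
#' @param min_r2 minimum R^2 of the fitted focus plane for the gradient to
#'   count as present in `"auto"` mode.
#' @param use_fluorescence if `FALSE`, ignore fluorescence channels: set
#'   mu_N = mu_B, skip focus correction, and derive the interior threshold
#'   from background statistics only.
#' @param border_margin distance (px) from the frame edge within which a
#'   contour vertex counts as border contact.
#' @param rng_seed seed routed to every stochastic step (validator training).
#' @param ... ignored, reserved.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(shading_radius = 40,
                            target_contrast = NULL,
                            target_contrast_frac = 0.15,
                            focus_correction_mode = c("auto", "on", "off"),
                            min_cell_area = 50,
                            min_nucleus_area = 20,
                            se_radius = 1,
                            contour_spacing = 2,
                            lambda1 = 1, lambda2 = 1,
                            alpha = 0.03, beta = 0.2,
                            mu_gvf = 0.8,
                            gvf_iters = 80, gvf_dt = NULL,
                            snake_iters = 200, snake_dt = 1,
                            resample_every = 10,
                            min_r2 = 0.3,
                            use_fluorescence = TRUE,
                            border_margin = 1,
                            rng_seed = 1L, ...) {
  focus_correction_mode <- match.arg(focus_correction_mode)
  if (is.null(gvf_dt)) gvf_dt <- 0.9 * 0.25 / mu_gvf
  cfg <- list(shading_radius = shading_radius,
              target_contrast = target_contrast,
              target_contrast_frac = target_contrast_frac,
              focus_correction_mode = focus_correction_mode,
              min_cell_area = min_cell_area,
              min_nucleus_area = min_nucleus_area,
              se_radius = se_radius,
              contour_spacing = contour_spacing,
              lambda1 = lambda1, lambda2 = lambda2,
              alpha = alpha, beta = beta,
              mu_gvf = mu_gvf,
              gvf_iters = gvf_iters, gvf_dt = gvf_dt,
              snake_iters = snake_iters, snake_dt = snake_dt,
              resample_every = resample_every,
              min_r2 = min_r2,
              use_fluorescence = isTRUE(use_fluorescence),
              border_margin = border_margin,
              rng_seed = as.integer(rng_seed))
  pos <- c("shading_radius", "min_cell_area", "min_nucleus_area", "se_radius",
           "contour_spacing", "mu_gvf", "gvf_iters", "gvf_dt", "snake_iters",
           "snake_dt", "resample_every")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1L || cfg[[p]] <= 0)
      ps_error(sprintf("pipeline_config: '%s' must be a positive scalar", p),
               "pombeseg_validation_error")
  }
  if (cfg$gvf_dt > 1 / (4 * cfg$mu_gvf) + 1e-12)
    ps_error("pipeline_config: gvf_dt exceeds the stability bound 1/(4*mu_gvf)",
             "pombeseg_validation_error")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(pipeline_config, vals)
}

# resolved target contrast for a given field
target_contrast_for <- function(config, field) {
  if (!is.null(config$target_contrast)) return(config$target_contrast)
  config$target_contrast_frac * field$dynamic_range
}
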