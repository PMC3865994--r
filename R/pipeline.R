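#' Run the full segmentation pipeline on one field
#'
#' Stages: region detection (shading correction, background and nucleus
#' masks, mu_N / mu_B) -> focus-gradient and contrast correction -> pixel
#' classification, smoothing and ambiguity resolution -> initial contours,
#' GVF field and snake evolution -> feature extraction and contour
#' validation. Degenerate-histogram conditions downgrade to warnings with
#' the documented fallbacks (skip correction, mu_N = mu_B).
#'
#' @param field a [field_images()].
#' @param config a [pipeline_config()].
#' @param model a `validation_model`, or `NULL` to skip validation (all
#'   contours are then marked `"unvalidated"` and accepted, with a warning).
#' @return object of class `pipeline_result`: `records` (accepted cell
#'   records re-indexed 1..N, matching `label_mask`), `rejected`,
#'   `all_contours`, `label_mask`, `label_mask_all` (before validation),
#'   `cmap`, `corrected`, `regions`, and `report` (a run report with
#'   per-stage timings, counts, the focus decision and the fitted plane).
#' @export
run_pipeline <- function(field, config = pipeline_config(), model = NULL) {
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, stage) {
    timings[stage] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tic()
  regions <- detect_regions(field, config)
  toc(t0, "preprocess")

  t0 <- tic()
  fc <- correct_focus(regions, config,
                      delta = target_contrast_for(config, field))
  toc(t0, "focus_correct")

  t0 <- tic()
  mu_N_cls <- if (regions$fluorescence_used) fc$mu_N else NULL
  cmap <- classify_pixels(fc$image, regions$background, mu_N_cls, fc$mu_B)
  cmap <- smooth_classes(cmap, config$se_radius)
  cmap <- resolve_ambiguous(cmap)
  toc(t0, "pixel_classify")

  t0 <- tic()
  seg <- segment_cells(cmap, config)
  toc(t0, "gvf_snake")

  t0 <- tic()
  # Otsu thresholds are affine-equivariant, so the background-to-membrane
  # threshold gap is a contrast unit comparable across correction modes
  iscale <- fc$mu_B - cmap$t_membrane
  if (!is.finite(iscale) || iscale <= 0) iscale <- 1
  records <- lapply(seq_along(seg$contours), function(i) {
    f <- extract_features(seg$contours[[i]], fc$image, mu_B = fc$mu_B,
                          nucleus_centroids = regions$centroids,
                          border_margin = config$border_margin,
                          intensity_scale = iscale)
    new_cell_record(i, seg$contours[[i]], f)
  })
  if (!is.null(model)) {
    fl <- filter_contours(records, model)
    accepted <- fl$accepted
    rejected <- fl$rejected
  } else {
    if (length(records) > 0L)
      warning("no validation model supplied; contours are unvalidated")
    accepted <- records
    rejected <- list()
  }
  # re-index accepted records 1..N and rasterize them into the final mask
  for (i in seq_along(accepted)) accepted[[i]]$id <- i
  label_mask <- contours_label_mask(lapply(accepted, `[[`, "contour"),
                                    dim(field$trans))
  toc(t0, "validate")

  verdicts <- vapply(rejected, `[[`, "", "verdict")
  report <- list(
    timings = timings,
    counts = list(nuclei = nrow(regions$centroids),
                  initial_contours = length(seg$contours),
                  final_contours = length(records),
                  accepted = length(accepted),
                  rejected = length(rejected),
                  rejected_by_verdict = table(factor(verdicts,
                    levels = c("partial", "merged", "artifact")))),
    focus = list(complemented = fc$complemented, adjusted = fc$adjusted,
                 plane = fc$plane, mu_N = fc$mu_N, mu_B = fc$mu_B,
                 delta = fc$delta,
                 fluorescence_used = regions$fluorescence_used),
    config = unclass(config))
  structure(list(records = accepted, rejected = rejected,
                 all_contours = seg$contours,
                 label_mask = label_mask,
                 label_mask_all = seg$label_mask,
                 cmap = cmap, corrected = fc$image, regions = regions,
                 report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  co <- x$report$counts
  cat(sprintf("<pipeline_result> %d nuclei, %d contours -> %d accepted, %d rejected\n",
              co$nuclei, co$final_contours, co$accepted, co$rejected))
  invisible(x)
}

#' Compare a predicted label mask with a ground-truth instance mask
#'
#' Matches every predicted label with the truth cell it overlaps most and
#' scores: a truth cell is detected when some predicted label reaches at
#' least `iou_match` intersection-over-union with it; a predicted label is
#' correct under the same criterion. Dice coefficients are reported for
#' detected cells. Truth cells listed in `exclude_ids` (typically
#' border-truncated cells) are excluded from recall but still count as
#' legitimate matches for precision.
#'
#' @param pred integer predicted label mask.
#' @param truth integer ground-truth instance mask.
#' @param iou_match IoU threshold for a correct match (default 0.5).
#' @param dice_segmented Dice threshold above which a truth cell counts as
#'   well-segmented.
#' @param exclude_ids truth cell ids excluded from recall; contours matching
#'   only excluded cells count as incorrect (a truncated boundary cell is
#'   not a validly segmented cell).
#' @return list: `recall`, `precision`, `mean_dice` (over detected cells),
#'   `pct_segmented` (fraction of evaluated truth cells with best Dice at
#'   least `dice_segmented`; missed cells count against), `n_truth`,
#'   `n_pred`, `detected` (logical per evaluated truth cell), `dice` (per
#'   detected cell).
#' @export
evaluate_segmentation <- function(pred, truth, iou_match = 0.5,
                                  dice_segmented = 0.85,
                                  exclude_ids = integer()) {
  tl <- sort(unique(truth[truth > 0L]))
  pl <- sort(unique(pred[pred > 0L]))
  eval_ids <- setdiff(tl, exclude_ids)
  if (length(pl) == 0L) {
    return(list(recall = 0, precision = NA_real_, mean_dice = NA_real_,
                pct_segmented = 0,
                n_truth = length(eval_ids), n_pred = 0L,
                detected = setNames(rep(FALSE, length(eval_ids)), eval_ids),
                dice = numeric(0)))
  }
  sel <- truth > 0L | pred > 0L
  ov <- table(factor(truth[sel], levels = c(0L, tl)),
              factor(pred[sel], levels = c(0L, pl)))
  tsz <- tabulate(truth[truth > 0L], nbins = max(tl))
  psz <- tabulate(pred[pred > 0L], nbins = max(pl))
  iou <- matrix(0, length(tl), length(pl), dimnames = list(tl, pl))
  dice <- iou
  for (i in seq_along(tl)) for (j in seq_along(pl)) {
    inter <- ov[i + 1L, j + 1L]
    un <- tsz[tl[i]] + psz[pl[j]] - inter
    iou[i, j] <- if (un > 0) inter / un else 0
    dice[i, j] <- if (tsz[tl[i]] + psz[pl[j]] > 0)
      2 * inter / (tsz[tl[i]] + psz[pl[j]]) else 0
  }
  ev_rows <- as.character(eval_ids)
  det <- apply(iou[ev_rows, , drop = FALSE], 1, function(r) any(r >= iou_match))
  correct <- apply(iou[ev_rows, , drop = FALSE], 2, function(cc) any(cc >= iou_match))
  best_dice <- apply(dice[ev_rows, , drop = FALSE], 1, max)
  dice_det <- best_dice[det]
  list(recall = if (length(det)) mean(det) else NA_real_,
       precision = if (length(correct)) mean(correct) else NA_real_,
       mean_dice = if (length(dice_det)) mean(dice_det) else NA_real_,
       pct_segmented = if (length(best_dice)) mean(best_dice >= dice_segmented)
                       else NA_real_,
       n_truth = length(eval_ids), n_pred = length(pl),
       detected = det, dice = dice_det)
}
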