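# Labeled training contours for the validators. No manually labeled corpus
# ships with the package, so labels come from synthetic-scene ground truth: the
# segmentation chain is run on generated scenes and each produced contour is
# labeled by matching it against the truth instance masks; deliberately
# truncated, merged and background contours are constructed from the truth
# geometry and refined for a few snake iterations so their local intensity
# statistics match what the pipeline produces at application time.

# closed outline of a (possibly truncated) rod: axis p0->p1, radius R;
# cap0/cap1 select round cap or flat cut at each end
rod_polygon <- function(p0, p1, R, cap0 = TRUE, cap1 = TRUE, arc_n = 12L) {
  th <- atan2(p1[2] - p0[2], p1[1] - p0[1])
  end_pts <- function(p, from, to, cap) {
    if (cap) {
      a <- seq(from, to, length.out = arc_n)
      cbind(p[1] + R * cos(a), p[2] + R * sin(a))
    } else {
      a <- c(from, to)
      cbind(p[1] + R * cos(a), p[2] + R * sin(a))
    }
  }
  rbind(end_pts(p1, th - pi / 2, th + pi / 2, cap1),
        end_pts(p0, th + pi / 2, th + 3 * pi / 2, cap0))
}

clip_polygon_frame <- function(v, height, width) {
  v[, 1] <- pmin(pmax(v[, 1], 0), width - 1)
  v[, 2] <- pmin(pmax(v[, 2], 0), height - 1)
  v
}

#' Label segmentation contours against ground-truth instances
#'
#' A contour is `merged` when it covers at least half of two or more truth
#' cells, `valid` when it matches a non-border truth cell with IoU at least
#' `iou_valid`, `partial` when it matches a border-truncated cell or
#' overlaps a cell too weakly for a valid match, and `artifact` when it
#' overlaps no cell appreciably.
#'
#' @param contours list of contour matrices.
#' @param truth integer truth instance mask.
#' @param border_ids truth ids of border-truncated cells.
#' @param iou_valid IoU threshold for a valid match.
#' @return character vector of verdicts, one per contour.
#' @export
label_contours_by_truth <- function(contours, truth, border_ids = integer(),
                                    iou_valid = 0.6) {
  tsz <- tabulate(truth[truth > 0L], nbins = max(truth, 1L))
  vapply(contours, function(v) {
    pm <- polygon_mask(as.matrix(v[, 1:2]), nrow(truth), ncol(truth))
    a <- sum(pm)
    if (a == 0L) return("artifact")
    tv <- truth[pm]
    ids <- sort(unique(tv[tv > 0L]))
    if (length(ids) == 0L) return("artifact")
    inter <- vapply(ids, function(i) sum(tv == i), 0L)
    cover <- inter / tsz[ids]
    iou <- inter / (tsz[ids] + a - inter)
    if (sum(cover >= 0.5) >= 2L) return("merged")
    best <- which.max(iou)
    if (iou[best] >= iou_valid)
      return(if (ids[best] %in% border_ids) "partial" else "valid")
    if (max(cover) >= 0.2 || max(iou) >= 0.2) return("partial")
    "artifact"
  }, "")
}

#' Build a labeled feature set for validator training from synthetic scenes
#'
#' Generates preset scenes, runs the segmentation chain (without
#' validation), labels the produced contours against ground truth, and adds
#' constructed error contours: truncated rods (partial), convex hulls of
#' nearby cell pairs (merged) and background blobs (artifact), each refined
#' for `refine_iters` snake iterations under the scene's GVF field.
#'
#' @param seed RNG seed (scenes, truncation points, sampling).
#' @param presets preset names cycled over the scenes.
#' @param n_scenes number of scenes.
#' @param config a [pipeline_config()].
#' @param refine_iters snake iterations applied to constructed contours.
#' @return data.frame: columns of [feature_names()] plus `verdict`.
#' @export
make_training_set <- function(seed = 1L,
                              presets = c("wildtype", "cdc", "mixed",
                                          "septating", "wildtype_gradient"),
                              n_scenes = 5L,
                              config = pipeline_config(),
                              refine_iters = 40L) {
  rows <- list()
  for (si in seq_len(n_scenes)) {
    preset <- presets[(si - 1L) %% length(presets) + 1L]
    scene <- generate_scene(scene_preset(preset, seed = seed + 1000L * si))
    res <- suppressWarnings(run_pipeline(scene$field, config, model = NULL))
    img <- res$corrected
    h <- nrow(img); w <- ncol(img)
    cells <- scene$truth$cells
    mu_B <- res$report$focus$mu_B
    ctr <- res$regions$centroids
    gvf <- compute_gvf(membrane_edge_map(res$cmap), mu = config$mu_gvf,
                       n_iter = config$gvf_iters, dt = config$gvf_dt)
    refine <- function(v) evolve_snake(v, gvf, lambda1 = config$lambda1,
                                       lambda2 = config$lambda2,
                                       alpha = config$alpha, beta = config$beta,
                                       n_iter = refine_iters,
                                       dt = config$snake_dt,
                                       resample_every = config$resample_every,
                                       spacing = config$contour_spacing)
    iscale <- mu_B - res$cmap$t_membrane
    if (!is.finite(iscale) || iscale <= 0) iscale <- 1
    feats <- function(v) extract_features(v, img, mu_B = mu_B,
                                          nucleus_centroids = ctr,
                                          border_margin = config$border_margin,
                                          intensity_scale = iscale)
    add <- function(v, verdict) {
      f <- feats(v)
      if (!isTRUE(attr(f, "degenerate")))
        rows[[length(rows) + 1L]] <<- c(as.list(f), list(verdict = verdict))
    }

    # pipeline contours, labeled by truth
    verd <- label_contours_by_truth(res$all_contours, scene$truth$instance,
                                    cells$id[cells$border])
    for (i in seq_along(res$all_contours)) add(res$all_contours[[i]], verd[i])

    with_local_seed(seed + si, {
      # truncated rods (partial), refined under the field
      donors <- which(!cells$border)
      for (i in donors) {
        tt <- runif(1, 0.3, 0.65)
        p0 <- c(cells$x0[i], cells$y0[i]); p1 <- c(cells$x1[i], cells$y1[i])
        pc <- p0 + tt * (p1 - p0)
        vtr <- clip_polygon_frame(rod_polygon(p0, pc, cells$R[i], cap1 = FALSE),
                                  h, w)
        add(refine(resample_closed(vtr, spacing = config$contour_spacing)),
            "partial")
      }
      # merged: refined hulls of nearby cell pairs
      if (nrow(cells) >= 2L) {
        dmat <- as.matrix(stats::dist(cells[, c("cx", "cy")]))
        diag(dmat) <- Inf
        prs <- which(dmat < 90, arr.ind = TRUE)
        prs <- prs[prs[, 1] < prs[, 2], , drop = FALSE]
        if (nrow(prs) > 12L) prs <- prs[sample(nrow(prs), 12L), , drop = FALSE]
        for (pi in seq_len(nrow(prs))) {
          i <- prs[pi, 1]; j <- prs[pi, 2]
          vv <- rbind(rod_polygon(c(cells$x0[i], cells$y0[i]),
                                  c(cells$x1[i], cells$y1[i]), cells$R[i]),
                      rod_polygon(c(cells$x0[j], cells$y0[j]),
                                  c(cells$x1[j], cells$y1[j]), cells$R[j]))
          hv <- clip_polygon_frame(vv[grDevices::chull(vv), , drop = FALSE], h, w)
          add(refine(resample_closed(hv, spacing = config$contour_spacing)),
              "merged")
        }
      }
      # artifacts: refined wobbly blobs on background
      bg <- which(scene$truth$instance == 0L, arr.ind = TRUE)
      for (k in seq_len(12L)) {
        p <- bg[sample(nrow(bg), 1L), ]
        cx <- p[2] - 1; cy <- p[1] - 1
        r <- runif(1, 3.5, 9)
        a <- seq(0, 2 * pi, length.out = 17L)[-17L]
        rr <- r * (1 + runif(length(a), -0.25, 0.25))
        v <- clip_polygon_frame(cbind(cx + rr * cos(a), cy + rr * sin(a)), h, w)
        add(refine(resample_closed(v, spacing = config$contour_spacing)),
            "artifact")
      }
      NULL
    })
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(df) <- NULL
  df
}
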