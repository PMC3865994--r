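#' Read the channels of one field of view
#'
#' Loads a transmitted-illumination TIFF plus optional registered
#' fluorescence TIFFs into a [field_images()] object. Single-plane grayscale
#' 8-bit, 16-bit or float TIFFs are supported; integer images are kept on
#' their native intensity scale (0..255 / 0..65535) but stored as double.
#'
#' @param trans_path path to the bright-field TIFF.
#' @param fluor_paths character vector (0..2 paths) of fluorescence TIFFs.
#' @return a `field_images` object; `dynamic_range` is set from the on-disk
#'   bit depth (255, 65535, or the observed range for float data).
#' @export
read_field <- function(trans_path, fluor_paths = character()) {
  tr <- read_gray_tiff(trans_path)
  fl <- lapply(fluor_paths, function(p) read_gray_tiff(p)$img)
  for (i in seq_along(fl)) {
    if (!identical(dim(fl[[i]]), dim(tr$img)))
      ps_error(sprintf(
        "channel shape mismatch: trans '%s' is %dx%d but fluorescence '%s' is %dx%d",
        trans_path, nrow(tr$img), ncol(tr$img),
        fluor_paths[i], nrow(fl[[i]]), ncol(fl[[i]])),
        "pombeseg_validation_error")
  }
  field_images(tr$img, fl, dynamic_range = tr$dynamic_range)
}

read_gray_tiff <- function(path) {
  if (!file.exists(path))
    ps_error(sprintf("cannot read '%s': no such file", path), "pombeseg_io_error")
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) ps_error(
                    sprintf("cannot decode '%s' as TIFF: %s", path, conditionMessage(e)),
                    "pombeseg_io_error"))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else ps_error(sprintf("'%s' is not single-plane grayscale", path),
                  "pombeseg_io_error")
  }
  dr <- if (is.integer(img)) {
    if (max(img) > 255L) 65535 else 255
  } else max(diff(range(img)), 1)
  storage.mode(img) <- "double"
  list(img = img, dynamic_range = dr)
}

#' Write segmentation outputs for one field
#'
#' Writes `labels.tif` (16-bit instance label mask, 0 = background, k = cell
#' k), `cells.json` (one record per contour: id, vertices, verdict,
#' features) and `features.csv` (per-cell feature table).
#'
#' @param records list of `cell_record` objects indexed 1..N.
#' @param label_mask integer matrix with values 0..N.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_results <- function(records, label_mask, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) ps_error(sprintf("cannot create output directory '%s'", out_dir),
                      "pombeseg_io_error")
  }
  if (file.access(out_dir, 2L) != 0L)
    ps_error(sprintf("output directory '%s' is not writable", out_dir),
             "pombeseg_io_error")
  mask_path <- file.path(out_dir, "labels.tif")
  json_path <- file.path(out_dir, "cells.json")
  csv_path <- file.path(out_dir, "features.csv")
  write_label_mask(label_mask, mask_path)
  recs <- lapply(records, function(r) {
    list(id = r$id,
         verdict = r$verdict,
         vertices = unname(round(r$contour[, 1:2, drop = FALSE], 3)),
         features = as.list(r$features))
  })
  jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA)
  ft <- feature_table(records)
  utils::write.csv(ft, csv_path, row.names = FALSE)
  invisible(c(mask = mask_path, cells = json_path, features = csv_path))
}

#' @rdname write_results
#' @param path TIFF path for the label mask.
#' @export
write_label_mask <- function(label_mask, path) {
  m <- label_mask
  storage.mode(m) <- "double"
  if (max(m) > 65535) ps_error("more than 65535 labels", "pombeseg_io_error")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_results
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Per-cell feature table
#'
#' @param records list of `cell_record`s.
#' @return a data.frame with id, verdict and one column per feature.
#' @export
feature_table <- function(records) {
  if (length(records) == 0L) {
    cols <- c("id", "verdict", feature_names())
    ft <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    ft$verdict <- character(0)
    return(ft)
  }
  ft <- do.call(rbind, lapply(records, function(r) {
    as.data.frame(c(list(id = r$id, verdict = r$verdict), as.list(r$features)))
  }))
  rownames(ft) <- NULL
  ft
}
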