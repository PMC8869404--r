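#' Single-cell binary mask
#'
#' Wraps a binary 2D raster with its spatial calibration. The default
#' calibration of 0.31 micrometres per pixel corresponds to a 40x
#' confocal field of 624.39 x 624.39 um at 1024 x 1024 px, the
#' acquisition setting the morphometry defaults are tuned for.
#'
#' @param mask logical or numeric matrix; positive/TRUE = foreground.
#' @param calibration micrometres per pixel (> 0).
#' @param check_single_component validate that the foreground is one
#'   8-connected component (required by per-cell feature operations).
#' @return logical matrix of class `cell_mask` with a `calibration`
#'   attribute.
#' @export
cell_mask <- function(mask, calibration = 0.31, check_single_component = FALSE) {
  gp_assert(is_scalar_num(calibration) && calibration > 0, "calibration must be > 0")
  m <- as_binary_matrix(mask)
  if (check_single_component) {
    nc <- n_components(m)
    gp_assert(nc == 1L, sprintf("mask must have exactly one component, found %d", nc))
  }
  structure(m, calibration = calibration, class = c("cell_mask", class(m)))
}

mask_calibration <- function(mask, calibration = NULL) {
  calibration %||% attr(mask, "calibration") %||% 0.31
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf(
    "<cell_mask> %d x %d px, %d foreground px, %.3g um/px\n",
    nrow(x), ncol(x), sum(x), attr(x, "calibration")
  ))
  invisible(x)
}

#' Threshold and clean a grayscale image into a cell mask
#'
#' Binarises a single-channel image (Otsu or fixed threshold), removes
#' objects smaller than `min_object_px`, and optionally keeps only the
#' largest connected component. Already-binary inputs pass through
#' unchanged (idempotent).
#'
#' @param raster numeric matrix (any range; rescaled to 0-1 internally).
#' @param threshold_method `"otsu"` or a numeric threshold on the 0-1
#'   scale.
#' @param min_object_px drop 8-connected components smaller than this.
#' @param single_cell keep only the largest component.
#' @param calibration micrometres per pixel for the resulting mask.
#' @return a [cell_mask()].
#' @export
preprocess_mask <- function(raster, threshold_method = "otsu",
                            min_object_px = 10L, single_cell = FALSE,
                            calibration = 0.31) {
  gp_assert(is.matrix(raster) && is.numeric(raster), "raster must be a numeric matrix")
  vals <- unique(as.vector(raster))
  if (all(vals %in% c(0, 1))) {
    bin <- raster > 0
  } else {
    rng <- range(raster, finite = TRUE)
    x <- if (diff(rng) > 0) (raster - rng[1]) / diff(rng) else raster * 0
    thr <- if (identical(threshold_method, "otsu")) {
      otsu_threshold(x)
    } else {
      gp_assert(is_scalar_num(threshold_method), "threshold_method must be 'otsu' or a number")
      threshold_method
    }
    bin <- x > thr
  }
  lab <- label_components(bin)
  if (max(lab) > 0L && min_object_px > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_px)
    bin <- matrix(lab %in% keep, nrow(lab), ncol(lab)) & bin
    lab <- label_components(bin)
  }
  if (single_cell && max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    bin <- lab == which.max(sizes)
  }
  if (!any(bin)) {
    gp_stop("no foreground left after thresholding and cleaning", "gp_empty_mask_error")
  }
  cell_mask(bin, calibration = calibration)
}
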