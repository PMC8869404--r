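#' Extract the 25-feature table from a collection of cell masks
#'
#' Runs [skeletonize()] + [skeleton_feature_vector()] and
#' [shape_feature_vector()] on every mask and binds one row per cell,
#' prefixed by the supplied metadata columns. Cells whose extraction
#' fails (empty mask, multiple components, degenerate hull, ...) are
#' skipped; the reasons are returned in the `skipped` attribute and
#' reported via a message.
#'
#' @param masks list of [cell_mask()] objects or binary matrices.
#' @param metadata optional data.frame with one row per mask (e.g.
#'   genotype, region, animal); recycled column `cell_id` is added when
#'   absent.
#' @param calibration micrometres per pixel used for all masks lacking
#'   their own calibration.
#' @return data.frame: metadata columns followed by the 25 features in
#'   the order of [morpho_feature_names()]; attribute `skipped` is a
#'   data.frame of failed cells and reasons.
#' @export
extract_feature_table <- function(masks, metadata = NULL, calibration = 0.31) {
  gp_assert(is.list(masks) && length(masks) >= 1L, "masks must be a non-empty list")
  if (!is.null(metadata)) {
    gp_assert(is.data.frame(metadata) && nrow(metadata) == length(masks),
              "metadata must have one row per mask")
  } else {
    metadata <- data.frame(row.names = seq_along(masks))
  }
  if (!"cell_id" %in% names(metadata)) {
    metadata$cell_id <- sprintf("cell_%04d", seq_along(masks))
  }

  rows <- vector("list", length(masks))
  skipped <- list()
  for (i in seq_along(masks)) {
    res <- tryCatch({
      calib <- mask_calibration(masks[[i]], if (is.null(attr(masks[[i]], "calibration"))) calibration else NULL)
      sk <- skeletonize(masks[[i]], calibration = calib)
      c(skeleton_feature_vector(sk),
        shape_feature_vector(masks[[i]], calibration = calib))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        cell_id = metadata$cell_id[i], reason = conditionMessage(res),
        stringsAsFactors = FALSE
      )
    } else {
      rows[[i]] <- res
    }
  }
  ok <- !vapply(rows, is.null, logical(1))
  feats <- do.call(rbind, rows[ok])
  out <- cbind(metadata[ok, , drop = FALSE], as.data.frame(feats))
  rownames(out) <- NULL
  skipped_df <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(cell_id = character(0), reason = character(0))
  if (nrow(skipped_df) > 0L) {
    message(sprintf("extract_feature_table: skipped %d cell(s): %s",
                    nrow(skipped_df),
                    paste(skipped_df$cell_id, collapse = ", ")))
  }
  attr(out, "skipped") <- skipped_df
  out
}
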