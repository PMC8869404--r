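#' Transformation index of a cell mask
#'
#' `TI = perimeter^2 / (4 pi area)`, the reciprocal of circularity: 1
#' for a perfect disc, increasing with ramification. Used to grade the
#' ramification status of cultured microglia.
#'
#' @inheritParams shape_feature_vector
#' @return dimensionless transformation index.
#' @export
transformation_index <- function(mask, perimeter_method = "chain") {
  m <- as_binary_matrix(mask)
  area <- sum(m)
  gp_assert(area > 0, "mask has zero area", "gp_empty_mask_error")
  p <- perimeter_px(m, method = perimeter_method)
  p^2 / (4 * pi * area)
}

#' Phagocytic efficiency from bead-ingestion bins
#'
#' Weighted ingestion score: cells are binned by the number of
#' fluorescent beads ingested (1, 2, 3, 4, 5, more than 5) and the
#' efficiency is `100 * sum(w_i * n_i) / N` with default weights
#' 1..6 (the open ">5" bin contributes weight 6). Weights are exposed
#' because different bead-uptake scoring schemes grade the top bin
#' differently.
#'
#' @param bin_counts numeric vector of length 6: cells having ingested
#'   1, 2, 3, 4, 5, >5 beads.
#' @param total_cells total number of cells scored (>= sum of bins).
#' @param weights per-bin weights, default `c(1, 2, 3, 4, 5, 6)`.
#' @return efficiency in percent (can exceed 100 when cells ingest
#'   multiple beads).
#' @export
#' @examples
#' phagocytic_efficiency(c(1, 1, 0, 0, 1, 1), total_cells = 4) # 350
phagocytic_efficiency <- function(bin_counts, total_cells,
                                  weights = c(1, 2, 3, 4, 5, 6)) {
  gp_assert(length(bin_counts) == length(weights),
            "bin_counts and weights must have equal length")
  gp_assert(all(bin_counts >= 0), "bin counts must be non-negative")
  gp_assert(is_scalar_num(total_cells) && total_cells > 0,
            "total_cells must be a positive number")
  gp_assert(sum(bin_counts) <= total_cells,
            "bin counts sum exceeds the total cell count")
  100 * sum(weights * bin_counts) / total_cells
}

#' Iba-1-positive cell density per area and per volume
#'
#' Normalises a cell count first to the imaged area and then to the
#' imaged volume (area times Z-stack depth), mirroring how tissue
#' microglial densities are reported for confocal stacks.
#'
#' @param count number of cells (>= 0).
#' @param image_area area of the field in um^2 (for the default 40x
#'   field, 624.39 x 624.39 um).
#' @param stack_depth imaged depth in um (> 0).
#' @return list with `count`, `image_area_um2`, `stack_depth_um`,
#'   `per_area` (cells/um^2) and `per_volume` (cells/um^3).
#' @export
cell_density <- function(count, image_area = 624.39^2, stack_depth = 40) {
  gp_assert(is_scalar_num(count) && count >= 0, "count must be >= 0")
  gp_assert(is_scalar_num(image_area) && image_area > 0, "image_area must be > 0")
  gp_assert(is_scalar_num(stack_depth) && stack_depth > 0, "stack_depth must be > 0")
  per_area <- count / image_area
  list(
    count = count, image_area_um2 = image_area, stack_depth_um = stack_depth,
    per_area = per_area, per_volume = per_area / stack_depth
  )
}
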