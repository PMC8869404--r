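#' Canonical morphometric feature names
#'
#' The profiling pipeline describes every cell with 25 named features:
#' 10 derived from the skeletonised cell (ramification) and 15 from the
#' full mask (shape, size, surface and texture). All downstream stages
#' (feature tables, significance screening, clustering, boosted trees)
#' use these names. Lengths are in micrometres, areas in square
#' micrometres; circularities, density, lacunarity, fractal dimension and
#' ratios are dimensionless.
#'
#' @return Character vector of feature names.
#' @export
#' @examples
#' length(morpho_feature_names()) # 25
morpho_feature_names <- function() {
  c(skeleton_feature_names(), shape_feature_names())
}

#' @rdname morpho_feature_names
#' @export
skeleton_feature_names <- function() {
  c(
    "n_branches", "n_junction_voxels", "n_endpoint_voxels", "n_slab_voxels",
    "avg_branch_length", "max_branch_length", "total_branch_length",
    "euclidean_distance", "n_triple_points", "n_quadruple_points"
  )
}

#' @rdname morpho_feature_names
#' @export
shape_feature_names <- function() {
  c(
    "fractal_dimension", "lacunarity", "density", "span_ratio",
    "convex_hull_area", "convex_hull_perimeter", "convex_hull_circularity",
    "bounding_circle_diameter", "mean_radius", "max_span_across_hull",
    "max_min_radii_ratio", "max_radius",
    "cell_area", "cell_perimeter", "cell_circularity"
  )
}

#' Features separating spinal-cord microglia of the two genotypes
#'
#' In the cervical spinal cord, 14 of the 25 features differ between
#' wild-type and MJD-model microglia: 4 skeleton features (all decreased
#' in the disease model) and 10 shape features (all decreased except
#' density and cell circularity, which increase as cells de-ramify and
#' compact). The signs returned here drive the default effect directions
#' of the feature-table simulator.
#'
#' @param what `"all"`, `"skeleton"` or `"shape"`.
#' @return Named numeric vector: +1 for features increased in the disease
#'   phenotype, -1 for decreased; names are the affected features.
#' @export
significant_feature_directions <- function(what = c("all", "skeleton", "shape")) {
  what <- match.arg(what)
  skel <- c(
    n_slab_voxels = -1, max_branch_length = -1,
    total_branch_length = -1, euclidean_distance = -1
  )
  shape <- c(
    lacunarity = -1, convex_hull_area = -1, convex_hull_perimeter = -1,
    bounding_circle_diameter = -1, mean_radius = -1,
    max_span_across_hull = -1, cell_area = -1, cell_perimeter = -1,
    density = +1, cell_circularity = +1
  )
  switch(what, all = c(skel, shape), skeleton = skel, shape = shape)
}

#' Per-region, per-genotype cell counts of the morphology study design
#'
#' Numbers of single microglial cells analysed per brain region (cervical
#' spinal cord, deep cerebellar nuclei, pontine nuclei) and genotype in
#' the study design this pipeline reproduces. Stored as a plain-text
#' table under `inst/extdata/study_cell_counts.tsv`.
#'
#' @return data.frame with columns `region`, `genotype`, `n_cells`.
#' @export
#' @examples
#' sum(study_cell_counts()$n_cells) # 1825
study_cell_counts <- function() {
  path <- system.file("extdata", "study_cell_counts.tsv", package = "gliaProfiler")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
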