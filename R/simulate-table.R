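#' Baseline feature means and dispersions of the morphology simulator
#'
#' Plausible wild-type spinal-cord microglia values for the 25
#' features (lengths in um, areas in um^2), with standard deviations
#' of roughly a quarter of each mean. These anchor the multivariate
#' normal surrogate in a realistic region of feature space; effect
#' sizes are always expressed in SD units, so the absolute scale does
#' not affect the downstream statistics.
#'
#' @return list with numeric vectors `mean` and `sd` (length 25).
#' @export
morpho_feature_baseline <- function() {
  mean <- c(
    n_branches = 12, n_junction_voxels = 18, n_endpoint_voxels = 15,
    n_slab_voxels = 180, avg_branch_length = 6, max_branch_length = 25,
    total_branch_length = 75, euclidean_distance = 18,
    n_triple_points = 5, n_quadruple_points = 1,
    fractal_dimension = 1.45, lacunarity = 0.35, density = 0.35,
    span_ratio = 1.3, convex_hull_area = 1200, convex_hull_perimeter = 130,
    convex_hull_circularity = 0.85, bounding_circle_diameter = 46,
    mean_radius = 18, max_span_across_hull = 44, max_min_radii_ratio = 1.8,
    max_radius = 24, cell_area = 420, cell_perimeter = 210,
    cell_circularity = 0.12
  )
  list(mean = mean[morpho_feature_names()], sd = 0.25 * mean[morpho_feature_names()])
}

#' Simulate a two-genotype morphology feature table
#'
#' Fast multivariate-normal surrogate of the mask-level pipeline: draws
#' 25-feature vectors for two groups, shifting a chosen subset of
#' features in the second (disease) group by a given effect in SD
#' units. Default shifted features and signs follow the spinal-cord
#' phenotype: 14 features affected, all decreased except density and
#' cell circularity, which increase.
#'
#' @param n_wt,n_mjd cells per genotype (>= 2; defaults 310 and 389,
#'   the cervical spinal cord design).
#' @param effect_size shift magnitude in SD units applied to the
#'   shifted features (default 3).
#' @param shifted named numeric vector of effect signs/multipliers per
#'   feature (subset of the 25 names); default
#'   [significant_feature_directions()]. The realised shift is
#'   `effect_size * shifted[f] * sd[f]`.
#' @param mean,sd baseline feature means and SDs; default
#'   [morpho_feature_baseline()].
#' @param covariance optional full 25x25 covariance matrix (symmetric
#'   positive semi-definite); default `diag(sd^2)`.
#' @param labels genotype labels (control first).
#' @param seed integer seed.
#' @return list with `table` (data.frame: `cell_id`, `genotype`, then
#'   the 25 features) and `truth` (data.frame `cell_id`, `genotype`).
#' @export
simulate_morphology_table <- function(n_wt = 310L, n_mjd = 389L,
                                      effect_size = 3,
                                      shifted = significant_feature_directions(),
                                      mean = NULL, sd = NULL,
                                      covariance = NULL,
                                      labels = c("WT", "MJD"),
                                      seed = 1L) {
  gp_assert(n_wt >= 2L && n_mjd >= 2L, "each group needs n >= 2")
  feats <- morpho_feature_names()
  base <- morpho_feature_baseline()
  mean <- mean %||% base$mean
  sd <- sd %||% base$sd
  gp_assert(length(mean) == 25L && length(sd) == 25L,
            "mean and sd must cover the 25 features")
  if (length(shifted) > 0) {
    gp_assert(all(names(shifted) %in% feats),
              sprintf("unknown shifted feature(s): %s",
                      paste(setdiff(names(shifted), feats), collapse = ", ")))
  }
  if (is.null(covariance)) {
    covariance <- diag(sd^2)
    dimnames(covariance) <- list(feats, feats)
  } else {
    gp_assert(is.matrix(covariance) && all(dim(covariance) == 25L),
              "covariance must be 25 x 25")
    gp_assert(max(abs(covariance - t(covariance))) < 1e-8,
              "covariance must be symmetric")
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    gp_assert(min(ev) > -1e-8 * max(abs(ev)),
              "covariance must be positive semi-definite")
  }

  mu_wt <- setNames(as.numeric(mean), feats)
  mu_mjd <- mu_wt
  if (length(shifted) > 0) {
    mu_mjd[names(shifted)] <- mu_mjd[names(shifted)] +
      effect_size * shifted * sd[match(names(shifted), feats)]
  }

  draws <- with_seed(seed, {
    rbind(
      MASS::mvrnorm(n_wt, mu_wt, covariance),
      MASS::mvrnorm(n_mjd, mu_mjd, covariance)
    )
  })
  colnames(draws) <- feats
  genotype <- rep(labels, c(n_wt, n_mjd))
  tab <- data.frame(
    cell_id = sprintf("cell_%04d", seq_len(n_wt + n_mjd)),
    genotype = factor(genotype, levels = labels),
    draws,
    stringsAsFactors = FALSE
  )
  list(table = tab, truth = tab[, c("cell_id", "genotype")])
}
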