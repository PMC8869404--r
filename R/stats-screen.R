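#' Per-feature two-group significance screening
#'
#' Two-tailed unpaired Student's t-test for every feature column
#' between the two levels of `group_column`; features with `p < alpha`
#' are flagged as selected. Features constant in both groups are
#' reported with p = 1 and a warning.
#'
#' @param table data.frame containing `group_column` and the feature
#'   columns.
#' @param group_column name of the two-level grouping column.
#' @param features feature columns to test; default every column of
#'   [morpho_feature_names()] present in the table.
#' @param alpha selection level.
#' @param var_equal pooled-variance Student test (default TRUE,
#'   matching the classical unpaired t); FALSE gives Welch.
#' @return data.frame: `feature`, `mean_<level1>`, `mean_<level2>`,
#'   `p`, `selected`.
#' @export
feature_significance <- function(table, group_column = "genotype",
                                 features = NULL, alpha = 0.05,
                                 var_equal = TRUE) {
  gp_assert(group_column %in% names(table), "group column not found")
  g <- droplevels(as.factor(table[[group_column]]))
  gp_assert(nlevels(g) == 2L, "exactly two groups are required")
  gp_assert(all(table(g) >= 2L), "each group needs n >= 2")
  features <- features %||% intersect(morpho_feature_names(), names(table))
  gp_assert(length(features) >= 1L, "no feature columns found")

  lev <- levels(g)
  res <- lapply(features, function(f) {
    x1 <- table[[f]][g == lev[1]]; x2 <- table[[f]][g == lev[2]]
    if (sd(x1) == 0 && sd(x2) == 0) {
      warning(sprintf("feature '%s' is constant in both groups; p set to 1", f))
      p <- 1
    } else {
      p <- t.test(x1, x2, var.equal = var_equal)$p.value
    }
    data.frame(feature = f, m1 = mean(x1), m2 = mean(x2), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", lev)
  out$selected <- out$p < alpha
  attr(out, "alpha") <- alpha
  out
}

#' Principal component analysis of a feature table
#'
#' Eigen-decomposition of the (optionally standardised) feature
#' covariance via [stats::prcomp()], returning loadings, per-cell
#' scores and explained-variance fractions. Standardisation is the
#' default because the features span incommensurate units (um, um^2,
#' dimensionless ratios).
#'
#' @param table data.frame or matrix of features (rows = cells).
#' @param features columns to use (default: all 25 present).
#' @param standardize z-score each feature first.
#' @return list of class `pca_result`: `loadings`, `scores`,
#'   `variance_fraction`, `cumulative_fraction`, `center`, `scale`.
#' @export
pca_project <- function(table, features = NULL, standardize = TRUE) {
  if (is.data.frame(table)) {
    features <- features %||% intersect(morpho_feature_names(), names(table))
    x <- as.matrix(table[, features, drop = FALSE])
  } else {
    x <- as.matrix(table)
    if (!is.null(features)) x <- x[, features, drop = FALSE]
  }
  gp_assert(ncol(x) >= 3L, "need at least 3 features")
  gp_assert(nrow(x) >= 4L, "need at least 4 rows")
  sds <- apply(x, 2, sd)
  scale_arg <- if (standardize) {
    # guard constant columns: prcomp(scale=TRUE) fails on zero variance
    ifelse(sds > 0, sds, 1)
  } else {
    FALSE
  }
  pc <- prcomp(x, center = TRUE, scale. = scale_arg)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      loadings = pc$rotation, scores = pc$x,
      variance_fraction = vf, cumulative_fraction = cumsum(vf),
      center = pc$center, scale = pc$scale
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3L, length(x$variance_fraction))
  cat(sprintf(
    "<pca_result> %d components; first %d explain %s (cumulative %.1f%%)\n",
    length(x$variance_fraction), k,
    paste(sprintf("%.1f%%", 100 * x$variance_fraction[1:k]), collapse = " + "),
    100 * x$cumulative_fraction[k]
  ))
  invisible(x)
}
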