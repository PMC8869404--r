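#' k-means fit with restarts and mean-squared-error summary
#'
#' Wraps [stats::kmeans()] (Lloyd/Hartigan-Wong with `nstart`
#' restarts), reporting the assignment, centroids and the within-
#' cluster mean squared error (total within-cluster sum of squares
#' divided by the number of rows).
#'
#' @param data numeric matrix or data.frame of features.
#' @param k number of clusters (`<=` number of rows).
#' @param n_restarts random restarts; best fit kept.
#' @param seed integer seed.
#' @param standardize z-score columns first (recommended for
#'   mixed-unit morphometric features).
#' @return list: `assignments`, `centroids`, `mse`, `totss`, `k`.
#' @export
kmeans_fit <- function(data, k, n_restarts = 10L, seed = 1L, standardize = FALSE) {
  x <- as.matrix(data)
  gp_assert(is.numeric(x), "data must be numeric")
  gp_assert(k >= 1L && k <= nrow(x),
            sprintf("k must be in [1, %d]", nrow(x)))
  if (standardize) x <- scale_safe(x)
  fit <- with_seed(seed, {
    if (k == 1L) {
      ctr <- matrix(colMeans(x), 1, ncol(x))
      list(cluster = rep(1L, nrow(x)), centers = ctr,
           tot.withinss = sum(sweep(x, 2, ctr[1, ])^2))
    } else if (k == nrow(x)) {
      # every point its own centroid
      list(cluster = seq_len(nrow(x)), centers = x, tot.withinss = 0)
    } else {
      kmeans(x, centers = k, nstart = n_restarts, iter.max = 50L)
    }
  })
  list(
    assignments = fit$cluster,
    centroids = fit$centers,
    mse = fit$tot.withinss / nrow(x),
    totss = sum(sweep(x, 2, colMeans(x))^2),
    k = k
  )
}

scale_safe <- function(x) {
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1
  scale(x, center = TRUE, scale = sds)
}

#' Choose the cluster number from a within-cluster MSE curve
#'
#' Applies an elbow rule to an MSE-versus-k curve. `"knee"` (default)
#' picks the k maximising the discrete second difference of the
#' log-MSE curve, `log MSE(k-1) - 2 log MSE(k) + log MSE(k+1)`, over
#' `2 <= k <= k_max - 1`: on the log scale a structureless
#' (geometrically decaying) curve is flat, so the rule responds to the
#' point where the *proportional* error drop collapses, which is scale-
#' free and locates elbows beyond k = 2. `"largest_drop"` picks the k
#' maximising `MSE(k-1) - MSE(k)`, which
#' for any convex decreasing curve is always k = 2 (the historical
#' reading of the elbow plot). When the relative drop at the chosen k
#' is small (`< drop_warn`), a low-confidence warning is attached: the
#' curve is compatible with a single cluster.
#'
#' @param mse numeric vector of MSE values for k = 1..k_max.
#' @param rule `"knee"` or `"largest_drop"`.
#' @param drop_warn relative-drop threshold for the low-confidence
#'   warning.
#' @return list of class `elbow_curve`: `k_values`, `mse`, `chosen_k`,
#'   `rule`, `low_confidence`.
#' @export
elbow_from_curve <- function(mse, rule = c("knee", "largest_drop"),
                             drop_warn = 0.2) {
  rule <- match.arg(rule)
  gp_assert(all(is.finite(mse)), "MSE curve contains non-finite values")
  k_max <- length(mse)
  gp_assert(k_max >= 3L, "need MSE for at least k = 1..3")
  chosen <- if (rule == "largest_drop") {
    which.max(mse[-k_max] - mse[-1]) + 1L
  } else {
    lm_ <- log(pmax(mse, max(mse) * 1e-12))
    ks <- 2:(k_max - 1L)
    sd2 <- lm_[ks - 1L] - 2 * lm_[ks] + lm_[ks + 1L]
    # a geometrically decaying curve is exactly flat here: no cluster
    # structure, fall back to the smallest k (the warning below fires)
    if (max(sd2) < 1e-8) ks[1] else ks[which.max(sd2)]
  }
  rel_drop <- (mse[chosen - 1L] - mse[chosen]) / max(mse[chosen - 1L], .Machine$double.eps)
  low_conf <- rel_drop < drop_warn
  if (low_conf) {
    warning(sprintf(
      "elbow at k = %d has a small relative drop (%.2f): cluster structure is weak",
      chosen, rel_drop
    ))
  }
  structure(
    list(k_values = seq_len(k_max), mse = mse, chosen_k = chosen,
         rule = rule, low_confidence = low_conf),
    class = "elbow_curve"
  )
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat(sprintf("<elbow_curve> k = 1..%d, chosen k = %d (%s rule%s)\n",
              length(x$k_values), x$chosen_k, x$rule,
              if (x$low_confidence) ", low confidence" else ""))
  invisible(x)
}

#' Elbow-method cluster-number selection
#'
#' Runs [kmeans_fit()] for k = 1..`k_max` and selects k with
#' [elbow_from_curve()].
#'
#' @inheritParams kmeans_fit
#' @param k_max largest k tried (default 12).
#' @param rule forwarded to [elbow_from_curve()].
#' @return an `elbow_curve` with an extra `fits` element (the per-k
#'   [kmeans_fit()] results).
#' @export
elbow_select_k <- function(data, k_max = 12L, rule = "knee",
                           n_restarts = 10L, seed = 1L, standardize = TRUE) {
  gp_assert(k_max >= 3L, "k_max must be >= 3")
  x <- as.matrix(data)
  if (standardize) x <- scale_safe(x)
  fits <- lapply(seq_len(k_max), function(k) {
    kmeans_fit(x, k, n_restarts = n_restarts, seed = seed + k)
  })
  curve <- elbow_from_curve(vapply(fits, `[[`, numeric(1), "mse"), rule = rule)
  curve$fits <- fits
  curve
}

#' Cluster-by-genotype composition
#'
#' Cross-tabulates cluster assignments against genotype labels and
#' reports within-cluster fractions.
#'
#' @param assignments integer/factor cluster ids.
#' @param labels genotype labels, same length.
#' @return list: `counts` (clusters x labels), `fractions` (row-
#'   normalised), `majority` (dominant label per cluster).
#' @export
cluster_composition <- function(assignments, labels) {
  gp_assert(length(assignments) == length(labels),
            "assignments and labels must have equal length")
  counts <- table(cluster = assignments, label = labels)
  fractions <- prop.table(counts, margin = 1)
  majority <- colnames(fractions)[apply(fractions, 1, which.max)]
  list(counts = counts, fractions = fractions,
       majority = setNames(majority, rownames(counts)))
}
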