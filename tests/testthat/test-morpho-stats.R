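test_that("feature screening flags planted shifts and handles degenerate input", {
  # identical groups: t = 0, p = 1
  df <- data.frame(genotype = rep(c("a", "b"), each = 4),
                   cell_area = rep(c(1, 2, 3, 4), 2),
                   cell_perimeter = rep(c(2, 4, 6, 8), 2))
  sig <- feature_significance(df)
  expect_true(all(sig$p > 0.999))

  # a 3-SD shift on one feature at n = 300/group is essentially certain
  set.seed(1)
  df2 <- data.frame(
    genotype = rep(c("WT", "MJD"), each = 300),
    cell_area = c(rnorm(300), rnorm(300, 3)),
    density = rnorm(600)
  )
  sig2 <- feature_significance(df2)
  expect_lt(sig2$p[sig2$feature == "cell_area"], 1e-6)
  expect_true(sig2$selected[sig2$feature == "cell_area"])

  # constant feature warns and reports p = 1
  df3 <- data.frame(genotype = rep(c("a", "b"), each = 3),
                    cell_area = rep(1, 6), density = rnorm(6))
  expect_warning(sig3 <- feature_significance(df3), "constant")
  expect_equal(sig3$p[sig3$feature == "cell_area"], 1)

  expect_error(feature_significance(data.frame(genotype = rep("a", 4),
                                               cell_area = rnorm(4))),
               "two groups")
})

test_that("PCA recovers exact low-rank structure and isotropy", {
  # points on a 2D plane embedded in 14 dims: 2 components explain 100%
  set.seed(2)
  basis <- qr.Q(qr(matrix(rnorm(14 * 2), 14)))
  x <- matrix(rnorm(200 * 2), 200) %*% t(basis)
  colnames(x) <- names(significant_feature_directions())
  p <- pca_project(x, standardize = FALSE)
  expect_equal(p$cumulative_fraction[2], 1, tolerance = 1e-9)
  expect_equal(tail(p$cumulative_fraction, 1), 1, tolerance = 1e-9)

  # isotropic Gaussian: every fraction ~ 1/14
  x2 <- matrix(rnorm(10000 * 14), 10000)
  colnames(x2) <- colnames(x)
  p2 <- pca_project(x2)
  expect_true(all(abs(p2$variance_fraction - 1 / 14) < 0.01))

  expect_error(pca_project(x2[1:3, ]), "at least 4 rows")
})

test_that("k-means closed forms hold at the k extremes", {
  set.seed(3)
  x <- matrix(rnorm(60 * 3), 60)
  f1 <- kmeans_fit(x, 1L)
  expect_equal(as.numeric(f1$centroids), colMeans(x), tolerance = 1e-12)
  expect_equal(f1$mse, sum(sweep(x, 2, colMeans(x))^2) / nrow(x), tolerance = 1e-12)

  fn <- kmeans_fit(x, nrow(x), n_restarts = 2L)
  expect_equal(fn$mse, 0, tolerance = 1e-9)

  # two well-separated blobs: perfect purity
  y <- rbind(matrix(rnorm(100 * 2), 100), matrix(rnorm(100 * 2, 10), 100))
  f2 <- kmeans_fit(y, 2L)
  purity <- max(table(f2$assignments[1:100]))
  expect_equal(unname(purity), 100)

  expect_error(kmeans_fit(x, 61L), "k must be")
})

test_that("elbow rules pick the planted cluster count", {
  # two separated blobs in 14D at the study's group sizes
  hits <- sapply(1:15, function(s) {
    sim <- simulate_morphology_table(seed = s)
    x <- sim$table[, names(significant_feature_directions())]
    c(
      suppressWarnings(elbow_select_k(x, rule = "knee", seed = s)$chosen_k),
      suppressWarnings(elbow_select_k(x, rule = "largest_drop", seed = s)$chosen_k)
    )
  })
  expect_gte(sum(hits[1, ] == 2L), 14L)
  expect_gte(sum(hits[2, ] == 2L), 14L)

  # four well-separated blobs: the knee rule finds k = 4
  hits4 <- sapply(1:10, function(s) {
    set.seed(s)
    centers <- matrix(c(0, 0, 12, 0, 0, 12, 12, 12), 4, 2, byrow = TRUE)
    x <- do.call(rbind, lapply(1:4, function(i) {
      sweep(matrix(rnorm(80 * 2), 80), 2, centers[i, ], "+")
    }))
    suppressWarnings(elbow_select_k(x, rule = "knee", seed = s,
                                    standardize = FALSE)$chosen_k)
  })
  expect_gte(sum(hits4 == 4L), 9L)

  # a strictly geometric curve carries no cluster signal: both rules
  # return 2 with a low-confidence warning
  geom <- 10 * 0.93^(0:11)
  expect_warning(e1 <- elbow_from_curve(geom, rule = "knee"), "weak")
  expect_warning(e2 <- elbow_from_curve(geom, rule = "largest_drop"), "weak")
  expect_equal(e1$chosen_k, 2L)
  expect_equal(e2$chosen_k, 2L)
  expect_true(e1$low_confidence)

  expect_error(elbow_from_curve(c(1, NA, 0.5)), "non-finite")
})

test_that("k-means MSE is non-increasing in k with enough restarts", {
  sim <- simulate_morphology_table(n_wt = 150L, n_mjd = 150L, seed = 8L)
  e <- suppressWarnings(
    elbow_select_k(sim$table[, names(significant_feature_directions())],
                   k_max = 8L, n_restarts = 10L, seed = 8L)
  )
  expect_true(all(diff(e$mse) < 1e-8))
})

test_that("cluster composition reflects separation, shuffling and the trivial case", {
  sim <- simulate_morphology_table(seed = 10L)
  x <- sim$table[, names(significant_feature_directions())]
  e <- suppressWarnings(elbow_select_k(x, seed = 10L))
  expect_equal(e$chosen_k, 2L)
  comp <- cluster_composition(e$fits[[2L]]$assignments, sim$table$genotype)
  expect_true(all(apply(comp$fractions, 1, max) >= 0.95))

  # shuffled labels: fractions near the genotype prior
  set.seed(10)
  shuf <- cluster_composition(e$fits[[2L]]$assignments,
                              sample(sim$table$genotype))
  prior <- 389 / 699
  expect_true(all(abs(shuf$fractions[, "MJD"] - prior) < 0.1))

  # single cluster: composition equals the global proportions
  one <- cluster_composition(rep(1L, 699), sim$table$genotype)
  expect_equal(unname(one$fractions[1, "MJD"]), prior, tolerance = 1e-12)

  expect_error(cluster_composition(1:5, rep("a", 4)), "equal length")
})
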