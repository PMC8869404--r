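test_that("a branchless phenotype draws a clean disc, deterministically", {
  p <- cell_phenotype_params(soma_radius_px = 10, n_primary_branches = 0L, seed = 3L)
  r1 <- simulate_cell_mask(p, canvas = 120L)
  r2 <- simulate_cell_mask(p, canvas = 120L)
  expect_identical(unclass(r1$mask), unclass(r2$mask))
  expect_equal(sum(r1$mask), pi * 100, tolerance = 0.02)
  expect_equal(max(gliaProfiler:::label_components(r1$mask)), 1L)
  expect_equal(r1$truth$label, "custom")
})

test_that("mask generation is deterministic and single-component for both presets", {
  for (ph in c("ramified", "activated")) {
    a <- simulate_cell_mask(phenotype_preset(ph, seed = 7), canvas = 296L)
    b <- simulate_cell_mask(phenotype_preset(ph, seed = 7), canvas = 296L)
    expect_identical(unclass(a$mask), unclass(b$mask))
    expect_equal(max(gliaProfiler:::label_components(a$mask)), 1L)
    expect_equal(a$truth$label, ph)
  }
  # different seeds give different masks
  c1 <- simulate_cell_mask(phenotype_preset("ramified", seed = 1), canvas = 296L)
  c2 <- simulate_cell_mask(phenotype_preset("ramified", seed = 2), canvas = 296L)
  expect_false(identical(unclass(c1$mask), unclass(c2$mask)))
})

test_that("an undersized canvas fails with an explicit sizing error", {
  err <- tryCatch(
    simulate_cell_mask(phenotype_preset("ramified", seed = 1), canvas = 64L),
    error = function(e) e
  )
  expect_s3_class(err, "gp_canvas_error")
  expect_match(conditionMessage(err), "required")
  expect_match(conditionMessage(err), "at least")
})

test_that("ramified cells have more total branch length than activated ones", {
  n_seeds <- 100L
  wins <- 0L
  for (s in seq_len(n_seeds)) {
    ram <- simulate_cell_mask(phenotype_preset("ramified", seed = s), canvas = 296L)
    act <- simulate_cell_mask(phenotype_preset("activated", seed = s), canvas = 296L)
    lr <- skeleton_feature_vector(skeletonize(ram$mask))["total_branch_length"]
    la <- skeleton_feature_vector(skeletonize(act$mask))["total_branch_length"]
    wins <- wins + (lr > la)
  }
  expect_gte(wins, 95L)
})

test_that("preset medians move every significant feature in the reported direction", {
  n_seeds <- 30L
  feats <- c("density", "cell_circularity", "total_branch_length",
             "convex_hull_area", "max_span_across_hull")
  vals <- lapply(c("ramified", "activated"), function(ph) {
    sapply(seq_len(n_seeds), function(s) {
      m <- simulate_cell_mask(phenotype_preset(ph, seed = s), canvas = 296L)$mask
      c(skeleton_feature_vector(skeletonize(m)),
        shape_feature_vector(m))[feats]
    })
  })
  med_ram <- apply(vals[[1]], 1, median)
  med_act <- apply(vals[[2]], 1, median)
  expect_gt(med_act["density"], med_ram["density"])
  expect_gt(med_act["cell_circularity"], med_ram["cell_circularity"])
  expect_lt(med_act["total_branch_length"], med_ram["total_branch_length"])
  expect_lt(med_act["convex_hull_area"], med_ram["convex_hull_area"])
  expect_lt(med_act["max_span_across_hull"], med_ram["max_span_across_hull"])
})

test_that("the feature-table generator reproduces requested effects and nulls", {
  # null: ~5% rejections at alpha = 0.05
  n_rej <- sapply(1:60, function(s) {
    sim <- simulate_morphology_table(n_wt = 200L, n_mjd = 200L,
                                     effect_size = 0, shifted = c(), seed = s)
    sig <- feature_significance(sim$table)
    sum(sig$selected)
  })
  expect_gt(mean(n_rej), 0.6)  # 25 * 0.05 = 1.25 expected
  expect_lt(mean(n_rej), 2.0)

  # power: 3-SD shifts on the 14 features are always detected
  for (s in 1:10) {
    sim <- simulate_morphology_table(seed = s)
    sig <- feature_significance(sim$table)
    hit <- sig$feature[sig$selected]
    expect_true(all(names(significant_feature_directions()) %in% hit))
  }

  # effect calibration at large n: realised shift close to requested
  sim <- simulate_morphology_table(n_wt = 10000L, n_mjd = 10000L, seed = 99L)
  base <- morpho_feature_baseline()
  dirs <- significant_feature_directions()
  for (f in names(dirs)) {
    shift <- (mean(sim$table[[f]][sim$table$genotype == "MJD"]) -
                mean(sim$table[[f]][sim$table$genotype == "WT"])) /
      base$sd[f]
    expect_equal(unname(shift), unname(3 * dirs[f]), tolerance = 0.05)
  }

  expect_error(simulate_morphology_table(n_wt = 0L), "n >= 2")
  bad_cov <- diag(25); bad_cov[1, 1] <- -1
  expect_error(simulate_morphology_table(covariance = bad_cov),
               "positive semi-definite")
  expect_error(simulate_morphology_table(shifted = c(not_a_feature = 1)),
               "unknown shifted")
})

test_that("count simulation is deterministic with NB marginals and planted effects", {
  a <- simulate_count_matrix(n_genes = 10L, n_up = 1L, n_down = 0L, seed = 5L)
  b <- simulate_count_matrix(n_genes = 10L, n_up = 1L, n_down = 0L, seed = 5L)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts >= 0))
  expect_equal(sort(unique(a$truth$status)), c("null", "up"))

  # near-zero dispersion, log2 effect 2: empirical FC within 10% of 4
  cs <- simulate_count_matrix(n_genes = 400L, n_ctrl = 50L, n_case = 50L,
                              n_up = 40L, n_down = 0L, log2_effect = 2,
                              dispersion = 1e-4, seed = 11L)
  up <- cs$truth$status == "up"
  fc <- rowMeans(cs$counts[up, cs$groups == "case"]) /
    rowMeans(cs$counts[up, cs$groups == "ctrl"])
  expect_true(all(abs(fc - 4) / 4 < 0.1))

  expect_error(simulate_count_matrix(planted_up = 1:3, planted_down = 3:5),
               "disjoint")
  expect_error(simulate_count_matrix(n_genes = 10L, n_up = 8L, n_down = 8L),
               "exceed")
})

test_that("overlap gene-set generator plants exact overlap and concordance", {
  sim <- simulate_overlap_gene_sets(23930L, 101L, 1000L, 27L, 17L, seed = 3L)
  cc <- direction_concordance(sim$set_a, sim$set_b)
  expect_equal(cc$overlap, 27L)
  expect_equal(cc$concordant, 17L)
  expect_equal(cc$discordant, 10L)

  # zero overlap
  sim0 <- simulate_overlap_gene_sets(500L, 20L, 30L, 0L, 0L, seed = 1L)
  cc0 <- direction_concordance(sim0$set_a, sim0$set_b)
  expect_equal(unlist(cc0[c("overlap", "concordant", "discordant")]),
               c(overlap = 0L, concordant = 0L, discordant = 0L))

  expect_error(simulate_overlap_gene_sets(100L, 10L, 10L, 12L, 5L),
               "<= both set sizes")
  expect_error(simulate_overlap_gene_sets(100L, 10L, 10L, 5L, 7L),
               "planted_concordant")
  expect_error(simulate_overlap_gene_sets(10L, 8L, 8L, 2L, 1L),
               "do not fit")
})
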