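test_that("RPM columns always sum to one million", {
  m <- matrix(c(5, 50), 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(as.numeric(rpm_normalize(m)), c(1e6, 1e6))

  m2 <- matrix(c(3, 1), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(as.numeric(rpm_normalize(m2)), c(750000, 250000))

  set.seed(1)
  m3 <- matrix(rpois(600, 40), 60, 10)
  expect_true(all(abs(colSums(rpm_normalize(m3)) - 1e6) < 1e-6 * 1e6))

  m4 <- cbind(m2, s2 = c(0, 0))
  expect_error(rpm_normalize(m4), "s2", class = "gp_zero_library_error")
})

test_that("the null behaves: |FC| near 1, uniform p, no filter passers", {
  cs <- simulate_count_matrix(n_genes = 4000L, n_up = 0L, n_down = 0L,
                              log2_effect = 0, seed = 2L)
  rpm <- rpm_normalize(cs$counts)
  de <- differential_expression(rpm, cs$groups)
  expect_true(all(abs(de$fc) >= 1, na.rm = TRUE))
  # p roughly uniform
  expect_gt(mean(de$p > 0.5, na.rm = TRUE), 0.4)
  expect_lt(mean(de$p < 0.05, na.rm = TRUE), 0.1)
  dg <- filter_degs(de)
  expect_lte(dg$n_total, 3L)

  # large n null: fold changes concentrate at 1
  cs2 <- simulate_count_matrix(n_genes = 300L, n_ctrl = 60L, n_case = 60L,
                               n_up = 0L, n_down = 0L, log2_effect = 0,
                               seed = 3L)
  de2 <- differential_expression(rpm_normalize(cs2$counts), cs2$groups)
  expect_lt(median(abs(de2$fc)), 1.1)
})

test_that("a planted 4-fold gene at n=4 passes the filter almost always", {
  hits <- sapply(1:40, function(s) {
    cs <- simulate_count_matrix(n_genes = 2000L, n_up = 1L, n_down = 0L,
                                log2_effect = 2, dispersion = 0.05, seed = s)
    de <- differential_expression(rpm_normalize(cs$counts), cs$groups)
    dg <- filter_degs(de)
    cs$truth$gene[cs$truth$status == "up"] %in% dg$up
  })
  expect_gte(mean(hits), 0.95)
})

test_that("BH adjustment matches the hand computation and is monotone", {
  # hand BH: p = (.01,.02,.03,.04), m = 4 -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))

  cs <- simulate_count_matrix(n_genes = 1000L, seed = 4L, n_up = 20L, n_down = 5L)
  de <- differential_expression(rpm_normalize(cs$counts), cs$groups)
  ord <- order(de$p)
  expect_true(all(diff(de$fdr[ord]) >= -1e-12, na.rm = TRUE))
  expect_true(all(de$fdr >= 0 & de$fdr <= 1, na.rm = TRUE))
})

test_that("all-zero genes are flagged and excluded from testing", {
  cs <- simulate_count_matrix(n_genes = 50L, n_up = 2L, n_down = 0L, seed = 5L)
  counts <- cs$counts
  counts[3, ] <- 0L
  rpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  de <- differential_expression(rpm, cs$groups)
  expect_false(de$tested[3])
  expect_true(is.na(de$p[3]) && is.na(de$fc[3]))
  expect_equal(sum(!de$tested), 1L)
})

test_that("the moderated t agrees with the independent empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  cs <- simulate_count_matrix(n_genes = 800L, n_up = 15L, n_down = 5L, seed = 6L)
  rpm <- rpm_normalize(cs$counts)
  de <- differential_expression(rpm, cs$groups, method = "moderated")

  x <- log2(rpm + 1)
  design <- model.matrix(~ cs$groups)
  fit <- limma::eBayes(limma::lmFit(x, design))
  lp <- fit$p.value[, 2]
  # same moderation family: correlation of log p near 1, and the same
  # top genes
  keep <- de$tested
  expect_gt(cor(log(de$p[keep]), log(lp[keep])), 0.99)
  top_mine <- de$gene[order(de$p)][1:20]
  top_limma <- rownames(x)[order(lp)][1:20]
  expect_gte(length(intersect(top_mine, top_limma)), 18L)
})

test_that("welch mode is available and calibrated under the null", {
  cs <- simulate_count_matrix(n_genes = 2000L, n_up = 0L, n_down = 0L,
                              log2_effect = 0, seed = 7L)
  de <- differential_expression(rpm_normalize(cs$counts), cs$groups,
                                method = "welch")
  expect_lt(abs(mean(de$p < 0.05, na.rm = TRUE) - 0.05), 0.03)
})

test_that("marker panels score purity and report misses", {
  set.seed(8)
  rpm <- matrix(rexp(8 * 6, 1), 8, 6,
                dimnames = list(c("Tmem119", "P2ry12", "Gfap", "Aqp4",
                                  "Snap25", "Rbfox3", "Mbp", "Plp1"),
                                paste0("s", 1:6)))
  rpm[1:2, ] <- rpm[1:2, ] + 100 # microglia genes high
  panels <- list(
    microglia = c("Tmem119", "P2ry12", "Hexb"),
    astrocyte = c("Gfap", "Aqp4"),
    neuron = c("Snap25", "Rbfox3"),
    oligodendrocyte = c("Mbp", "Plp1")
  )
  sc <- marker_panel_scores(rpm, panels)
  expect_gte(sc$enrichment, 50)
  expect_equal(sc$misses$microglia, "Hexb")

  # uniform expression: enrichment 1
  u <- matrix(10, 8, 6, dimnames = dimnames(rpm))
  expect_equal(marker_panel_scores(u, panels)$enrichment, 1)

  expect_error(marker_panel_scores(rpm, c(panels, list(tcell = "Cd3e"))),
               class = "gp_empty_panel_error")
})

test_that("ddCT fold changes follow the 2^-ddCT arithmetic", {
  ct <- data.frame(
    sample = rep(paste0("s", 1:6), each = 2),
    group = rep(rep(c("WT", "TG"), each = 3), each = 2),
    gene = rep(c("B2m", "Fos"), 6),
    ct = c(20, 25, 20, 25, 20, 25, 20, 24, 20, 24, 20, 24)
  )
  q <- ddct_fold_change(ct, "B2m", "WT")
  expect_equal(unique(q$fold_change[q$group == "WT"]), 1)
  expect_equal(unique(q$fold_change[q$group == "TG"]), 2)
  expect_equal(mean(q$ddct[q$group == "WT"]), 0)

  # all CTs equal: every fold is 1
  ct2 <- ct; ct2$ct <- rep(c(20, 23), 6)
  q2 <- ddct_fold_change(ct2, "B2m", "WT")
  expect_true(all(q2$fold_change == 1))

  # missing housekeeping CT errors with the sample named
  ct3 <- ct[-1, ]
  expect_error(ddct_fold_change(ct3, "B2m", "WT"), "s1",
               class = "gp_missing_housekeeping_error")
})
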