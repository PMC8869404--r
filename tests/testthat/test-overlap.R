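test_that("gene sets normalise symbols and reject duplicates", {
  gs <- gene_set(c(" Fos", "JunB "), c("up", "down"), name = "x")
  expect_equal(gs$genes, c("Fos", "JunB"))
  expect_equal(gs$key, c("fos", "junb"))
  expect_error(gene_set(c("Fos", "FOS")), "duplicate")
  expect_error(gene_set(c("a", "b"), c("up", "sideways")), "up")
})

test_that("fisher_overlap builds the right table and symmetric case", {
  r <- fisher_overlap(gene_set(paste0("g", 1:10)),
                      gene_set(paste0("g", c(1:5, 11:15))),
                      universe_size = 20)
  expect_equal(as.numeric(r$table), c(5, 5, 5, 5))
  expect_equal(sum(r$table), 20)
  expect_equal(r$p, 1)
  expect_equal(r$odds_ratio, 1)
  expect_true(r$ci[1] < 1 && r$ci[2] > 1)

  expect_error(
    fisher_overlap(gene_set(paste0("g", 1:10)), gene_set(paste0("g", 5:20)),
                   universe_size = 15),
    class = "gp_universe_error"
  )
})

test_that("Fisher p matches exhaustive hypergeometric enumeration on small tables", {
  worst <- 0
  for (m1 in seq(0, 12, by = 2)) {
    for (n1 in seq(0, 12, by = 2)) {
      for (m2 in seq(0, 12, by = 3)) {
        lo <- max(0, n1 - m2); hi <- min(n1, m1)
        if (lo > hi) next
        for (a in lo:hi) {
          b <- m1 - a; c_ <- n1 - a; d <- m2 - c_
          if (min(b, c_, d) < 0 || a + b + c_ + d == 0) next
          p_impl <- fisher.test(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))$p.value
          worst <- max(worst, abs(p_impl - brute_fisher_p(a, b, c_, d)))
        }
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("the Baptista-Pike interval brackets the point estimate and covers", {
  # CI contains the point OR on assorted tables
  set.seed(9)
  for (i in 1:25) {
    a <- sample(1:10, 1); b <- sample(1:10, 1)
    c_ <- sample(1:10, 1); d <- sample(1:10, 1)
    or <- (a * d) / (b * c_)
    ci <- baptista_pike_ci(a, b, c_, d)
    expect_lte(ci[1], or * (1 + 1e-6))
    expect_gte(ci[2], or * (1 - 1e-6))
  }

  # coverage at the null: exact inversion is conservative (>= 95%)
  set.seed(10)
  m1 <- 12L; m2 <- 15L; n <- 10L
  cover <- sum(sapply(1:800, function(i) {
    a <- rhyper(1, m1, m2, n)
    ci <- baptista_pike_ci(a, m1 - a, n - a, m2 - (n - a))
    ci[1] <= 1 && ci[2] >= 1
  }))
  expect_gte(cover / 800, 0.93)

  # zero cells: explicit one-sided bounds, no crash
  ci0 <- baptista_pike_ci(0, 10, 5, 100)
  expect_equal(unname(ci0[1]), 0)
  ci_inf <- baptista_pike_ci(10, 0, 5, 100)
  expect_true(is.infinite(ci_inf[2]))

  # degenerate support (overlap = sizes = universe) handled
  sim <- simulate_overlap_gene_sets(10L, 10L, 10L, 10L, 10L, seed = 2L)
  r <- fisher_overlap(sim$set_a, sim$set_b, universe_size = 10)
  expect_equal(r$p, 1)
  expect_true(is.infinite(r$ci[2]))
})

test_that("direction concordance reproduces the published model comparisons", {
  als <- direction_concordance(
    fixture_set("overlap_mjd_vs_als_mjd_directions.csv"),
    fixture_set("overlap_mjd_vs_als_als_directions.csv")
  )
  expect_equal(als$overlap, 27L)
  expect_equal(als$concordant, 17L)
  expect_equal(als$discordant, 10L)

  ad <- direction_concordance(
    fixture_set("overlap_mjd_vs_ad_mjd_directions.csv"),
    fixture_set("overlap_mjd_vs_ad_ad_directions.csv")
  )
  expect_equal(ad$overlap, 31L)
  expect_equal(ad$discordant, 19L)
  expect_equal(ad$concordant, 12L)
})

test_that("concordance identities and error paths hold", {
  a <- gene_set(c("Fos", "Junb", "Plin2"), c("up", "up", "down"))
  expect_equal(direction_concordance(a, a)$concordant, 3L)
  expect_equal(direction_concordance(a, a)$discordant, 0L)

  b <- gene_set(c("Xyz1", "Xyz2"), c("up", "down"))
  cc <- direction_concordance(a, b)
  expect_equal(unlist(cc[c("overlap", "concordant", "discordant")]),
               c(overlap = 0L, concordant = 0L, discordant = 0L))

  # shared gene without a direction errors and names the gene
  c1 <- gene_set(c("Fos", "Junb"), c("up", "up"))
  c2 <- c1; c2$directions <- c("up", NA)
  expect_error(direction_concordance(c1, c2), "Junb",
               class = "gp_missing_direction_error")
})
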