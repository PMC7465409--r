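test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_samples = 80, n_genes = 120, n_de_genes = 10,
                       n_disparity_genes = 5, n_modules = 1,
                       module_size = 30, seed = 7)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$clinical, b2$clinical)
  expect_identical(b1$copy_number, b2$copy_number)
  expect_identical(b1$truth, b2$truth)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(race_fractions = c(White = 0.5, BAA = 0.4)),
               "sum to 1")
  expect_error(cohort_config(n_genes = 100, n_modules = 2, module_size = 60),
               "exceeds n_genes")
  expect_error(cohort_config(disparity_hazard_ratio = 0), "> 0")
})

test_that("cohort structure honors the configured composition", {
  cfg <- cohort_config(n_samples = 600, n_genes = 100, n_de_genes = 0,
                       n_disparity_genes = 0, n_modules = 0, seed = 3)
  b <- generate_cohort(cfg)
  expect_identical(colnames(b$expression), b$clinical$sample_id)
  expect_false(anyDuplicated(b$gene_ids) > 0)
  expect_true(all(b$expression >= 0))
  expect_true(all(b$copy_number %in% -2:2))
  tab <- table(b$clinical$race)
  expect_equal(as.integer(tab[c("White", "BAA", "Asian", "Unknown")]),
               c(414, 102, 36, 48))
  # ~90% diploid copy number
  expect_gt(mean(b$copy_number == 0), 0.88)
  expect_lt(mean(b$copy_number == 0), 0.92)
})

test_that("planted DE genes recover the configured log2 shift", {
  cfg <- cohort_config(n_samples = 600, n_genes = 300, n_de_genes = 50,
                       de_log2_shift = 1, n_disparity_genes = 0,
                       n_modules = 0, seed = 42)
  b <- generate_cohort(cfg)
  baa <- b$clinical$race == "BAA"
  wht <- b$clinical$race == "White"
  fc <- rowMeans(b$expression[b$truth$de_genes, baa]) -
    rowMeans(b$expression[b$truth$de_genes, wht])
  expect_lt(abs(mean(fc) - 1), 0.05)
})

test_that("module genes share the configured within-block correlation", {
  cfg <- cohort_config(n_samples = 300, n_genes = 200, n_de_genes = 0,
                       n_disparity_genes = 0, n_modules = 1,
                       module_size = 40, module_correlation = 0.8, seed = 5)
  b <- generate_cohort(cfg)
  idx <- names(b$truth$modules)[b$truth$modules == "B1"]
  cm <- cor(t(b$expression[idx, ]))
  mean_off <- mean(cm[upper.tri(cm)])
  expect_gt(mean_off, 0.72)
  expect_lt(mean_off, 0.88)
})

test_that("disparity genes are overexpressed near the configured frequency", {
  cfg <- cohort_config(n_samples = 600, n_genes = 80, n_de_genes = 0,
                       n_disparity_genes = 10, overexpression_fraction = 0.15,
                       n_modules = 0, seed = 9)
  b <- generate_cohort(cfg)
  st <- expression_status_matrix(b$expression, b$copy_number)
  freq <- over_frequency(st, b$clinical, "BAA")[b$truth$disparity_genes]
  expect_true(all(freq >= 0.10))
  expect_true(all(freq <= 0.30))
  # risk-pool samples get the multiplied hazard: planted samples should be
  # enriched for events relative to the rest of the target race
  baa <- b$clinical$race == "BAA"
  pool <- b$clinical$sample_id %in% b$truth$target_pool
  expect_gt(mean(b$clinical$os_event[pool]),
            mean(b$clinical$os_event[baa & !pool]))
})

test_that("null configurations yield uniform DE p-values", {
  cfg <- cohort_config(n_samples = 300, n_genes = 400, n_de_genes = 0,
                       n_disparity_genes = 0, n_modules = 0, seed = 17)
  b <- generate_cohort(cfg)
  de <- de_table(b$expression, b$clinical)
  expect_gt(suppressWarnings(stats::ks.test(de$p, "punif"))$p.value, 0.01)
  expect_equal(sum(de$q < 0.001), 0)
})

test_that("gene set generation covers the trivial and planted cases", {
  uni <- sprintf("G%03d", 1:50)
  gs <- generate_gene_sets(uni, n_sets = 1, set_size = 50, seed = 1)
  expect_setequal(gs$sets[[1]], uni)
  expect_error(generate_gene_sets(character(0), 1, 1), "empty universe")
  expect_error(generate_gene_sets(uni, 1, 60), "exceeds universe")
  g1 <- generate_gene_sets(uni, 5, 10, seed = 3)
  g2 <- generate_gene_sets(uni, 5, 10, seed = 3)
  expect_identical(g1$sets, g2$sets)
})

test_that("planted driver sets carry the configured gene-driver correlation", {
  cfg <- cohort_config(n_samples = 200, n_genes = 300, n_de_genes = 0,
                       n_disparity_genes = 0, n_modules = 0, seed = 21)
  b <- generate_cohort(cfg)
  gs <- generate_gene_sets(b$gene_ids, n_sets = 3, set_size = 30, seed = 5,
                           planted_driver = "G0001", n_planted_sets = 1,
                           planted_correlation = 0.8, bundle = b)
  drv <- gs$bundle$expression["G0001", ]
  r <- vapply(setdiff(gs$truth$planted_genes, "G0001"),
              function(g) cor(gs$bundle$expression[g, ], drv), numeric(1))
  expect_gt(median(r), 0.6)
})

test_that("mask generation conserves pixel counts and records exact truth", {
  m0 <- generate_masks(60, 40, n_nests = 0, seed = 2)
  expect_equal(sum(m0$mask == 1L), 0)
  expect_equal(nrow(m0$truth$nests), 0)
  expect_equal(sum(m0$truth$class_counts), 60 * 40)

  m <- generate_masks(120, 100, n_nests = 4, nest_radius_range = c(4, 8),
                      seed = 6)
  expect_equal(sum(m$truth$class_counts), 120 * 100)
  expect_equal(sum(m$mask == 1L), sum(m$truth$nests$area))
  expect_equal(nrow(m$truth$nests), 4)
  # truth areas equal labeled component areas
  f <- extract_nest_features(m$mask, min_nest_area = 1)
  expect_equal(f$n_nests, 4)
  expect_setequal(f$nests$area, m$truth$nests$area)
  expect_error(generate_masks(50, 50, n_nests = 40,
                              nest_radius_range = c(10, 12), seed = 1),
               "could not place")
})
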