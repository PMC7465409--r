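test_that("Fisher overrepresentation matches the enumeration oracle", {
  uni <- sprintf("g%04d", 1:1000)
  sets <- list(big = uni[1:100])
  res0 <- fisher_overrepresentation(uni[900:909], sets, uni)   # k = 0
  expect_equal(res0$ovf, 0)
  expect_equal(res0$p, 1)
  res <- fisher_overrepresentation(c(uni[1:5], uni[500:504]), sets, uni)
  expect_equal(res$k, 5)
  expect_equal(res$ovf, 5.0)
  expect_equal(res$p, enum_fisher_p(5, 100, 1000, 10), tolerance = 1e-10)
  full <- fisher_overrepresentation(uni, sets, uni)
  expect_equal(full$k, full$K)
  expect_equal(full$ovf, 1)
  expect_equal(full$p, 1)
  expect_error(fisher_overrepresentation("a", sets, character(0)), "empty")
  # random small instances against enumeration
  set.seed(41)
  for (i in 1:15) {
    N <- sample(20:60, 1)
    u <- sprintf("x%02d", 1:N)
    K <- sample(3:(N - 2), 1); n <- sample(3:(N - 2), 1)
    s <- list(s = sample(u, K))
    q <- sample(u, n)
    r <- fisher_overrepresentation(q, s, u)
    expect_equal(r$p, enum_fisher_p(r$k, K, N, n), tolerance = 1e-10)
  }
})

test_that("signal-to-noise ranking behaves at the extremes", {
  set.seed(42)
  ex <- matrix(rnorm(50 * 40), 50, 40,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:40)))
  ex["g02", ] <- 7                       # constant gene scores 0
  rk <- gsea_rank_genes(ex, "g01", high_low_fraction = 0.25)
  expect_equal(rk$score[rk$gene == "g02"], 0)
  expect_equal(rk$gene[order(rk$score, decreasing = TRUE)], rk$gene)
  # reversing the phenotype negates every score
  ex2 <- ex
  ex2["g01", ] <- -ex["g01", ]
  rk2 <- gsea_rank_genes(ex2, "g01", high_low_fraction = 0.25)
  s1 <- setNames(rk$score, rk$gene)
  s2 <- setNames(rk2$score, rk2$gene)
  common <- setdiff(names(s1), "g01")
  expect_equal(s2[common], -s1[common], tolerance = 1e-12)
  expect_error(gsea_rank_genes(ex, "g01", high_low_fraction = 0.05),
               "fewer than")
})

test_that("a gene tracking the phenotype ranks at the top of the list", {
  set.seed(43)
  n <- 200
  ex <- matrix(rnorm(2000 * n), 2000, n,
               dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%03d", 1:n)))
  drv <- ex[1, ]
  ex[2, ] <- 0.9 * scale(drv)[, 1] + sqrt(1 - 0.81) * rnorm(n)
  rk <- gsea_rank_genes(ex, "g0001")
  expect_lte(match("g0002", rk$gene), 200)   # top decile of 2000
})

test_that("running enrichment score matches the walked running sum and fgsea", {
  genes <- sprintf("g%03d", 1:200)
  set.seed(44)
  ranked <- data.frame(gene = genes,
                       score = sort(rnorm(200), decreasing = TRUE))
  # single-gene set at rank 1
  top <- running_enrichment_score(ranked, genes[1])
  expect_equal(top$es, 1.0)
  expect_equal(top$leading_edge, genes[1])
  # set at the bottom of the list
  bottom <- running_enrichment_score(ranked, genes[181:200])
  expect_lt(bottom$es, 0)
  expect_true(all(bottom$leading_edge %in% genes[181:200]))
  # random sets: ES equals the extreme of the full running sum, which ends at 0
  for (i in 1:10) {
    s <- sample(genes, 25)
    walk <- walk_running_sum(ranked, s)
    expect_lt(abs(walk[length(walk)]), 1e-9)
    r <- running_enrichment_score(ranked, s)
    expect_equal(r$es, walk[which.max(abs(walk))], tolerance = 1e-12)
  }
  expect_error(running_enrichment_score(ranked, "absent"), "empty intersection")
})

test_that("enrichment score agrees with the fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(45)
  sc <- sort(rnorm(300), decreasing = TRUE)
  names(sc) <- sprintf("g%03d", 1:300)
  ranked <- data.frame(gene = names(sc), score = sc)
  for (i in 1:10) {
    s <- sample(names(sc), 20)
    es1 <- running_enrichment_score(ranked, s)$es
    es2 <- fgsea::calcGseaStat(sc, selectedStats = sort(match(s, names(sc))),
                               gseaParam = 1)
    expect_equal(es1, es2, tolerance = 1e-12)
  }
})

test_that("GSEA is reproducible bit-for-bit under a fixed seed", {
  set.seed(46)
  ex <- matrix(rnorm(300 * 60), 300, 60,
               dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:60)))
  sets <- list(A = sample(rownames(ex), 20), B = sample(rownames(ex), 20))
  r1 <- gsea(ex, "g001", sets, n_permutations = 100, seed = 99)
  r2 <- gsea(ex, "g001", sets, n_permutations = 100, seed = 99)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$leading_edges, r2$leading_edges)
  expect_error(gsea(ex, "g001", list(bad = "nope"), n_permutations = 10),
               "bad")
})

test_that("driver-correlated sets enrich and their leading edges are recovered", {
  cfg <- cohort_config(n_samples = 200, n_genes = 400, n_de_genes = 0,
                       n_disparity_genes = 0, n_modules = 0, seed = 47)
  b <- generate_cohort(cfg)
  gs <- generate_gene_sets(b$gene_ids, n_sets = 4, set_size = 30, seed = 48,
                           planted_driver = "G0001", n_planted_sets = 2,
                           planted_correlation = 0.8, bundle = b)
  res <- gsea(gs$bundle$expression, "G0001", gs$sets,
              n_permutations = 200, seed = 49)
  planted <- res$table$set %in% gs$truth$planted_sets
  expect_true(all(res$table$p[planted] < 0.05))
  core <- core_enrichment_union(res)
  recovered <- length(intersect(core, gs$truth$planted_genes)) /
    length(gs$truth$planted_genes)
  expect_gte(recovered, 0.8)
})

test_that("core enrichment union deduplicates and handles the empty case", {
  fake <- structure(list(
    table = data.frame(set = c("A", "B", "C"), p = c(0.01, 0.02, 0.9)),
    leading_edges = list(A = c("g1", "g2"), B = c("g2", "g3"), C = "g9")),
    class = "gsea_result")
  expect_equal(core_enrichment_union(fake), c("g1", "g2", "g3"))
  fake$table$p <- rep(0.9, 3)
  expect_equal(core_enrichment_union(fake), character(0))
})
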