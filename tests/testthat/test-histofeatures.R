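test_that("class weights follow the zero-ignore rule", {
  expect_equal(unname(class_weights(c("0" = 30, "1" = 25, "2" = 45))),
               c(0, 0.75, 0.55))
  expect_equal(unname(class_weights(c("1" = 100))), 0)   # single-class image
  expect_error(class_weights(c("1" = -5, "2" = 10)), "\\[0, N\\]")
  # identity on random count vectors
  set.seed(51)
  for (i in 1:10) {
    counts <- setNames(rmultinom(1, 5000, runif(6))[, 1], as.character(0:5))
    w <- class_weights(counts)
    expect_equal(unname(w[-1]), unname(1 - counts[-1] / sum(counts)))
    expect_equal(unname(w["0"]), 0)
  }
})

test_that("Reinhard normalization is an identity for own stats and idempotent", {
  set.seed(52)
  img <- array(runif(30 * 20 * 3, 0.1, 0.9), c(30, 20, 3))
  st <- lab_stats(img)
  out <- reinhard_normalize(img, st$mean, st$sd)
  expect_lt(max(abs(out - img)), 1 / 255)
  ref <- array(runif(30 * 20 * 3, 0.2, 0.8), c(30, 20, 3))
  tgt <- lab_stats(ref)
  once <- reinhard_normalize(img, tgt$mean, tgt$sd)
  expect_warning(twice <- reinhard_normalize(once, tgt$mean, tgt$sd), NA)
  expect_lt(max(abs(twice - once)), 1 / 255)
})

test_that("constant-color images map to the target means", {
  img <- array(rep(c(0.6, 0.3, 0.4), each = 50), c(10, 5, 3))
  tgt <- lab_stats(array(rep(c(0.2, 0.7, 0.5), each = 50), c(10, 5, 3)))
  w <- testthat::capture_warnings(out <- reinhard_normalize(img, tgt$mean, tgt$sd))
  expect_true(all(grepl("zero source sd", w)))   # one per constant channel
  got <- rgb_to_lab(out)
  expect_equal(colMeans(matrix(got, ncol = 3)), tgt$mean, tolerance = 0.02)
})

test_that("HSI ROI selection and tiling follow the constructed geometry", {
  # pure white has saturation 0
  white <- array(1, c(8, 8, 3))
  hsi <- rgb_to_hsi(white)
  expect_true(all(hsi[, , 2] == 0))
  expect_warning(
    roi_w <- select_roi_hsi(white, s_range = c(0.2, 1), tile_size = 4,
                            min_coverage = 0),
    "empty ROI")
  expect_false(any(roi_w$roi))
  expect_equal(nrow(roi_w$tiles), 0)
  # pass-all thresholds: every tile kept
  img <- array(runif(64 * 48 * 3), c(48, 64, 3))
  all_t <- select_roi_hsi(img, tile_size = 16, min_coverage = 0)
  expect_true(all(all_t$roi))
  expect_equal(nrow(all_t$tiles), floor(64 / 16) * floor(48 / 16))
  # one saturated rectangle spanning 2 x 1 tiles at full coverage
  img2 <- array(1, c(64, 96, 3))            # white background
  img2[1:32, 1:64, 2:3] <- 0                # saturated red block
  sel <- select_roi_hsi(img2, s_range = c(0.5, 1), tile_size = 32,
                        scale = 1, min_coverage = 1.0)
  expect_equal(nrow(sel$tiles), 2)
  expect_setequal(sel$tiles$x0, c(0, 32))
  expect_true(all(sel$tiles$y0 == 0))
  # scaled low-res mask places tiles at full-resolution coordinates
  sel2 <- select_roi_hsi(img2, s_range = c(0.5, 1), tile_size = 1024,
                         scale = 32, min_coverage = 1.0)
  expect_equal(nrow(sel2$tiles), 2)
  expect_setequal(sel2$tiles$x0, c(0, 1024))
})

test_that("nest features are exact on constructed masks", {
  m <- blank_mask(100, 100)
  m[5:14, 5:14] <- 1L
  m[50:59, 70:79] <- 1L
  f <- extract_nest_features(m, min_nest_area = 50)
  expect_equal(f$n_nests, 2)
  expect_equal(f$global[["nests_per_pixel"]], 2e-4)
  expect_equal(f$local_mean[["area"]], 100)
  expect_equal(f$global[["tumor_stroma_ratio"]], 200 / 9800)
  expect_equal(f$global[["necrosis_tumor_ratio"]], 0)
  # tumor 4000 / stroma 2000
  m2 <- blank_mask(100, 100, fill = 5L)
  m2[1:40, 1:100] <- 1L
  m2[41:60, 1:100] <- 2L
  f2 <- extract_nest_features(m2)
  expect_equal(f2$global[["tumor_stroma_ratio"]], 2.0)
  # stromal TIL score
  m3 <- blank_mask(50, 50, fill = 2L)
  m3[1:10, ] <- 3L
  f3 <- extract_nest_features(m3)
  expect_equal(f3$global[["stromal_til_score"]], 500 / 2500)
})

test_that("undefined ratios are flagged, not infinite", {
  m <- blank_mask(20, 20, fill = 1L)        # all tumor: no stroma
  f <- extract_nest_features(m, min_nest_area = 10)
  expect_true(is.na(f$global[["tumor_stroma_ratio"]]))
  expect_true("tumor_stroma_undefined" %in% f$flags)
  m2 <- blank_mask(20, 20, fill = 2L)       # no tumor
  f2 <- extract_nest_features(m2)
  expect_true(is.na(f2$global[["necrosis_tumor_ratio"]]))
  expect_equal(f2$n_nests, 0)
  expect_error(extract_nest_features(matrix(0L, 5, 5)), "non-ignore")
  expect_error(extract_nest_features(matrix(7L, 5, 5)), "0..5")
})

test_that("nests use 8-connectivity and a filled disc is near-circular", {
  m <- blank_mask(10, 10)
  m[2, 2] <- 1L; m[3, 3] <- 1L             # diagonal touch: one nest
  f <- extract_nest_features(m, min_nest_area = 1)
  expect_equal(f$n_nests, 1)
  xy <- expand.grid(x = 1:61, y = 1:61)
  disc <- matrix((xy$x - 31)^2 + (xy$y - 31)^2 <= 20^2, 61, 61)
  md <- blank_mask(61, 61); md[disc] <- 1L
  fd <- extract_nest_features(md, min_nest_area = 10)
  expect_gte(fd$nests$circularity, 0.9)
  expect_lte(fd$nests$circularity, 1.1)
  expect_gte(fd$nests$solidity, 0.98)
  expect_lte(fd$nests$solidity, 1)
  expect_lt(fd$nests$eccentricity, 0.1)
})

test_that("features are invariant to translation and 90-degree rotation", {
  set.seed(53)
  base <- blank_mask(80, 80)
  base[10:25, 12:30] <- 1L
  base[40:49, 50:64] <- 1L
  f0 <- extract_nest_features(base, min_nest_area = 20)
  shifted <- blank_mask(80, 80)
  shifted[20:35, 22:40] <- 1L
  shifted[50:59, 60:74] <- 1L
  f1 <- extract_nest_features(shifted, min_nest_area = 20)
  expect_equal(f0$global, f1$global)
  expect_equal(f0$local_mean, f1$local_mean)
  rot <- t(base[nrow(base):1, ])            # 90-degree rotation
  f2 <- extract_nest_features(rot, min_nest_area = 20)
  expect_equal(f0$global, f2$global)
  expect_equal(f0$local_mean[["area"]], f2$local_mean[["area"]])
  expect_equal(f0$local_mean[["perimeter"]], f2$local_mean[["perimeter"]],
               tolerance = 0.05)
})

test_that("mask PNG round trip preserves labels", {
  m <- generate_masks(40, 30, n_nests = 2, nest_radius_range = c(3, 5),
                      seed = 54)$mask
  path <- tempfile(fileext = ".png")
  write_mask_png(m, path)
  expect_identical(read_mask_png(path), m)
})

test_that("feature-expression Spearman correlation is exact at the extremes", {
  set.seed(55)
  n <- 30
  ids <- sprintf("s%02d", 1:n)
  expr <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("gA", "gB"), ids))
  feats <- data.frame(f_mono = rank(expr["gA", ]) * 2.5,
                      f_flat = rep(1, n),
                      row.names = ids)
  res <- correlate_features_expression(feats, expr)
  mono <- res[res$feature == "f_mono" & res$gene == "gA", ]
  expect_equal(mono$rho, 1)
  flat <- res[res$feature == "f_flat", ]
  expect_true(all(is.na(flat$rho)))
  # negation antisymmetry
  feats2 <- data.frame(f = feats$f_mono, row.names = ids)
  feats2n <- data.frame(f = -feats$f_mono, row.names = ids)
  r1 <- correlate_features_expression(feats2, expr)
  r2 <- correlate_features_expression(feats2n, expr)
  expect_equal(r2$rho, -r1$rho, tolerance = 1e-12)
  expect_error(correlate_features_expression(feats[1:3, , drop = FALSE], expr),
               ">= 5")
})

test_that("independent features stay uncorrelated at n = 50", {
  set.seed(56)
  ok <- replicate(20, {
    n <- 50
    ids <- sprintf("s%02d", 1:n)
    expr <- matrix(rnorm(n), 1, n, dimnames = list("g", ids))
    feats <- data.frame(f = rnorm(n), row.names = ids)
    r <- correlate_features_expression(feats, expr)
    abs(r$rho) < 0.4 && r$q > 0.05
  })
  expect_gte(mean(ok), 0.95)
})
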