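#' Class weights for weighted categorical cross-entropy
#'
#' W_0 = 0 for the ignore class and W_c = 1 - N_c / N for every other class,
#' where N is the total pixel count and N_c the count of class c.
#'
#' @param class_counts named integer vector of per-class pixel counts; the
#'   name "0" denotes the ignore class. Counts must sum to the mask area.
#' @return named numeric weights.
#' @export
class_weights <- function(class_counts) {
  n <- sum(class_counts)
  if (n <= 0) stop("total pixel count must be > 0")
  if (any(class_counts < 0) || any(class_counts > n))
    stop("class counts must lie in [0, N]")
  w <- 1 - class_counts / n
  if ("0" %in% names(class_counts)) w[["0"]] <- 0
  w
}

# Ruderman RGB <-> l-alpha-beta transform matrices (Reinhard color transfer).
.lms_from_rgb <- matrix(c(0.3811, 0.5783, 0.0402,
                          0.1967, 0.7244, 0.0782,
                          0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.rgb_from_lms <- solve(.lms_from_rgb)   # exact inverse keeps round trips tight
.lab_from_loglms <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.loglms_from_lab <- matrix(c(1, 1, 1, 1, 1, -1, 1, -2, 0), 3, 3, byrow = TRUE) %*%
  diag(c(sqrt(3) / 3, sqrt(6) / 6, sqrt(2) / 2))

#' Convert an RGB image to the Ruderman l-alpha-beta space
#'
#' @param img H x W x 3 array with values in \[0, 1\].
#' @return H x W x 3 array of l, alpha, beta channels.
#' @export
rgb_to_lab <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  d <- dim(img)
  px <- matrix(img, ncol = 3)
  lms <- px %*% t(.lms_from_rgb)
  lms[lms < 1e-6] <- 1e-6
  lab <- log10(lms) %*% t(.lab_from_loglms)
  array(lab, d)
}

#' Convert a Ruderman l-alpha-beta image back to RGB
#'
#' @param lab H x W x 3 array of l, alpha, beta channels.
#' @return H x W x 3 RGB array clipped to \[0, 1\].
#' @export
lab_to_rgb <- function(lab) {
  d <- dim(lab)
  px <- matrix(lab, ncol = 3)
  lms <- 10^(px %*% t(.loglms_from_lab))
  rgb <- lms %*% t(.rgb_from_lms)
  rgb[rgb < 0] <- 0
  rgb[rgb > 1] <- 1
  array(rgb, d)
}

#' Per-channel mean and sd of an image in l-alpha-beta space
#'
#' Convenience for deriving Reinhard target statistics from a reference
#' image.
#'
#' @param img H x W x 3 RGB array in \[0, 1\].
#' @return list with `mean` and `sd`, length-3 each.
#' @export
lab_stats <- function(img) {
  lab <- matrix(rgb_to_lab(img), ncol = 3)
  list(mean = colMeans(lab), sd = apply(lab, 2, stats::sd))
}

#' Reinhard color normalization
#'
#' Transfers per-channel mean and sd in the Ruderman l-alpha-beta space:
#' x' = (x - mu_src) * (sd_tgt / sd_src) + mu_tgt, then converts back to RGB
#' and clips. A channel with zero source sd skips the scaling (mean shift
#' only) with a warning.
#'
#' @param img H x W x 3 RGB array in \[0, 1\] (8-bit semantics).
#' @param target_mean,target_sd length-3 target statistics in l-alpha-beta
#'   space, e.g. from [lab_stats()] of a reference image.
#' @return normalized RGB array.
#' @export
reinhard_normalize <- function(img, target_mean, target_sd) {
  stopifnot(length(target_mean) == 3, length(target_sd) == 3)
  lab <- rgb_to_lab(img)
  d <- dim(lab)
  px <- matrix(lab, ncol = 3)
  for (ch in 1:3) {
    mu <- mean(px[, ch]); s <- stats::sd(px[, ch])
    if (!is.finite(s) || s == 0) {
      warning("zero source sd in l-alpha-beta channel ", ch,
              "; mean shift only")
      px[, ch] <- px[, ch] - mu + target_mean[ch]
    } else {
      px[, ch] <- (px[, ch] - mu) * (target_sd[ch] / s) + target_mean[ch]
    }
  }
  lab_to_rgb(array(px, d))
}

#' Convert RGB to Hue-Saturation-Intensity
#'
#' H in degrees \[0, 360), S and I in \[0, 1\]. Achromatic pixels get H = 0
#' and S = 0.
#'
#' @param img H x W x 3 RGB array in \[0, 1\].
#' @return H x W x 3 HSI array.
#' @export
rgb_to_hsi <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  d <- dim(img)
  px <- matrix(img, ncol = 3)
  r <- px[, 1]; g <- px[, 2]; b <- px[, 3]
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  h <- ifelse(den > 0, acos(pmin(1, pmax(-1, num / den))) * 180 / pi, 0)
  h <- ifelse(b > g, 360 - h, h)
  h[s == 0] <- 0
  array(cbind(h, s, i), d)
}

#' HSI-thresholded region of interest and full-resolution tile grid
#'
#' Thresholds a low-resolution RGB image in HSI space (a pixel is in the ROI
#' when all three channels fall inside their ranges), then enumerates
#' non-overlapping `tile_size` x `tile_size` windows at full-resolution
#' coordinates (low-res coordinates times `scale`) and keeps windows whose
#' ROI coverage reaches `min_coverage`.
#'
#' @param img low-resolution H x W x 3 RGB array in \[0, 1\].
#' @param h_range,s_range,i_range length-2 inclusive ranges.
#' @param tile_size full-resolution tile side (default 1024).
#' @param scale full-resolution pixels per low-res pixel (default 1).
#' @param min_coverage minimum ROI fraction per tile (default 0.5).
#' @return list with `roi` (logical matrix) and `tiles` (data.frame with
#'   0-based full-resolution x0, y0 and `coverage`).
#' @export
select_roi_hsi <- function(img, h_range = c(0, 360), s_range = c(0, 1),
                           i_range = c(0, 1), tile_size = 1024, scale = 1,
                           min_coverage = 0.5) {
  hsi <- rgb_to_hsi(img)
  roi <- hsi[, , 1] >= h_range[1] & hsi[, , 1] <= h_range[2] &
    hsi[, , 2] >= s_range[1] & hsi[, , 2] <= s_range[2] &
    hsi[, , 3] >= i_range[1] & hsi[, , 3] <= i_range[2]
  full_h <- nrow(roi) * scale
  full_w <- ncol(roi) * scale
  x0s <- seq(0, full_w - tile_size, by = tile_size)
  y0s <- seq(0, full_h - tile_size, by = tile_size)
  if (full_w < tile_size) x0s <- integer(0)
  if (full_h < tile_size) y0s <- integer(0)
  if (!any(roi)) {
    warning("empty ROI; no tiles selected")
    x0s <- integer(0); y0s <- integer(0)
  }
  tiles <- expand.grid(x0 = x0s, y0 = y0s)
  if (nrow(tiles) > 0) {
    tiles$coverage <- vapply(seq_len(nrow(tiles)), function(t) {
      cols <- (floor(tiles$x0[t] / scale) + 1):
        min(ncol(roi), ceiling((tiles$x0[t] + tile_size) / scale))
      rows <- (floor(tiles$y0[t] / scale) + 1):
        min(nrow(roi), ceiling((tiles$y0[t] + tile_size) / scale))
      mean(roi[rows, cols])
    }, numeric(1))
    tiles <- tiles[tiles$coverage >= min_coverage, , drop = FALSE]
    rownames(tiles) <- NULL
  } else {
    tiles <- data.frame(x0 = integer(0), y0 = integer(0),
                        coverage = numeric(0))
  }
  list(roi = roi, tiles = tiles)
}

# 8-connected component labels for a logical matrix, via pixel-graph
# components. Returns an integer matrix (0 = background).
label_components_8 <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  idx <- which(binary)
  labels <- matrix(0L, h, w)
  if (length(idx) == 0) return(labels)
  id <- matrix(0L, h, w)
  id[idx] <- seq_along(idx)
  edges <- list()
  shift_pairs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  for (s in shift_pairs) {
    nr <- rows + s[1]; nc <- cols + s[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nb <- id[cbind(nr[ok], nc[ok])]
    has <- nb > 0L
    if (any(has))
      edges[[length(edges) + 1L]] <- cbind(id[idx[ok]][has], nb[has])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

# Marching-squares contour length of a logical matrix: straight cells
# contribute 1, corner cells sqrt(2)/2, saddle (diagonal) cells sqrt(2).
# The raw digital length overestimates smooth boundaries, so the classic
# pi*(1+sqrt(2))/8 correction for (1, sqrt 2)-weighted digital contours is
# applied; a radius-20 digital disc then lands within ~2% of 2*pi*r.
ms_perimeter <- function(binary) {
  p <- matrix(FALSE, nrow(binary) + 2, ncol(binary) + 2)
  p[2:(nrow(binary) + 1), 2:(ncol(binary) + 1)] <- binary
  a <- p[-nrow(p), -ncol(p)]
  b <- p[-nrow(p), -1]
  c_ <- p[-1, -ncol(p)]
  d <- p[-1, -1]
  s <- a + b + c_ + d
  corners <- sum(s == 1 | s == 3)
  twos <- s == 2
  diag2 <- twos & (a == d) & (a != b)
  raw <- sum(twos & !diag2) * 1 + corners * sqrt(2) / 2 + sum(diag2) * sqrt(2)
  raw * pi * (1 + sqrt(2)) / 8
}

# Number of grid pixels whose centers lie inside (or on) the convex hull of
# the given pixel centers; a convex polygon lets the inside test reduce to
# "left of every edge" with a small tolerance for boundary pixels.
convex_pixel_area <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2) return(n)
  hull <- grDevices::chull(cols, rows)      # clockwise order
  hx <- cols[hull]; hy <- rows[hull]
  if (length(hull) <= 2) return(n)          # collinear set
  cand <- expand.grid(x = min(cols):max(cols), y = min(rows):max(rows))
  inside <- rep(TRUE, nrow(cand))
  nh <- length(hx)
  for (e in seq_len(nh)) {
    x1 <- hx[e]; y1 <- hy[e]
    x2 <- hx[e %% nh + 1]; y2 <- hy[e %% nh + 1]
    # clockwise hull: interior points give non-positive cross products
    cr <- (x2 - x1) * (cand$y - y1) - (y2 - y1) * (cand$x - x1)
    inside <- inside & cr <= 1e-9
  }
  max(n, sum(inside))
}

# Shape descriptors of one pixel set (row, col coordinates).
nest_shape <- function(rows, cols, perimeter) {
  area <- length(rows)
  circ <- if (perimeter > 0) 4 * pi * area / perimeter^2 else NA_real_
  # solidity = pixel area / rasterized convex-hull area (pixels whose
  # centers fall inside the hull of the object pixel centers); the object's
  # pixels are always inside their own hull, so solidity <= 1
  solidity <- area / convex_pixel_area(rows, cols)
  mu20 <- stats::var(cols) * (area - 1) / area
  mu02 <- stats::var(rows) * (area - 1) / area
  mu11 <- if (area > 1)
    stats::cov(cols, rows) * (area - 1) / area else 0
  if (area == 1) { mu20 <- 0; mu02 <- 0; mu11 <- 0 }
  tr <- mu20 + mu02
  det_rt <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (tr + det_rt) / 2
  l2 <- (tr - det_rt) / 2
  ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
  c(area = area, perimeter = perimeter, circularity = circ,
    solidity = solidity, eccentricity = ecc)
}

#' Tumor-nest morphometrics from a class-labeled mask
#'
#' Classes: 0 outside-ROI/ignore, 1 tumor, 2 stroma, 3 tumor-infiltrating
#' lymphocytes, 4 necrosis/debris, 5 other. Tumor nests are 8-connected
#' components of tumor pixels with area >= `min_nest_area`. Four global
#' features (tumor/stroma pixel ratio, stromal TIL score TIL/(TIL+stroma),
#' necrosis/tumor ratio, nest count per non-ignore ROI pixel) and five local
#' features (area, perimeter, circularity 4*pi*A/P^2, solidity,
#' eccentricity), the locals averaged over nests. Undefined ratios (zero
#' denominators) are NA with a flag, never infinities.
#'
#' @param mask integer matrix with labels in \{0..5\}.
#' @param min_nest_area minimum nest pixel area (default 50).
#' @return object of class `nest_features`: list with `global` (named
#'   numeric), `local_mean` (named numeric), `nests` (per-nest data.frame),
#'   `n_nests`, `flags`.
#' @export
extract_nest_features <- function(mask, min_nest_area = 50) {
  if (!all(mask %in% 0:5)) stop("mask labels must lie in 0..5")
  counts <- vapply(0:5, function(k) sum(mask == k), numeric(1))
  names(counts) <- as.character(0:5)
  n_roi <- sum(mask != 0L)
  if (n_roi == 0) stop("mask has no non-ignore pixels")
  flags <- character(0)
  labels <- label_components_8(mask == 1L)
  sizes <- if (max(labels) > 0) tabulate(labels[labels > 0]) else integer(0)
  keep <- which(sizes >= min_nest_area)
  nests <- NULL
  for (ni in seq_along(keep)) {
    pix <- which(labels == keep[ni], arr.ind = TRUE)
    per <- ms_perimeter(labels == keep[ni])
    nests <- rbind(nests, nest_shape(pix[, 1], pix[, 2], per))
  }
  n_nests <- length(keep)
  tum <- counts[["1"]]; str <- counts[["2"]]
  til <- counts[["3"]]; nec <- counts[["4"]]
  tsr <- if (str > 0) tum / str else { flags <- c(flags, "tumor_stroma_undefined"); NA_real_ }
  stil <- if (til + str > 0) til / (til + str) else { flags <- c(flags, "stromal_til_undefined"); NA_real_ }
  ntr <- if (tum > 0) nec / tum else { flags <- c(flags, "necrosis_tumor_undefined"); NA_real_ }
  global <- c(tumor_stroma_ratio = tsr, stromal_til_score = stil,
              necrosis_tumor_ratio = ntr, nests_per_pixel = n_nests / n_roi)
  local_mean <- if (n_nests > 0) colMeans(nests) else
    stats::setNames(rep(NA_real_, 5),
                    c("area", "perimeter", "circularity", "solidity",
                      "eccentricity"))
  nest_df <- if (n_nests > 0) as.data.frame(nests) else
    data.frame(area = numeric(0), perimeter = numeric(0),
               circularity = numeric(0), solidity = numeric(0),
               eccentricity = numeric(0))
  structure(list(global = global, local_mean = local_mean, nests = nest_df,
                 n_nests = n_nests, class_counts = counts, flags = flags),
            class = "nest_features")
}

#' Spearman correlation between per-sample histology features and expression
#'
#' Midrank Spearman with the t-distribution approximation for p, BH adjusted
#' across all tested (feature, gene) pairs. Constant features or genes are
#' excluded from the BH family and reported with NA.
#'
#' @param features data.frame, samples x features, rownames = sample ids.
#' @param expression genes x samples matrix; columns matched to feature rows
#'   by name.
#' @return data.frame: feature, gene, n, rho, p, q.
#' @export
correlate_features_expression <- function(features, expression) {
  common <- intersect(rownames(features), colnames(expression))
  if (length(common) < 5) stop("need >= 5 paired samples")
  f <- features[common, , drop = FALSE]
  x <- expression[, common, drop = FALSE]
  out <- NULL
  for (fe in colnames(f)) {
    for (gn in rownames(x)) {
      fv <- f[[fe]]; gv <- x[gn, ]
      n <- length(fv)
      if (length(unique(fv)) == 1L || length(unique(gv)) == 1L) {
        out <- rbind(out, data.frame(feature = fe, gene = gn, n = n,
                                     rho = NA_real_, p = NA_real_,
                                     stringsAsFactors = FALSE))
        next
      }
      rho <- stats::cor(fv, gv, method = "spearman")
      p <- if (abs(rho) >= 1) 0 else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * stats::pt(-abs(tstat), df = n - 2)
      }
      out <- rbind(out, data.frame(feature = fe, gene = gn, n = n, rho = rho,
                                   p = p, stringsAsFactors = FALSE))
    }
  }
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- bh_adjust(out$p[tested])
  out
}

#' Write a class-labeled mask as a single-channel PNG
#'
#' @param mask integer matrix of labels in 0..255.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a class-labeled mask from a single-channel PNG
#'
#' @param path file path.
#' @return integer matrix of labels.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}
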