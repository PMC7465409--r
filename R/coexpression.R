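#' Signed soft-threshold adjacency from a correlation matrix
#'
#' a_ij = ((1 + cor_ij)/2)^beta; the diagonal is set to 0 so that row sums
#' are node connectivities.
#'
#' @param correlation_matrix symmetric matrix with unit diagonal.
#' @param beta soft-threshold power (>= 1).
#' @return adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
signed_adjacency <- function(correlation_matrix, beta) {
  if (!isSymmetric(unname(correlation_matrix), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  if (beta < 1) stop("beta must be >= 1")
  a <- ((1 + correlation_matrix) / 2)^beta
  diag(a) <- 0
  a
}

# Scale-free topology fit: regress log10 frequency density of binned
# connectivity on log10 mean binned connectivity using equal-occupancy bins;
# R^2 is sign-flipped negative when the slope is positive (hub-poor fit).
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) return(NA_real_)
  bin <- cut(k, breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nlevels(bin))
  widths <- diff(breaks)
  dens <- counts / (length(k) * widths)
  mean_k <- tapply(k, bin, mean)
  keep <- counts > 0 & dens > 0 & is.finite(mean_k) & mean_k > 0
  if (sum(keep) < 3) return(NA_real_)
  lx <- log10(mean_k[keep]); ly <- log10(dens[keep])
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  if (is.finite(slope) && slope > 0) -r2 else r2
}

#' Choose the soft-threshold power for scale-free topology
#'
#' For each candidate power, builds the signed adjacency, computes node
#' connectivities, and fits the scale-free model (log-log regression of the
#' connectivity frequency density over equal-occupancy bins). Picks the
#' smallest power whose signed R-squared reaches `r2_target`; if none does,
#' falls back to the argmax and flags it.
#'
#' @param expression genes x samples matrix.
#' @param beta_grid candidate powers.
#' @param r2_target scale-free fit threshold (default 0.8).
#' @param n_bins connectivity bins for the fit (default 10).
#' @return list with `beta`, `reached_target`, and `fit_table`
#'   (beta, r_squared, mean_connectivity).
#' @export
pick_soft_threshold <- function(expression, beta_grid = c(1:10, 12, 14, 16, 18, 20),
                                r2_target = 0.8, n_bins = 10) {
  if (length(beta_grid) == 0) stop("beta_grid must be non-empty")
  if (nrow(expression) < 50) stop("need >= 50 genes")
  if (ncol(expression) < 10) stop("need >= 10 samples")
  cm <- stats::cor(t(expression))
  fit_table <- data.frame(beta = beta_grid, r_squared = NA_real_,
                          mean_connectivity = NA_real_)
  for (i in seq_along(beta_grid)) {
    a <- signed_adjacency(cm, beta_grid[i])
    k <- rowSums(a)
    fit_table$r_squared[i] <- scale_free_fit(k, n_bins)
    fit_table$mean_connectivity[i] <- mean(k)
  }
  ok <- which(!is.na(fit_table$r_squared) & fit_table$r_squared >= r2_target)
  if (length(ok) > 0) {
    beta <- beta_grid[min(ok)]
    reached <- TRUE
  } else {
    beta <- beta_grid[which.max(fit_table$r_squared)]
    reached <- FALSE
    warning("no power reached scale-free R^2 target ", r2_target,
            "; using argmax beta = ", beta)
  }
  list(beta = beta, reached_target = reached, fit_table = fit_table)
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for i != j
#' and TOM_ii = 1, where k is node connectivity.
#'
#' @param adjacency symmetric matrix, entries in \[0, 1\], zero diagonal.
#' @return TOM matrix, symmetric, entries in \[0, 1\], unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(adjacency < 0) || any(adjacency > 1))
    stop("adjacency entries must lie in [0, 1]")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  k <- rowSums(adjacency)
  l <- adjacency %*% adjacency
  kmin <- outer(k, k, pmin)
  tom <- (l + adjacency) / (kmin + 1 - adjacency)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on dissimilarity 1 - TOM, cut at
#' `cut_height_fraction` of the maximum merge height (static variant of the
#' tree-cut method); clusters below `min_module_size` are labeled
#' "unassigned" and surviving modules are labeled M1, M2, ... by decreasing
#' size.
#'
#' @param tom topological overlap matrix (with gene dimnames).
#' @param min_module_size minimum genes per module (default 100).
#' @param cut_height_fraction fraction of the max merge height (default 0.99).
#' @return object of class `module_assignment`: list with `assignment`
#'   (named character vector), `sizes` (named, decreasing), `cut_height`,
#'   `tree` (hclust).
#' @export
detect_modules <- function(tom, min_module_size = 100,
                           cut_height_fraction = 0.99) {
  stopifnot(nrow(tom) == ncol(tom))
  genes <- rownames(tom) %||% paste0("g", seq_len(nrow(tom)))
  if (nrow(tom) < min_module_size) {
    warning("fewer genes than min_module_size; all unassigned")
    return(structure(list(assignment = stats::setNames(
      rep("unassigned", nrow(tom)), genes),
      sizes = integer(0), cut_height = NA_real_, tree = NULL),
      class = "module_assignment"))
  }
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cut_height <- cut_height_fraction * max(tree$height)
  raw <- stats::cutree(tree, h = cut_height)
  tab <- table(raw)
  keep <- names(tab)[tab >= min_module_size]
  assignment <- rep("unassigned", length(raw))
  if (length(keep) > 0) {
    keep_sorted <- keep[order(tab[keep], decreasing = TRUE)]
    for (i in seq_along(keep_sorted))
      assignment[raw == as.integer(keep_sorted[i])] <- paste0("M", i)
  }
  names(assignment) <- genes
  sizes <- table(assignment[assignment != "unassigned"])
  sizes <- sort(sizes, decreasing = TRUE)
  structure(list(assignment = assignment,
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 cut_height = cut_height, tree = tree),
            class = "module_assignment")
}
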