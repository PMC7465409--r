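#' Group-mean log2 fold change on log2(x+1)-scale expression
#'
#' The fold change is defined as the difference of group means on the log2
#' scale, `mu_a - mu_b` (target group minus comparator group).
#'
#' @param expression_row numeric per-sample values (log2(x+1) scale).
#' @param group_labels character vector aligned to `expression_row`.
#' @param group_a,group_b labels of the target and comparator groups.
#' @return list with `mu_a`, `mu_b`, `log2_fc`.
#' @export
log2_fold_change <- function(expression_row, group_labels,
                             group_a = "BAA", group_b = "White") {
  stopifnot(length(expression_row) == length(group_labels))
  a <- expression_row[group_labels == group_a]
  b <- expression_row[group_labels == group_b]
  if (length(a) == 0) stop("empty group: ", group_a)
  if (length(b) == 0) stop("empty group: ", group_b)
  mu_a <- mean(a); mu_b <- mean(b)
  list(mu_a = mu_a, mu_b = mu_b, log2_fc = mu_a - mu_b)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' `exact` mode evaluates the permutation null of the rank sum: via the exact
#' Wilcoxon distribution when there are no ties, and by full enumeration of
#' all group labelings of the midranks when ties are present (practical for
#' combined n <= 12, which is what `auto` uses it for). `normal` mode uses
#' the tie-corrected normal approximation with a continuity correction.
#' The two-sided exact p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y numeric samples.
#' @param mode "auto", "exact" or "normal".
#' @return two-sided p-value in (0, 1].
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  if (mode == "auto") mode <- if (nx + ny <= 12) "exact" else "normal"
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  if (mode == "exact") {
    ties <- any(duplicated(pooled))
    if (!ties) {
      # rank-sum W relates to the Mann-Whitney U by W = U + nx(nx+1)/2
      u <- w - nx * (nx + 1) / 2
      p_lo <- stats::pwilcox(u, nx, ny)
      p_hi <- stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
      return(min(1, 2 * min(p_lo, p_hi)))
    }
    if (nx + ny > 14)
      stop("exact mode with ties is limited to combined n <= 14")
    sums <- utils::combn(r, nx, FUN = sum)
    p_lo <- mean(sums <= w + 1e-9)
    p_hi <- mean(sums >= w - 1e-9)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  n <- nx + ny
  ew <- nx * (n + 1) / 2
  tie_tab <- table(pooled)
  v <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (v <= 0) return(1)
  z <- max(0, abs(w - ew) - 0.5) / sqrt(v)   # continuity-corrected
  min(1, 2 * stats::pnorm(-z))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Diploid-referenced per-sample expression status for one gene
#'
#' The reference mean and sd are computed from the samples in which the gene
#' is copy-number diploid (GISTIC 0). Each sample's z-score is
#' (value - mu) / sigma; z above the threshold is called `over`, below the
#' negative threshold `under`, otherwise `normal`. Genes with fewer than
#' `min_diploid` diploid samples (or zero reference sd) are `undefined` for
#' all samples.
#'
#' @param expression_row numeric per-sample expression.
#' @param copy_number_row integer GISTIC calls aligned to the same samples.
#' @param z_threshold call threshold (default 2).
#' @param min_diploid minimum diploid reference size (default 10).
#' @param sd_type "sample" (n-1 denominator, default) or "population".
#' @return character vector of statuses in
#'   \{"under", "normal", "over", "undefined"\}.
#' @export
call_expression_status <- function(expression_row, copy_number_row,
                                   z_threshold = 2, min_diploid = 10,
                                   sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(expression_row) != length(copy_number_row))
    stop("expression and copy-number rows must align to the same samples")
  dip <- copy_number_row == 0
  n_dip <- sum(dip)
  if (n_dip < min_diploid)
    return(rep("undefined", length(expression_row)))
  mu <- mean(expression_row[dip])
  sigma <- stats::sd(expression_row[dip])
  if (sd_type == "population") sigma <- sigma * sqrt((n_dip - 1) / n_dip)
  if (!is.finite(sigma) || sigma == 0)
    return(rep("undefined", length(expression_row)))
  z <- (expression_row - mu) / sigma
  status <- rep("normal", length(z))
  status[z > z_threshold] <- "over"
  status[z < -z_threshold] <- "under"
  status
}

#' Expression status matrix for all genes
#'
#' Applies [call_expression_status()] gene-wise; keeps the per-gene diploid
#' reference mean and sd.
#'
#' @param expression genes x samples matrix.
#' @param copy_number aligned genes x samples GISTIC matrix.
#' @inheritParams call_expression_status
#' @return object of class `expression_status`: list with `status` (character
#'   matrix), `mu`, `sigma`, `z_threshold`, `min_diploid`.
#' @export
expression_status_matrix <- function(expression, copy_number, z_threshold = 2,
                                     min_diploid = 10,
                                     sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(identical(dim(expression), dim(copy_number)))
  g <- nrow(expression)
  status <- matrix("undefined", g, ncol(expression),
                   dimnames = dimnames(expression))
  mu <- rep(NA_real_, g); sigma <- rep(NA_real_, g)
  for (i in seq_len(g)) {
    dip <- copy_number[i, ] == 0
    if (sum(dip) >= min_diploid) {
      m <- mean(expression[i, dip])
      s <- stats::sd(expression[i, dip])
      if (sd_type == "population")
        s <- s * sqrt((sum(dip) - 1) / sum(dip))
      mu[i] <- m; sigma[i] <- s
    }
    status[i, ] <- call_expression_status(expression[i, ], copy_number[i, ],
                                          z_threshold, min_diploid, sd_type)
  }
  structure(list(status = status, mu = mu, sigma = sigma,
                 z_threshold = z_threshold, min_diploid = min_diploid),
            class = "expression_status")
}

#' Per-gene differential expression table between two race groups
#'
#' Wilcoxon rank-sum p-values (tie-corrected normal approximation for the
#' cohort sizes this is meant for), BH q-values, and the log2 fold change of
#' group means. The `direction` column applies the q and fold gates.
#'
#' @param expression genes x samples matrix of log2(x+1) values.
#' @param clinical data.frame with `sample_id` and `race` aligned to columns.
#' @param group_a,group_b race labels compared (target vs comparator).
#' @param q_threshold significance gate on BH q (default 0.001).
#' @param min_pct_difference linear-scale percent-difference gate; the fold
#'   gate is |log2FC| >= log2(1 + min_pct_difference/100).
#' @param mode passed to [rank_sum_test()].
#' @return data.frame: gene, mu_a, mu_b, log2_fc, p, q, direction.
#' @export
de_table <- function(expression, clinical, group_a = "BAA", group_b = "White",
                     q_threshold = 0.001, min_pct_difference = 20,
                     mode = "normal") {
  stopifnot(ncol(expression) == nrow(clinical))
  labels <- clinical$race
  a_idx <- labels == group_a
  b_idx <- labels == group_b
  if (!any(a_idx)) stop("empty group: ", group_a)
  if (!any(b_idx)) stop("empty group: ", group_b)
  sub <- expression[, a_idx | b_idx, drop = FALSE]
  sub_a <- labels[a_idx | b_idx] == group_a
  mu_a <- rowMeans(expression[, a_idx, drop = FALSE])
  mu_b <- rowMeans(expression[, b_idx, drop = FALSE])
  p <- apply(sub, 1L, function(row)
    rank_sum_test(row[sub_a], row[!sub_a], mode = mode))
  q <- bh_adjust(p)
  log2_fc <- mu_a - mu_b
  fc_gate <- log2(1 + min_pct_difference / 100)
  direction <- rep("ns", nrow(expression))
  direction[q < q_threshold & log2_fc >= fc_gate] <- "BAA_high"
  direction[q < q_threshold & log2_fc <= -fc_gate] <- "BAA_low"
  data.frame(gene = rownames(expression), mu_a = mu_a, mu_b = mu_b,
             log2_fc = log2_fc, p = p, q = q, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene overexpression frequency within a race group
#'
#' Fraction of a race's samples called `over`, among samples with a defined
#' status for that gene.
#'
#' @param status_matrix an [expression_status_matrix()] result.
#' @param clinical clinical table aligned to the status columns.
#' @param race race label.
#' @return named numeric vector (NA when the gene is undefined).
#' @export
over_frequency <- function(status_matrix, clinical, race) {
  st <- status_matrix$status[, clinical$race == race, drop = FALSE]
  defined <- st != "undefined"
  n_def <- rowSums(defined)
  out <- ifelse(n_def > 0, rowSums(st == "over") / n_def, NA_real_)
  stats::setNames(out, rownames(st))
}

#' Gate the DE table into BAA_high / BAA_low / BAA_OVR gene sets
#'
#' `BAA_high` and `BAA_low` apply the q-value and linear-scale fold gates;
#' `BAA_OVR` keeps the BAA_high genes overexpressed in at least
#' `min_over_fraction` of the stated group's samples.
#'
#' @param de a [de_table()] result.
#' @param status_matrix an [expression_status_matrix()] result.
#' @param clinical clinical table aligned to the status columns.
#' @param q_threshold gate on q (default 0.001).
#' @param min_pct_difference percent-difference gate (default 20).
#' @param min_over_fraction overexpression frequency gate (default 0.05).
#' @param group race group for the overexpression gate (default "BAA").
#' @return list with character vectors `BAA_high`, `BAA_low`, `BAA_OVR`.
#' @export
classify_de_genes <- function(de, status_matrix, clinical,
                              q_threshold = 0.001, min_pct_difference = 20,
                              min_over_fraction = 0.05, group = "BAA") {
  if (!all(de$gene %in% rownames(status_matrix$status)))
    stop("DE table and status matrix cover different genes")
  fc_gate <- log2(1 + min_pct_difference / 100)
  high <- de$gene[de$q < q_threshold & de$log2_fc >= fc_gate]
  low <- de$gene[de$q < q_threshold & de$log2_fc <= -fc_gate]
  freq <- over_frequency(status_matrix, clinical, group)
  ovr <- high[!is.na(freq[high]) & freq[high] >= min_over_fraction]
  list(BAA_high = high, BAA_low = low, BAA_OVR = ovr)
}
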