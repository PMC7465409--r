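#' Fisher-exact overrepresentation of a query gene list in annotation sets
#'
#' One-sided hypergeometric upper-tail p per set, BH q across sets, and the
#' overrepresentation fold OVF = (k/n) / (K/N) where k = hits in the query,
#' n = query size, K = set size within the reference universe, N = universe
#' size.
#'
#' @param query character vector of gene ids (intersected with the universe).
#' @param sets named list of character vectors (intersected with the universe).
#' @param universe reference gene universe.
#' @return data.frame: set, k, n, K, N, ovf, p, q.
#' @export
fisher_overrepresentation <- function(query, sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  n <- length(query)
  N <- length(universe)
  res <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(query, sets[[nm]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ovf <- if (n > 0 && K > 0) (k / n) / (K / N) else 0
    data.frame(set = nm, k = k, n = n, K = K, N = N, ovf = ovf, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}

# Signal-to-noise scores for genes x (high, low) groups, with the GSEA-style
# per-group sd floor of 0.2 * |group mean|; a zero numerator scores 0.
s2n_scores <- function(x, high) {
  nh <- sum(high); nl <- sum(!high)
  xh <- x[, high, drop = FALSE]; xl <- x[, !high, drop = FALSE]
  mh <- rowMeans(xh); ml <- rowMeans(xl)
  sh <- sqrt(pmax(0, (rowSums(xh^2) - nh * mh^2) / (nh - 1)))
  sl <- sqrt(pmax(0, (rowSums(xl^2) - nl * ml^2) / (nl - 1)))
  sh <- pmax(sh, 0.2 * abs(mh))
  sl <- pmax(sl, 0.2 * abs(ml))
  num <- mh - ml
  den <- sh + sl
  ifelse(num == 0, 0, num / den)
}

#' Rank genes by signal-to-noise between expression-defined phenotypes
#'
#' High and Low phenotypes are the top and bottom `high_low_fraction` of
#' samples by the phenotype gene's expression; each gene is scored
#' (mu_High - mu_Low) / (sd_High + sd_Low) with per-group sd floored at
#' 0.2 |mu|, and genes are returned sorted by decreasing score.
#'
#' @param expression genes x samples matrix.
#' @param phenotype_gene gene id defining the phenotype.
#' @param high_low_fraction fraction per side (default 0.10).
#' @param min_per_side minimum samples per phenotype (default 3).
#' @return data.frame (gene, score) sorted decreasing, with attributes
#'   `high_samples` and `low_samples`.
#' @export
gsea_rank_genes <- function(expression, phenotype_gene,
                            high_low_fraction = 0.10, min_per_side = 3) {
  if (!phenotype_gene %in% rownames(expression))
    stop("phenotype gene not in expression matrix: ", phenotype_gene)
  n <- ncol(expression)
  n_side <- floor(high_low_fraction * n)
  if (n_side < min_per_side)
    stop("high/low fraction yields fewer than ", min_per_side,
         " samples per side")
  o <- order(expression[phenotype_gene, ], decreasing = TRUE)
  high <- o[seq_len(n_side)]
  low <- o[seq.int(n - n_side + 1, n)]
  sel <- c(high, low)
  scores <- s2n_scores(expression[, sel, drop = FALSE],
                       rep(c(TRUE, FALSE), each = n_side))
  ord <- order(-scores, rownames(expression))
  out <- data.frame(gene = rownames(expression)[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  attr(out, "high_samples") <- colnames(expression)[high]
  attr(out, "low_samples") <- colnames(expression)[low]
  out
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Hits increment the running sum by |score|^weight_exponent normalized by
#' the set's total; misses decrement by 1/(N - set size). The enrichment
#' score is the signed maximum deviation; the leading edge contains set
#' members at or before the peak (positive ES) or at or after it (negative).
#'
#' @param ranked data.frame (gene, score) sorted by decreasing score, as from
#'   [gsea_rank_genes()].
#' @param gene_set character vector of gene ids.
#' @param weight_exponent weighting exponent (default 1).
#' @return list with `es`, `peak_rank`, `leading_edge`, `size` (members found
#'   in the ranked list), `n` (list length).
#' @export
running_enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  pos <- sort(match(unique(gene_set), ranked$gene))
  pos <- pos[!is.na(pos)]
  k <- length(pos)
  if (k == 0) stop("gene set has empty intersection with the ranked list")
  n <- nrow(ranked)
  w <- abs(ranked$score[pos])^weight_exponent
  if (sum(w) == 0) w <- rep(1, k)
  cumw <- cumsum(w) / sum(w)
  if (k == n) {  # degenerate: every gene is a hit
    return(list(es = 1, peak_rank = n, leading_edge = ranked$gene,
                size = k, n = n))
  }
  miss <- 1 / (n - k)
  i <- seq_len(k)
  up <- cumw - (pos - i) * miss                 # value just after each hit
  low <- c(0, cumw[-k]) - (pos - i) * miss      # value just before each hit
  es_pos <- max(up)
  es_neg <- min(low)
  if (es_pos >= abs(es_neg)) {
    j <- which.max(up)
    list(es = es_pos, peak_rank = pos[j],
         leading_edge = ranked$gene[pos[seq_len(j)]], size = k, n = n)
  } else {
    j <- which.min(low)
    list(es = es_neg, peak_rank = pos[j] - 1,
         leading_edge = ranked$gene[pos[seq.int(j, k)]], size = k, n = n)
  }
}

#' Gene set enrichment analysis with phenotype permutation
#'
#' Ranks genes by signal-to-noise between expression-defined High/Low
#' phenotypes, computes weighted running-sum enrichment scores, and builds
#' the null by permuting the High/Low labels among the phenotype samples and
#' re-ranking the whole list per permutation. NES is ES divided by the mean
#' of same-sign permutation ES; p is the same-sign tail fraction (with the
#' +1 correction); FDR is the NES-based permutation estimate, with a BH
#' fallback on the permutation p-values.
#'
#' @param expression genes x samples matrix.
#' @param phenotype_gene gene id defining the phenotype.
#' @param gene_sets named list of character vectors.
#' @param high_low_fraction fraction per side (default 0.10).
#' @param weight_exponent hit-weight exponent (default 1).
#' @param n_permutations phenotype permutations (default 1000).
#' @param seed RNG seed.
#' @param fdr_method "permutation" (NES-based) or "bh".
#' @param min_per_side minimum samples per phenotype (default 3).
#' @return object of class `gsea_result`: list with `table` (set, size, es,
#'   nes, p, fdr), `leading_edges` (named list), `ranked`, and call metadata.
#' @export
gsea <- function(expression, phenotype_gene, gene_sets,
                 high_low_fraction = 0.10, weight_exponent = 1,
                 n_permutations = 1000, seed = 1L,
                 fdr_method = c("permutation", "bh"), min_per_side = 3) {
  fdr_method <- match.arg(fdr_method)
  set.seed(as.integer(seed))
  ranked <- gsea_rank_genes(expression, phenotype_gene, high_low_fraction,
                            min_per_side)
  obs <- stats::setNames(lapply(names(gene_sets), function(nm) {
    tryCatch(running_enrichment_score(ranked, gene_sets[[nm]], weight_exponent),
             error = function(e) stop("set '", nm, "': ", conditionMessage(e),
                                      call. = FALSE))
  }), names(gene_sets))
  sel <- c(attr(ranked, "high_samples"), attr(ranked, "low_samples"))
  n_side <- length(attr(ranked, "high_samples"))
  xs <- expression[, sel, drop = FALSE]
  set_rows <- lapply(gene_sets, function(s)
    which(rownames(expression) %in% s))
  n_genes <- nrow(expression)
  perm_es <- matrix(NA_real_, length(gene_sets), n_permutations,
                    dimnames = list(names(gene_sets), NULL))
  high_tpl <- rep(FALSE, length(sel))
  for (b in seq_len(n_permutations)) {
    high <- high_tpl
    high[sample.int(length(sel), n_side)] <- TRUE
    scores <- s2n_scores(xs, high)
    ord <- order(-scores, rownames(expression))
    rank_of <- integer(n_genes)
    rank_of[ord] <- seq_len(n_genes)
    sorted_abs_w <- abs(scores[ord])^weight_exponent
    for (si in seq_along(gene_sets)) {
      pos <- sort(rank_of[set_rows[[si]]])
      perm_es[si, b] <- es_from_positions(pos, sorted_abs_w, n_genes)
    }
  }
  es <- vapply(obs, `[[`, numeric(1), "es")
  nes <- rep(NA_real_, length(es))
  pval <- rep(NA_real_, length(es))
  nes_perm <- matrix(NA_real_, nrow(perm_es), ncol(perm_es))
  for (si in seq_along(es)) {
    pe <- perm_es[si, ]
    pos_mean <- mean(pe[pe > 0])
    neg_mean <- mean(abs(pe[pe < 0]))
    nes_perm[si, pe > 0] <- pe[pe > 0] / pos_mean
    nes_perm[si, pe < 0] <- pe[pe < 0] / neg_mean
    if (es[si] >= 0) {
      same <- pe[pe >= 0]
      pval[si] <- (1 + sum(same >= es[si])) / (1 + length(same))
      nes[si] <- if (is.finite(pos_mean) && pos_mean > 0) es[si] / pos_mean else NA_real_
    } else {
      same <- pe[pe < 0]
      pval[si] <- (1 + sum(same <= es[si])) / (1 + length(same))
      nes[si] <- if (is.finite(neg_mean) && neg_mean > 0) es[si] / neg_mean else NA_real_
    }
  }
  fdr <- if (fdr_method == "bh") bh_adjust(pval) else {
    pool <- nes_perm[!is.na(nes_perm)]
    vapply(seq_along(nes), function(si) {
      if (is.na(nes[si])) return(NA_real_)
      if (nes[si] >= 0) {
        num_pool <- pool[pool >= 0]
        num <- if (length(num_pool)) mean(num_pool >= nes[si]) else 0
        den_set <- nes[!is.na(nes) & nes >= 0]
        den <- mean(den_set >= nes[si])
      } else {
        num_pool <- pool[pool < 0]
        num <- if (length(num_pool)) mean(num_pool <= nes[si]) else 0
        den_set <- nes[!is.na(nes) & nes < 0]
        den <- mean(den_set <= nes[si])
      }
      if (den == 0) return(NA_real_)
      min(1, num / den)
    }, numeric(1))
  }
  table <- data.frame(set = names(gene_sets),
                      size = vapply(obs, `[[`, numeric(1), "size"),
                      es = es, nes = nes, p = pval, fdr = fdr,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = table,
                 leading_edges = lapply(obs, `[[`, "leading_edge"),
                 ranked = ranked,
                 phenotype_gene = phenotype_gene,
                 high_low_fraction = high_low_fraction,
                 weight_exponent = weight_exponent,
                 n_permutations = n_permutations,
                 fdr_method = fdr_method,
                 seed = as.integer(seed)),
            class = "gsea_result")
}

# ES from hit positions in a sorted list, given |score|^p of the sorted list.
es_from_positions <- function(pos, sorted_abs_w, n) {
  k <- length(pos)
  if (k == 0) return(NA_real_)
  if (k == n) return(1)
  w <- sorted_abs_w[pos]
  if (sum(w) == 0) w <- rep(1, k)
  cumw <- cumsum(w) / sum(w)
  miss <- 1 / (n - k)
  i <- seq_len(k)
  up <- cumw - (pos - i) * miss
  low <- c(0, cumw[-k]) - (pos - i) * miss
  es_pos <- max(up)
  es_neg <- min(low)
  if (es_pos >= abs(es_neg)) es_pos else es_neg
}

#' Union of leading-edge genes across significant sets
#'
#' @param gsea_result a [gsea()] result.
#' @param p_threshold permutation-p gate (default 0.05).
#' @return sorted, deduplicated character vector of core enrichment genes.
#' @export
core_enrichment_union <- function(gsea_result, p_threshold = 0.05) {
  stopifnot(inherits(gsea_result, "gsea_result"))
  keep <- gsea_result$table$set[!is.na(gsea_result$table$p) &
                                  gsea_result$table$p < p_threshold]
  out <- unlist(gsea_result$leading_edges[keep])
  if (is.null(out)) character(0) else sort(unique(out))
}
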