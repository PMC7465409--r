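# Independent oracles used across test files. These deliberately take the
# slow, direct route (enumeration, triple loops, closed forms) so they stay
# independent of the implementation they check.

# Two-sided rank-sum p by full enumeration of all group labelings.
enum_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w <- sum(r[seq_len(nx)])
  sums <- utils::combn(seq_along(pooled), nx,
                       FUN = function(idx) sum(r[idx]))
  min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
}

# Upper-tail hypergeometric p by direct summation of binomial coefficients.
enum_fisher_p <- function(k, K, N, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Topological overlap by the defining triple loop.
brute_tom <- function(a) {
  g <- nrow(a)
  k <- rowSums(a)
  tom <- diag(g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i == j) next
    l_ij <- sum(a[i, ] * a[, j])
    tom[i, j] <- (l_ij + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Full GSEA running sum walked position by position (oracle for the
# hits-only implementation).
walk_running_sum <- function(ranked, gene_set, p = 1) {
  hit <- ranked$gene %in% gene_set
  w <- abs(ranked$score)^p
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  inc <- w / sum(w)
  dec <- ifelse(hit, 0, 1 / sum(!hit))
  cumsum(inc - dec)
}

# Small random survival data.
random_surv <- function(n, rate = 0.1, p_event = 0.7) {
  list(times = stats::rexp(n, rate), events = stats::rbinom(n, 1, p_event))
}

# A tiny labeled mask with known content.
blank_mask <- function(h, w, fill = 2L) matrix(fill, h, w)
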