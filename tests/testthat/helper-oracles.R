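# Brute-force oracles, independent of the package implementation.

# linear-interpolation quantile written out from the order statistics
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  if (n == 1) return(s)
  h <- (n - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
}

# the six per-square statistics, computed from first principles
oracle_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(
    max = max(x),
    mean = m,
    median = oracle_quantile(x, 0.5),
    sd = if (n > 1) sqrt(sum((x - m)^2) / (n - 1)) else 0,
    iqr = oracle_quantile(x, 0.75) - oracle_quantile(x, 0.25))
}

# average ranks with ties, written out
oracle_ranks <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }
  r
}

# tie-corrected Kruskal-Wallis H from its definition
oracle_kw_h <- function(samples) {
  x <- unlist(samples)
  n <- length(x)
  r <- oracle_ranks(x)
  idx <- rep(seq_along(samples), lengths(samples))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(samples)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# exact permutation p-value of the KW statistic (all group relabelings)
oracle_kw_perm_p <- function(samples) {
  x <- unlist(samples)
  sizes <- lengths(samples)
  h_obs <- oracle_kw_h(samples)
  idx_all <- seq_along(x)
  count <- 0; total <- 0
  assign_rec <- function(remaining, sizes_left) {
    if (length(sizes_left) == 1) return(list(list(remaining)))
    picks <- utils::combn(remaining, sizes_left[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- assign_rec(setdiff(remaining, p), sizes_left[-1])
      for (r in rest) out[[length(out) + 1]] <- c(list(p), r)
    }
    out
  }
  for (asg in assign_rec(idx_all, sizes)) {
    g <- lapply(asg, function(ix) x[ix])
    total <- total + 1
    if (oracle_kw_h(g) >= h_obs - 1e-12) count <- count + 1
  }
  count / total
}

# exact permutation p-value of the two-sided rank-sum test
oracle_wilcoxon_perm_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  r_all <- oracle_ranks(all_v)
  w_obs <- sum(r_all[seq_len(n1)])
  mu <- n1 * (length(all_v) + 1) / 2
  subsets <- utils::combn(length(all_v), n1, simplify = FALSE)
  ws <- vapply(subsets, function(ix) sum(r_all[ix]), numeric(1))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Spearman rho as Pearson correlation of hand-computed average ranks
oracle_spearman_rho <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
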