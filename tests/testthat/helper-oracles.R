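# Brute-force oracles, independent of the package's implementations.

# Onnela weighted clustering by explicit enumeration of node triples,
# weights scaled by the maximum weight.
oracle_clustering <- function(w) {
  n <- nrow(w)
  wmax <- max(w)
  if (wmax == 0) return(rep(0, n))
  wn <- w / wmax
  k <- rowSums(w > 0)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      s <- s + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    }
    cc[i] <- s / (k[i] * (k[i] - 1))
  }
  cc
}

# all-pairs shortest paths by Floyd-Warshall on lengths 1/w
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_cpl <- function(w) {
  d <- oracle_distances(w)
  off <- d[upper.tri(d)]
  mean(off[is.finite(off)])
}

oracle_global_eff <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  d <- oracle_distances(w)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

oracle_local_eff <- function(w) {
  n <- nrow(w)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    eff[i] <- oracle_global_eff(w[nb, nb, drop = FALSE])
  }
  mean(eff)
}

# random symmetric nonnegative weight matrix with zero diagonal; the caller
# controls the RNG state
random_weight_matrix <- function(n, p_edge = 0.5) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- ifelse(runif(sum(ut)) < p_edge, runif(sum(ut), 0.1, 1), 0)
  w[ut] <- vals
  w + t(w)
}

# Pearson correlation by the explicit textbook sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
oracle_ranksum_exact_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n1)])
  combs <- combn(length(all_v), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(all_v) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

make_region_ts <- function(data, subject = "s1", group = "PBS", tr = 2) {
  region_ts(data, subject, group, tr_seconds = tr)
}
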