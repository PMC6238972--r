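test_that("low-pass restriction preserves DC, rejects cutoffs above Nyquist, and attenuates noise", {
  const <- make_region_ts(matrix(5, 50, 3))
  out <- lowpass_restrict(const, 0.1)
  expect_equal(out$data, const$data)

  ts <- make_region_ts(matrix(rnorm(300), 100, 3), tr = 2)
  expect_error(lowpass_restrict(ts, 0.25), class = "chemoconn_invalid_parameter")
  expect_error(lowpass_restrict(ts, 0.3), class = "chemoconn_invalid_parameter")

  set.seed(11)
  wn <- make_region_ts(matrix(rnorm(2000), 1000, 2), tr = 2)
  sm <- lowpass_restrict(wn, 0.1)
  expect_lt(var(sm$data[, 1]), var(wn$data[, 1]))
  # periodogram oracle: power above the cutoff must drop
  pow_above <- function(x, cutoff, tr) {
    sp <- Mod(fft(x - mean(x)))^2
    f <- seq(0, 1 / tr, length.out = length(x) + 1)[seq_along(x)]
    sum(sp[f > cutoff & f < 1 / (2 * tr)])
  }
  expect_lt(pow_above(sm$data[, 1], 0.1, 2),
            0.5 * pow_above(wn$data[, 1], 0.1, 2))
})

test_that("correlation matrix matches the textbook Pearson formula and flags degenerate regions", {
  x <- matrix(rnorm(30), 10, 3)
  ts <- make_region_ts(cbind(x, x[, 1], -x[, 2]))
  cm <- correlation_matrix(ts)
  expect_equal(cm$r[1, 4], 1)
  expect_equal(cm$r[2, 5], -1)
  expect_equal(unname(diag(cm$r)), rep(0, 5))
  expect_equal(cm$r, t(cm$r))

  set.seed(2)
  m <- matrix(sample(1:9, 40, replace = TRUE), 10, 4)
  m <- m + matrix(rnorm(40, 0, 0.01), 10, 4)   # break exact ties
  cm2 <- correlation_matrix(make_region_ts(m))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(cm2$r[i, j], oracle_pearson(m[, i], m[, j]),
                 tolerance = 1e-12)

  bad <- make_region_ts(cbind(rnorm(10), rep(1, 10)))
  err <- tryCatch(correlation_matrix(bad), error = identity)
  expect_s3_class(err, "chemoconn_degenerate_region")
  expect_match(conditionMessage(err), "R02")
})

test_that("negative edges are zeroed and density counts positive correlations exactly", {
  r <- matrix(-0.5, 4, 4); diag(r) <- 0
  cm <- structure(list(r = r, region_labels = letters[1:4]),
                  class = "connectivity_matrix")
  net <- to_weighted_network(cm)
  expect_equal(net$E, 0)
  expect_equal(net$D, 0)

  r1 <- matrix(1, 4, 4); diag(r1) <- 0
  net1 <- to_weighted_network(structure(list(r = r1, region_labels = letters[1:4]),
                                        class = "connectivity_matrix"))
  expect_equal(net1$E, 6)
  expect_equal(net1$D, 1)

  set.seed(3)
  r2 <- matrix(0, 5, 5)
  r2[upper.tri(r2)] <- runif(10, -1, 1)
  r2 <- r2 + t(r2)
  net2 <- to_weighted_network(structure(list(r = r2, region_labels = letters[1:5]),
                                        class = "connectivity_matrix"))
  expect_equal(net2$D, sum(r2[upper.tri(r2)] > 0) / 10)
  expect_true(all(net2$w >= 0))
})

test_that("nodal clustering matches triple-enumeration oracle", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(nodal_clustering(weighted_network(tri))$clustering),
               rep(1, 3))

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(unname(nodal_clustering(weighted_network(star))$clustering),
               rep(0, 5))

  set.seed(42)
  for (i in 1:5) {
    w <- random_weight_matrix(8)
    expect_equal(unname(nodal_clustering(weighted_network(w))$clustering),
                 oracle_clustering(w), tolerance = 1e-12)
  }
})

test_that("characteristic path length matches Floyd-Warshall and handles disconnection", {
  cw <- matrix(1, 5, 5); diag(cw) <- 0
  expect_equal(characteristic_path_length(weighted_network(cw))$L, 1)

  pw <- matrix(0, 3, 3)
  pw[1, 2] <- pw[2, 1] <- pw[2, 3] <- pw[3, 2] <- 1
  res <- characteristic_path_length(weighted_network(pw))
  expect_equal(res$L, 4 / 3)
  expect_equal(res$unreachable_pairs, 0)

  set.seed(7)
  for (i in 1:5) {
    w <- random_weight_matrix(10, p_edge = 0.4)
    if (all(is.infinite(oracle_distances(w)[upper.tri(w)]))) next
    expect_equal(characteristic_path_length(weighted_network(w))$L,
                 oracle_cpl(w), tolerance = 1e-12)
  }

  empty <- weighted_network(matrix(0, 4, 4))
  expect_error(characteristic_path_length(empty),
               class = "chemoconn_undefined_metric")
})

test_that("global and local efficiency match oracles", {
  expect_equal(global_efficiency(weighted_network(matrix(0, 4, 4))), 0)
  cw <- matrix(1, 6, 6); diag(cw) <- 0
  expect_equal(global_efficiency(weighted_network(cw)), 1)

  set.seed(13)
  for (i in 1:5) {
    w <- random_weight_matrix(8)
    net <- weighted_network(w)
    expect_equal(global_efficiency(net), oracle_global_eff(w),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(net), oracle_local_eff(w),
                 tolerance = 1e-12)
  }
})

test_that("null networks preserve size, density, and degree sequence; complete graphs are rigid", {
  cw <- matrix(runif(36, 0.2, 1), 6, 6)
  cw <- (cw + t(cw)) / 2; diag(cw) <- 0
  net <- weighted_network(cw)
  nulls <- null_networks(net, 3, 5, seed = 1)
  for (nn in nulls) {
    expect_equal(nn$N, net$N)
    expect_equal(nn$E, net$E)
    expect_equal(nn$D, net$D)
    # complete topology cannot be swapped
    expect_equal(nn$w > 0, net$w > 0)
  }

  set.seed(5)
  w <- random_weight_matrix(10, p_edge = 0.3)
  net2 <- weighted_network(w)
  nulls2 <- null_networks(net2, 4, 10, seed = 9)
  for (nn in nulls2) {
    expect_equal(sort(rowSums(nn$w > 0)), sort(rowSums(net2$w > 0)))
    expect_equal(rowSums(nn$w > 0), rowSums(net2$w > 0))
    expect_equal(sort(nn$w[upper.tri(nn$w) & nn$w > 0]),
                 sort(net2$w[upper.tri(net2$w) & net2$w > 0]))
  }
  # deterministic given seed
  nulls3 <- null_networks(net2, 4, 10, seed = 9)
  expect_identical(lapply(nulls2, `[[`, "w"), lapply(nulls3, `[[`, "w"))
})

test_that("self-normalization gives gamma = lambda = sigma = 1", {
  set.seed(8)
  w <- random_weight_matrix(9)
  net <- weighted_network(w)
  gm <- global_metrics(net, nulls = list(net))
  expect_equal(gm$gamma, 1)
  expect_equal(gm$lambda, 1)
  expect_equal(gm$sigma, 1)
  expect_equal(gm$D, net$D)
})

test_that("density thresholding keeps the top edges deterministically", {
  set.seed(21)
  w <- random_weight_matrix(8)
  net <- weighted_network(w)
  same <- threshold_to_density(net, net$D)
  expect_equal(same$w, net$w)

  cw <- matrix(1, 4, 4); diag(cw) <- 0
  th <- threshold_to_density(weighted_network(cw), 0.5)
  expect_equal(th$E, 3)

  # duplicate weights: result must be identical across calls
  wd <- matrix(0, 5, 5)
  wd[upper.tri(wd)] <- rep(c(0.5, 0.9), 5)
  wd <- wd + t(wd)
  netd <- weighted_network(wd)
  t1 <- threshold_to_density(netd, 0.4)
  t2 <- threshold_to_density(netd, 0.4)
  expect_identical(t1$w, t2$w)
  expect_equal(t1$E, floor(0.4 * 10))
  # surviving weights are the largest ones
  expect_true(min(t1$w[t1$w > 0]) >= max(wd) - 1e-9 ||
                sum(t1$w[upper.tri(t1$w)] > 0) == 4)

  expect_error(threshold_to_density(netd, netd$D + 0.1),
               class = "chemoconn_invalid_parameter")
})

test_that("relabeling invariance: permuting nodes permutes nodal metrics and fixes global ones", {
  set.seed(31)
  w <- random_weight_matrix(9)
  net <- weighted_network(w, letters[1:9])
  perm <- sample(9)
  netp <- weighted_network(w[perm, perm], letters[1:9][perm])
  expect_equal(unname(nodal_clustering(netp)$clustering),
               unname(nodal_clustering(net)$clustering[perm]))
  expect_equal(characteristic_path_length(netp)$L,
               characteristic_path_length(net)$L)
  expect_equal(global_efficiency(netp), global_efficiency(net))
  expect_equal(local_efficiency(netp), local_efficiency(net))
  expect_equal(netp$D, net$D)
})

test_that("gamma, lambda, sigma are invariant to uniform weight scaling", {
  set.seed(17)
  w <- random_weight_matrix(9)
  net <- weighted_network(w)
  net2 <- weighted_network(w * 3.7)
  gm1 <- global_metrics(net, n_nulls = 5, seed = 4)
  gm2 <- global_metrics(net2, n_nulls = 5, seed = 4)
  expect_equal(gm1$gamma, gm2$gamma, tolerance = 1e-10)
  expect_equal(gm1$lambda, gm2$lambda, tolerance = 1e-10)
  expect_equal(gm1$sigma, gm2$sigma, tolerance = 1e-10)
})

test_that("adding an edge never increases L and never decreases global efficiency", {
  set.seed(19)
  for (i in 1:5) {
    w <- random_weight_matrix(8, p_edge = 0.4)
    net <- weighted_network(w)
    if (net$E == 0) next
    zero <- which(upper.tri(w) & w == 0, arr.ind = TRUE)
    if (nrow(zero) == 0) next
    pick <- zero[sample.int(nrow(zero), 1), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- runif(1, 0.1, 1)
    net2 <- weighted_network(w2)
    d1 <- oracle_distances(w); d2 <- oracle_distances(w2)
    # every pairwise distance shrinks or stays; the mean over the pairs
    # already reachable cannot increase
    expect_true(all(d2 <= d1 + 1e-12))
    fin <- is.finite(d1[upper.tri(d1)])
    if (any(fin))
      expect_lte(mean(d2[upper.tri(d2)][fin]) -
                   mean(d1[upper.tri(d1)][fin]), 1e-9)
    expect_gte(global_efficiency(net2) - global_efficiency(net), -1e-12)
  }
})

test_that("network_from_ts chains band-limiting, correlation, and zeroing", {
  set.seed(23)
  ts <- make_region_ts(matrix(rnorm(600), 100, 6))
  net <- network_from_ts(ts, cutoff_hz = 0.1)
  expect_s3_class(net, "weighted_network")
  expect_equal(net$N, 6)
  expect_true(all(net$w >= 0))
  raw <- network_from_ts(ts, cutoff_hz = NULL)
  expect_equal(raw$w, pmax(correlation_matrix(ts)$r, 0),
               ignore_attr = TRUE)
})
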