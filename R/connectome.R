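#' Regional time-series container
#'
#' Holds one subject's preprocessed regional signal matrix (timepoints in
#' rows, brain regions in columns) together with its group label and sampling
#' interval (TR). This is the unit of input for connectome construction.
#'
#' @param data numeric matrix, timepoints x regions; no missing values and at
#'   least 3 timepoints.
#' @param subject_id character scalar.
#' @param group character scalar group label.
#' @param region_labels character vector of unique region names; defaults to
#'   the column names of `data` or `R01`, `R02`, ...
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @return An object of class `region_ts`.
#' @export
region_ts <- function(data, subject_id, group,
                      region_labels = colnames(data), tr_seconds = 2) {
  data <- as.matrix(data)
  if (anyNA(data)) stop_chemoconn("time series contains missing values",
                                  class = "chemoconn_invalid_input")
  if (nrow(data) < 3L)
    stop_chemoconn("time series needs at least 3 timepoints",
                   class = "chemoconn_invalid_input")
  if (is.null(region_labels))
    region_labels <- sprintf("R%02d", seq_len(ncol(data)))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != ncol(data) || anyDuplicated(region_labels))
    stop_chemoconn("region labels must be unique, one per column",
                   class = "chemoconn_invalid_input")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop_chemoconn("tr_seconds must be a positive duration",
                   class = "chemoconn_invalid_input")
  colnames(data) <- region_labels
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group),
                 data = data, region_labels = region_labels,
                 tr_seconds = as.numeric(tr_seconds)),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> subject %s (%s): %d timepoints x %d regions, TR = %g s\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data),
              x$tr_seconds))
  invisible(x)
}

#' Restrict a regional time series to the low-frequency band
#'
#' Intrinsic functional networks live below 0.1 Hz; this applies a
#' moving-average smoother whose window spans one period of the cutoff
#' frequency (`ceiling(1 / (cutoff_hz * tr_seconds))` samples), attenuating
#' power above the cutoff while preserving series length and region labels.
#' Edges use partial windows so constant signals pass through unchanged.
#'
#' @param ts a [region_ts()] object.
#' @param cutoff_hz cutoff frequency in Hz; must be below the Nyquist
#'   frequency `1 / (2 * tr_seconds)`.
#' @return A `region_ts` with smoothed data.
#' @export
lowpass_restrict <- function(ts, cutoff_hz = 0.1) {
  stopifnot(inherits(ts, "region_ts"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || cutoff_hz <= 0 ||
      cutoff_hz >= nyquist)
    stop_chemoconn(sprintf(
      "cutoff_hz must lie in (0, Nyquist = %g Hz) for TR = %g s",
      nyquist, ts$tr_seconds), class = "chemoconn_invalid_parameter")
  window <- ceiling(1 / (cutoff_hz * ts$tr_seconds))
  ts$data <- apply(ts$data, 2, moving_average, window = window)
  colnames(ts$data) <- ts$region_labels
  ts
}

#' Pearson correlation matrix of a regional time series
#'
#' Computes the region-by-region Pearson correlation matrix (the 62x62 matrix
#' of the original acquisition, for any number of regions). The diagonal is
#' stored as 0, never 1: self-edges must not enter edge counts, density, or
#' clustering downstream.
#'
#' @param ts a [region_ts()] object; every region must have nonzero variance.
#' @return An object of class `connectivity_matrix` with elements `r`
#'   (symmetric, zero diagonal, entries in \[-1, 1\]) and `region_labels`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  v <- apply(ts$data, 2, var)
  if (any(v == 0))
    stop_chemoconn("zero-variance region(s): ",
                   paste(ts$region_labels[v == 0], collapse = ", "),
                   class = "chemoconn_degenerate_region")
  r <- cor(ts$data)
  diag(r) <- 0
  structure(list(r = r, region_labels = ts$region_labels),
            class = "connectivity_matrix")
}

#' Weighted network container
#'
#' A symmetric nonnegative edge-weight matrix with zero diagonal — the unit
#' of all graph computation. Edge count `E` counts nonzero upper-triangle
#' entries and density is `D = E / (N * (N - 1) / 2)`.
#'
#' @param w symmetric nonnegative numeric matrix with zero diagonal.
#' @param region_labels optional node labels.
#' @return An object of class `weighted_network` with elements `w`,
#'   `region_labels`, `N`, `E`, `D`.
#' @export
weighted_network <- function(w, region_labels = colnames(w)) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w) || !isTRUE(all.equal(w, t(w), tolerance = 1e-12)))
    stop_chemoconn("weight matrix must be symmetric",
                   class = "chemoconn_invalid_input")
  if (any(diag(w) != 0))
    stop_chemoconn("weight matrix must have a zero diagonal",
                   class = "chemoconn_invalid_input")
  if (any(w < 0))
    stop_chemoconn("weights must be nonnegative",
                   class = "chemoconn_invalid_input")
  w <- (w + t(w)) / 2
  if (is.null(region_labels))
    region_labels <- sprintf("R%02d", seq_len(ncol(w)))
  dimnames(w) <- list(region_labels, region_labels)
  N <- nrow(w)
  E <- sum(w[upper.tri(w)] > 0)
  structure(list(w = w, region_labels = as.character(region_labels),
                 N = N, E = E, D = if (N > 1) E / (N * (N - 1) / 2) else 0),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> N = %d nodes, E = %d edges, D = %.3f\n",
              x$N, x$E, x$D))
  invisible(x)
}

#' Convert a correlation matrix to a weighted functional network
#'
#' Negative functional edges are zeroed (negative-correlation networks have
#' different properties and are excluded from this analysis); positive
#' weights are kept as-is with no magnitude thresholding, giving a fully
#' weighted network.
#'
#' @param cm a [correlation_matrix()] result.
#' @return A [weighted_network()].
#' @export
to_weighted_network <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  weighted_network(pmax(cm$r, 0), cm$region_labels)
}

#' Per-node weighted clustering coefficients
#'
#' Uses the geometric-mean-of-triangle-weights (Onnela) formulation on
#' weights normalized by the maximum weight; nodes with binary degree below 2
#' get 0. This is the default weighted clustering of the standard brain
#' connectivity toolboxes.
#'
#' @param net a [weighted_network()].
#' @return An object of class `nodal_metrics`: list with `clustering` (named
#'   numeric, one value >= 0 per region) and `region_labels`.
#' @export
nodal_clustering <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$w
  wmax <- max(w)
  k <- rowSums(w > 0)
  if (wmax == 0) {
    cc <- rep(0, net$N)
  } else {
    w3 <- (w / wmax)^(1 / 3)
    cyc <- diag(w3 %*% w3 %*% w3)
    cc <- ifelse(k < 2, 0, cyc / (k * (k - 1)))
  }
  names(cc) <- net$region_labels
  structure(list(clustering = cc, region_labels = net$region_labels),
            class = "nodal_metrics")
}

#' @export
print.nodal_metrics <- function(x, ...) {
  cat(sprintf("<nodal_metrics> clustering for %d regions (mean %.4f)\n",
              length(x$clustering), mean(x$clustering)))
  invisible(x)
}

# shortest-path distance matrix with edge lengths 1/w
distance_matrix <- function(w) {
  dist_shortest_cpp(as.matrix(w))
}

#' Characteristic path length
#'
#' Maps each edge weight to a length `1/w`, computes all-pairs shortest
#' paths, and averages the finite off-diagonal distances. Disconnected pairs
#' are excluded from the mean and reported as a count rather than forcing L
#' to infinity on sparse networks.
#'
#' @param net a [weighted_network()].
#' @return List with `L` (mean finite shortest-path distance) and
#'   `unreachable_pairs` (count of unordered node pairs with no path).
#' @export
characteristic_path_length <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  d <- distance_matrix(net$w)
  off <- d[upper.tri(d)]
  finite <- is.finite(off)
  if (!any(finite))
    stop_chemoconn("characteristic path length undefined: no connected pair",
                   class = "chemoconn_undefined_metric")
  list(L = mean(off[finite]), unreachable_pairs = sum(!finite))
}

#' Global and local efficiency
#'
#' Global efficiency is the mean over ordered node pairs of the inverse
#' shortest-path distance (with `1/Inf = 0`), so it is robust to
#' disconnection. Local efficiency averages, over nodes, the global
#' efficiency of each node's neighborhood subgraph; nodes with fewer than two
#' neighbors contribute 0. An empty network has efficiency 0.
#'
#' @param net a [weighted_network()].
#' @return A single nonnegative number.
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  if (net$N < 2) return(0)
  d <- distance_matrix(net$w)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (net$N * (net$N - 1))
}

#' @rdname global_efficiency
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$w
  eff <- vapply(seq_len(net$N), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(weighted_network(w[nb, nb, drop = FALSE],
                                       net$region_labels[nb]))
  }, numeric(1))
  mean(eff)
}

#' Degree-preserving null networks
#'
#' Randomizes the binary topology by double-edge swaps that preserve every
#' node's degree, then reshuffles the original edge weights among the
#' surviving edges. Node count, edge count, density, and the binary degree
#' sequence are preserved exactly. A complete graph admits no swap and is
#' returned with its topology intact.
#'
#' @param net a [weighted_network()] with at least 2 edges.
#' @param n_nulls number of null networks.
#' @param iterations_per_edge swap attempts per edge (total attempts =
#'   `iterations_per_edge * E`).
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return List of `weighted_network` objects. If a non-rigid topology
#'   yielded no successful swap within the attempt budget, those nulls are
#'   dropped, a warning is raised, and the attribute `swap_failures` records
#'   the count.
#' @export
null_networks <- function(net, n_nulls = 20, iterations_per_edge = 10,
                          seed = 1) {
  stopifnot(inherits(net, "weighted_network"))
  if (net$E < 2)
    stop_chemoconn("null networks need at least 2 edges",
                   class = "chemoconn_invalid_input")
  ut <- which(upper.tri(net$w) & net$w > 0, arr.ind = TRUE)
  weights <- net$w[upper.tri(net$w)][net$w[upper.tri(net$w)] > 0]
  complete <- net$E == net$N * (net$N - 1) / 2
  with_seed(seed, {
    nulls <- list()
    failures <- 0L
    for (b in seq_len(n_nulls)) {
      edges <- ut  # E x 2, i < j
      adj <- net$w > 0
      swapped <- 0L
      if (!complete) {
        attempts <- iterations_per_edge * net$E
        for (it in seq_len(attempts)) {
          pick <- sample.int(net$E, 2)
          a <- edges[pick[1], ]; b2 <- edges[pick[2], ]
          # random orientation of the second edge
          if (runif(1) < 0.5) b2 <- rev(b2)
          n1 <- sort(c(a[1], b2[2])); n2 <- sort(c(b2[1], a[2]))
          if (n1[1] == n1[2] || n2[1] == n2[2]) next
          if (adj[n1[1], n1[2]] || adj[n2[1], n2[2]]) next
          adj[a[1], a[2]] <- adj[a[2], a[1]] <- FALSE
          adj[b2[1], b2[2]] <- adj[b2[2], b2[1]] <- FALSE
          adj[n1[1], n1[2]] <- adj[n1[2], n1[1]] <- TRUE
          adj[n2[1], n2[2]] <- adj[n2[2], n2[1]] <- TRUE
          edges[pick[1], ] <- n1
          edges[pick[2], ] <- n2
          swapped <- swapped + 1L
        }
        if (swapped == 0L) { failures <- failures + 1L; next }
      }
      wnull <- matrix(0, net$N, net$N)
      wsh <- sample(weights)
      for (e in seq_len(nrow(edges))) {
        wnull[edges[e, 1], edges[e, 2]] <- wsh[e]
        wnull[edges[e, 2], edges[e, 1]] <- wsh[e]
      }
      nulls[[length(nulls) + 1L]] <- weighted_network(wnull,
                                                      net$region_labels)
    }
    if (failures > 0L)
      warning(sprintf("%d null(s) dropped: no successful swap in budget",
                      failures))
    attr(nulls, "swap_failures") <- failures
    nulls
  })
}

#' Global connectome metrics with null-model normalization
#'
#' Computes the five global measures reported per subject: mean weighted
#' clustering C, characteristic path length L, normalized clustering
#' `gamma = C / C_rand`, normalized path length `lambda = L / L_rand`,
#' small-worldness index `sigma = gamma / lambda`, global and local
#' efficiency, and density D. Normalization references are degree-preserving
#' rewired nulls ([null_networks()]); their count and seed are recorded in
#' the result so group comparisons can verify identical null settings.
#'
#' @param net a [weighted_network()].
#' @param n_nulls number of null networks (>= 1).
#' @param iterations_per_edge swap intensity, see [null_networks()].
#' @param seed RNG seed for the nulls.
#' @param nulls optional precomputed list of null networks (overrides
#'   generation; used mainly for testing the normalization identity).
#' @return An object of class `global_metrics` with fields `C`, `L`, `gamma`,
#'   `lambda`, `sigma`, `E_glob`, `E_loc`, `D`, `unreachable_pairs`,
#'   `n_nulls`, `null_seed`.
#' @export
global_metrics <- function(net, n_nulls = 20, iterations_per_edge = 10,
                           seed = 1, nulls = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (is.null(nulls)) {
    if (!is_count(n_nulls) || n_nulls < 1)
      stop_chemoconn("n_nulls must be a positive count",
                     class = "chemoconn_invalid_parameter")
    nulls <- null_networks(net, n_nulls, iterations_per_edge, seed)
  }
  C <- mean(nodal_clustering(net)$clustering)
  pl <- characteristic_path_length(net)
  C_rand <- mean(vapply(nulls, function(nn)
    mean(nodal_clustering(nn)$clustering), numeric(1)))
  L_rand <- mean(vapply(nulls, function(nn)
    characteristic_path_length(nn)$L, numeric(1)))
  gamma <- C / C_rand
  lambda <- pl$L / L_rand
  structure(list(C = C, L = pl$L, gamma = gamma, lambda = lambda,
                 sigma = gamma / lambda,
                 E_glob = global_efficiency(net),
                 E_loc = local_efficiency(net),
                 D = net$D, unreachable_pairs = pl$unreachable_pairs,
                 n_nulls = length(nulls), null_seed = seed),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat("<global_metrics>\n")
  cat(sprintf("  C = %.4f  L = %.4f  D = %.3f\n", x$C, x$L, x$D))
  cat(sprintf("  gamma = %.3f  lambda = %.3f  sigma = %.3f (%d nulls, seed %d)\n",
              x$gamma, x$lambda, x$sigma, x$n_nulls, x$null_seed))
  cat(sprintf("  E_glob = %.4f  E_loc = %.4f  unreachable pairs = %d\n",
              x$E_glob, x$E_loc, x$unreachable_pairs))
  invisible(x)
}

#' Threshold a weighted network to a target density
#'
#' Retains the top-weighted edges so that the result has exactly
#' `floor(target_density * N * (N - 1) / 2)` edges; ties are broken by
#' lexicographic node-pair order for determinism, and surviving edges keep
#' their weights. Used to bring every subject in a cohort down to the density
#' of the sparsest subject before nodal comparison ("minimum connection
#' density").
#'
#' @param net a [weighted_network()].
#' @param target_density fraction in `(0, D]` where `D` is the input density.
#' @return A [weighted_network()] at the target density.
#' @export
threshold_to_density <- function(net, target_density) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is.numeric(target_density) || length(target_density) != 1L ||
      target_density <= 0 || target_density > net$D + 1e-12)
    stop_chemoconn(sprintf(
      "target density must lie in (0, %.4f], the current density",
      net$D), class = "chemoconn_invalid_parameter")
  m <- floor(target_density * net$N * (net$N - 1) / 2)
  idx <- which(upper.tri(net$w) & net$w > 0, arr.ind = TRUE)
  wts <- net$w[idx]
  ord <- order(-wts, idx[, 1], idx[, 2])
  keep <- ord[seq_len(min(m, length(ord)))]
  wnew <- matrix(0, net$N, net$N)
  wnew[idx[keep, , drop = FALSE]] <- wts[keep]
  wnew <- wnew + t(wnew)
  weighted_network(wnew, net$region_labels)
}

#' Build a weighted network from a regional time series
#'
#' Convenience chain: low-pass restriction, Pearson correlation, zeroing of
#' negative edges.
#'
#' @param ts a [region_ts()].
#' @param cutoff_hz low-pass cutoff in Hz; `NULL` skips band-limiting (for
#'   data already restricted upstream).
#' @return A [weighted_network()].
#' @export
network_from_ts <- function(ts, cutoff_hz = 0.1) {
  if (!is.null(cutoff_hz)) ts <- lowpass_restrict(ts, cutoff_hz)
  to_weighted_network(correlation_matrix(ts))
}

#' Per-subject global metrics table for a cohort
#'
#' Runs [network_from_ts()] and [global_metrics()] over a list of subjects
#' and assembles the per-subject metrics table consumed by the group
#' statistics (one row per subject: C, L, gamma, lambda, sigma, E_glob,
#' E_loc, D, unreachable_pairs). All subjects share the same null settings.
#'
#' @param ts_list list of [region_ts()] objects.
#' @param n_nulls,iterations_per_edge,seed null-model settings, see
#'   [global_metrics()].
#' @param cutoff_hz passed to [network_from_ts()].
#' @return A data.frame, one row per subject.
#' @export
cohort_global_metrics <- function(ts_list, n_nulls = 20,
                                  iterations_per_edge = 10, seed = 1,
                                  cutoff_hz = 0.1) {
  rows <- lapply(ts_list, function(ts) {
    net <- network_from_ts(ts, cutoff_hz)
    gm <- global_metrics(net, n_nulls, iterations_per_edge, seed)
    data.frame(subject_id = ts$subject_id, group = ts$group,
               C = gm$C, L = gm$L, gamma = gm$gamma, lambda = gm$lambda,
               sigma = gm$sigma, E_glob = gm$E_glob, E_loc = gm$E_loc,
               D = gm$D, unreachable_pairs = gm$unreachable_pairs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Nodal clustering at the cohort's minimum connection density
#'
#' Thresholds every subject's network down to the density of the sparsest
#' subject, then computes per-region weighted clustering, so that nodal
#' comparisons are not confounded by subject-level edge-count differences.
#'
#' @param ts_list list of [region_ts()] objects.
#' @param cutoff_hz passed to [network_from_ts()].
#' @return List with `clustering` (subjects x regions matrix, rownames =
#'   subject ids), `design` (data.frame subject_id, group), and
#'   `min_density`.
#' @export
cohort_nodal_clustering <- function(ts_list, cutoff_hz = 0.1) {
  nets <- lapply(ts_list, network_from_ts, cutoff_hz = cutoff_hz)
  dmin <- min(vapply(nets, function(n) n$D, numeric(1)))
  cc <- t(vapply(nets, function(n)
    nodal_clustering(threshold_to_density(n, dmin))$clustering,
    numeric(nets[[1]]$N)))
  rownames(cc) <- vapply(ts_list, function(t) t$subject_id, character(1))
  list(clustering = cc,
       design = data.frame(
         subject_id = rownames(cc),
         group = vapply(ts_list, function(t) t$group, character(1)),
         stringsAsFactors = FALSE),
       min_density = dmin)
}
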