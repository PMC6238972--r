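#' Synthetic cohort specification
#'
#' Describes a synthetic chemobrain cohort: group sizes and labels, the
#' dimensions of the regional time series (62 regions, 450 volumes, TR = 2 s
#' by default, mirroring the original acquisition), the injected group
#' effects, and the seed. The group labels carry meaning: `"Cisplatin"`
#' receives the full injected effect, `"Cisplatin+MSC"` receives the effect
#' scaled by `1 - rescue_fraction`, and all other labels (controls) receive
#' none.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param groups character group labels.
#' @param n_regions number of brain regions (>= 4).
#' @param n_timepoints volumes per subject.
#' @param tr_seconds repetition time in seconds.
#' @param path_length_effect fractional reduction of latent characteristic
#'   path length in the Cisplatin group (0.15 = 15 percent shorter); must lie
#'   in `[0, 0.9]` — the randomization mechanism only shortens paths.
#' @param rescue_fraction fraction of every injected effect reversed in the
#'   Cisplatin+MSC group, in `[0, 1]` (1 = full rescue, the observed
#'   outcome).
#' @param noise_sd observation noise standard deviation relative to unit
#'   latent signal variance.
#' @param seed integer seed; identical specs produce identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 8,
                        groups = c("PBS", "Cisplatin", "MSC",
                                   "Cisplatin+MSC"),
                        n_regions = 62, n_timepoints = 450, tr_seconds = 2,
                        path_length_effect = 0.15, rescue_fraction = 1,
                        noise_sd = 0.5, seed = 1) {
  if (!is_count(n_per_group) || n_per_group < 2)
    stop_chemoconn("n_per_group must be a count >= 2",
                   class = "chemoconn_invalid_spec")
  if (!is_count(n_regions) || n_regions < 4)
    stop_chemoconn("n_regions must be a count >= 4",
                   class = "chemoconn_invalid_spec")
  if (!is_count(n_timepoints) || n_timepoints < 3)
    stop_chemoconn("n_timepoints must be a count >= 3",
                   class = "chemoconn_invalid_spec")
  if (rescue_fraction < 0 || rescue_fraction > 1)
    stop_chemoconn("rescue_fraction must lie in [0, 1]",
                   class = "chemoconn_invalid_spec")
  if (path_length_effect < 0 || path_length_effect > 0.9)
    stop_chemoconn("path_length_effect must lie in [0, 0.9]",
                   class = "chemoconn_invalid_spec")
  if (anyDuplicated(groups))
    stop_chemoconn("group labels must be unique",
                   class = "chemoconn_invalid_spec")
  if (!is_count(seed))
    stop_chemoconn("seed must be an integer",
                   class = "chemoconn_invalid_spec")
  structure(list(n_per_group = as.integer(n_per_group),
                 groups = as.character(groups),
                 n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = as.numeric(tr_seconds),
                 path_length_effect = as.numeric(path_length_effect),
                 rescue_fraction = as.numeric(rescue_fraction),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d x %d subjects [%s], %d regions x %d volumes (TR %g s)\n",
              length(x$groups), x$n_per_group,
              paste(x$groups, collapse = ", "),
              x$n_regions, x$n_timepoints, x$tr_seconds))
  cat(sprintf("  path_length_effect = %g, rescue_fraction = %g, noise_sd = %g, seed = %d\n",
              x$path_length_effect, x$rescue_fraction, x$noise_sd, x$seed))
  invisible(x)
}

# fraction of the full injected effect a group receives
group_effect_scale <- function(group, spec) {
  if (group == "Cisplatin") 1
  else if (group == "Cisplatin+MSC") 1 - spec$rescue_fraction
  else 0
}

subject_ids <- function(spec, group) {
  sprintf("%s_%02d", group, seq_len(spec$n_per_group))
}

# Latent correlation structure per group.
#
# A Watts-Strogatz small-world backbone (k = 6 neighbors, rewiring p = 0.05)
# carries uniform random edge weights; a weak uniform background
# ANTIcorrelation (eps0 < 0) sits on all non-backbone pairs, as denoised
# resting-state correlation matrices show (the analysis pipeline zeroes
# negative edges, which keeps measured network density in a realistic
# 0.3-0.5 range and preserves small-world organization of the measured
# graphs). The covariance is the Gram
# construction (I + alpha * (W + eps0 cross-links))^2 plus observation-noise
# variance on the diagonal — positive definite by construction, with
# backbone correlations in the 0.3-0.7 range typical of strong resting-state
# functional edges and genuine weaker two-hop correlations.
#
# Groups receiving a path-length effect gain strong cross-links between the
# currently most DISTANT region pairs — aberrant long-range couplings
# between normally segregated systems, the Watts-Strogatz shortcut move
# toward a more random, noisy, hyperconnected network — added greedily one
# at a time until the network's measured characteristic path length falls
# to (1 - scale x effect) of the control value. Greedy farthest-pair
# placement makes each link maximally effective, so only a handful (< ~20
# out of ~N^2/2 pairs) are needed and the expected sample density moves by
# little, keeping the injected effect from being a density artifact.
# Calibration targets the EXPECTED MEASURED path length — the mean L the
# analysis pipeline recovers from sample correlations of `n_timepoints`
# band-limited volumes, evaluated by a common-random-number Monte Carlo
# proxy that is deterministic given the spec seed — because finite-sample
# correlation noise floors the measured path length, and an effect injected
# only into the unobservable latent metric would be partially compressed.
# Link sequences are nested, so a partially rescued group uses a prefix of
# the full-effect sequence. Expected measured L, latent L, and the expected
# sample density (Fisher-z tail at the effective volume count) per group
# are reported in the ground truth.
latent_structure <- function(spec, eps0 = -0.04, alpha = 0.7,
                             link_weight = 0.95, max_links = 80L,
                             mc_reps = 3L) {
  n <- spec$n_regions
  with_seed(spec$seed, {
    nei <- max(1L, min(3L, (n - 1L) %/% 2L))
    g <- igraph::simplify(igraph::sample_smallworld(1, n, nei = nei,
                                                    p = 0.02))
    A_bin <- as.matrix(igraph::as_adjacency_matrix(g))
    wts <- matrix(0, n, n)
    ut <- upper.tri(wts)
    nw <- sum(A_bin[ut])
    wvals <- runif(nw, 0.35, 0.85)
    wts[ut][A_bin[ut] == 1] <- wvals
    wts <- wts + t(wts)
    corr_of <- function(W, a = alpha, e = eps0) {
      M <- diag(n) + a * (W + e * ((W == 0) & !diag(n)))
      sigma <- M %*% M + spec$noise_sd^2 * diag(n)
      if (inherits(tryCatch(chol(sigma), error = function(er) er), "error"))
        stop_chemoconn(
          "latent covariance not positive definite (degenerate construction)",
          class = "chemoconn_not_positive_definite")
      cov2cor(sigma)
    }
    L_of_R <- function(R) {
      diag(R) <- 0
      characteristic_path_length(weighted_network(pmax(R, 0)))$L
    }
    window <- ceiling(1 / (0.1 * spec$tr_seconds))
    # effective sample count of the band-limited series (moving-average
    # autocorrelation inflates correlation variance), for the expected
    # sample density
    infl <- 1 + 2 * sum(((window - seq_len(window - 1)) / window)^2)
    t_eff <- max(spec$n_timepoints / infl, 8)
    dens_of <- function(R) {
      z <- atanh(pmin(R[ut], 0.999)) * sqrt(t_eff - 3)
      mean(stats::pnorm(z))
    }
    scales <- vapply(spec$groups, group_effect_scale, numeric(1),
                     spec = spec)
    any_effect <- any(scales > 0) && spec$path_length_effect > 0
    # common-random-number draws for the measured-L proxy (calibration
    # only; subject data are drawn later from an independent stream)
    Zs <- if (any_effect)
      lapply(seq_len(mc_reps), function(i)
        matrix(rnorm(spec$n_timepoints * n), spec$n_timepoints, n))
    measured_L <- function(R) {
      U <- chol(R)
      mean(vapply(Zs, function(Z) {
        X <- apply(Z %*% U, 2, moving_average, window = window)
        r <- cor(X)
        diag(r) <- 0
        characteristic_path_length(weighted_network(pmax(r, 0)))$L
      }, numeric(1)))
    }
    L0h <- if (any_effect) measured_L(corr_of(wts)) else NA_real_
    D0 <- dens_of(corr_of(wts))
    # build the nested greedy link sequence once, toward the deepest
    # target, recording the measured-L proxy after each addition
    deepest <- if (any_effect)
      (1 - max(scales) * spec$path_length_effect) * L0h else Inf
    link_seq <- matrix(integer(0), 0, 2)
    L_path <- L0h
    if (any_effect && deepest < L0h) {
      W_cur <- wts
      repeat {
        R <- corr_of(W_cur)
        diag(R) <- 0
        dm <- distance_matrix(pmax(R, 0))
        dm[lower.tri(dm, diag = TRUE)] <- -Inf
        mx <- max(dm[is.finite(dm)])
        far <- which(dm == mx, arr.ind = TRUE)[1, ]
        W_cur[far[1], far[2]] <- W_cur[far[2], far[1]] <- link_weight
        link_seq <- rbind(link_seq, far)
        L_path[nrow(link_seq) + 1L] <- measured_L(corr_of(W_cur))
        if (min(L_path) <= deepest) break
        if (nrow(link_seq) >= max_links)
          stop_chemoconn(sprintf(
            "cannot reach requested path-length reduction (floor %.3f, target %.3f after %d links)",
            min(L_path), deepest, max_links),
            class = "chemoconn_invalid_spec")
      }
    }
    with_links <- function(k) {
      W <- wts
      if (k > 0) for (i in seq_len(k))
        W[link_seq[i, 1], link_seq[i, 2]] <-
          W[link_seq[i, 2], link_seq[i, 1]] <- link_weight
      W
    }
    structs <- lapply(seq_along(spec$groups), function(gi) {
      s <- scales[gi]
      k_g <- 0L
      target <- NA_real_
      if (s > 0 && spec$path_length_effect > 0) {
        target <- (1 - s * spec$path_length_effect) * L0h
        # cummin: the proxy is noisy per step; stop at the first k whose
        # running minimum reaches the target
        k_g <- which(cummin(L_path) <= target)[1] - 1L
      }
      R <- corr_of(with_links(k_g))
      Rnet <- R; diag(Rnet) <- 0
      net <- weighted_network(pmax(Rnet, 0), sprintf("R%02d", seq_len(n)))
      list(R = R, network = net, n_cross_links = k_g,
           expected_measured_L = if (is.na(target)) L0h else target,
           expected_L = L_of_R(R), expected_density = dens_of(R))
    })
    names(structs) <- spec$groups
    list(backbone_weights = wts, eps0 = eps0, groups = structs,
         n_cross_links = vapply(structs, function(x)
           as.numeric(x$n_cross_links), numeric(1)),
         expected_measured_L = vapply(structs, `[[`, numeric(1),
                                      "expected_measured_L"),
         expected_L = vapply(structs, `[[`, numeric(1), "expected_L"),
         expected_density = vapply(structs, `[[`, numeric(1),
                                   "expected_density"),
         baseline_density = D0)
  })
}

#' Generate synthetic regional time series for a cohort
#'
#' Draws each subject's timepoints-by-regions matrix from its group's latent
#' correlation structure: a weighted small-world backbone with weak
#' background anticorrelations, plus — in cisplatin-exposed groups — a
#' calibrated number of strong random cross-links so that the path length
#' the analysis pipeline measures from sample correlations falls by
#' `path_length_effect` relative to controls: a hyperconnected, more
#' random-looking network. Samples are temporally smoothed with a moving
#' average spanning one period of 0.1 Hz so the signal is band-limited the
#' way preprocessed resting-state data are. Identical specs give
#' byte-identical outputs.
#'
#' @param spec a [cohort_spec()].
#' @return List with `timeseries` (list of [region_ts()], one per subject)
#'   and `ground_truth` (latent networks, cross-link weights, expected
#'   latent path length per group).
#' @export
generate_timeseries <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  latent <- latent_structure(spec)
  window <- ceiling(1 / (0.1 * spec$tr_seconds))
  ts_list <- list()
  with_seed(spec$seed + 1L, {
    for (gr in spec$groups) {
      U <- chol(latent$groups[[gr]]$R)
      for (sid in subject_ids(spec, gr)) {
        Z <- matrix(rnorm(spec$n_timepoints * spec$n_regions),
                    spec$n_timepoints, spec$n_regions)
        X <- Z %*% U
        X <- apply(X, 2, moving_average, window = window)
        ts_list[[sid]] <- region_ts(
          X, sid, gr, sprintf("R%02d", seq_len(spec$n_regions)),
          spec$tr_seconds)
      }
    }
  })
  list(timeseries = ts_list, ground_truth = latent)
}

#' Generate synthetic behavioral event tables
#'
#' Produces, per subject: the 11 puzzle box escape times on the fixed
#' day/difficulty schedule with an additive delay on the difficult trials
#' for cisplatin-exposed groups; novel/familiar object interaction times
#' whose discrimination index is centered at 0 for Cisplatin (no novelty
#' preference) and at 0.3 for controls; and a Y-maze arm-entry sequence over
#' `{A, B, C}` without immediate self-reentry whose perfect-alternation
#' probability is 0.7 in controls and 0.5 (chance) under cisplatin.
#' `rescue_fraction` moves the Cisplatin+MSC group toward the controls; at 1
#' its distributions equal the control distributions.
#'
#' @param spec a [cohort_spec()].
#' @return List of data.frames `pbt` (subject_id, group, day, trial_index,
#'   difficulty, escape_time), `noprt` (subject_id, group, t_novel,
#'   t_familiar), `ymaze` (subject_id, group, entries as a string).
#' @export
generate_behavior <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sched <- pbt_schedule()
  tier_median <- c(easy = 15, intermediate = 40, difficult = 80)
  difficult_delay <- 60   # seconds added on difficult trials at full effect
  di_control <- 0.3
  q_control <- 0.7; q_deficit <- 0.2
  with_seed(spec$seed + 2L, {
    pbt <- list(); noprt <- list(); ymaze <- list()
    for (gr in spec$groups) {
      s <- group_effect_scale(gr, spec)
      for (sid in subject_ids(spec, gr)) {
        base <- rlnorm(11, meanlog = log(tier_median[sched$difficulty]),
                       sdlog = 0.4)
        delay <- ifelse(sched$difficulty == "difficult",
                        difficult_delay * s, 0)
        pbt[[length(pbt) + 1L]] <- data.frame(
          subject_id = sid, group = gr, day = sched$day,
          trial_index = sched$trial_index, difficulty = sched$difficulty,
          escape_time = base + delay, stringsAsFactors = FALSE)
        di <- di_control * (1 - s)
        m_f <- 15
        m_n <- m_f * (1 + di) / (1 - di)
        noprt[[length(noprt) + 1L]] <- data.frame(
          subject_id = sid, group = gr,
          t_novel = rgamma(1, shape = 9, rate = 9 / m_n),
          t_familiar = rgamma(1, shape = 9, rate = 9 / m_f),
          stringsAsFactors = FALSE)
        q <- q_control - q_deficit * s
        n_entries <- 3L + rpois(1, 22)
        arms <- c("A", "B", "C")
        e <- character(n_entries)
        e[1] <- sample(arms, 1)
        e[2] <- sample(setdiff(arms, e[1]), 1)
        for (k in 3:n_entries) {
          third <- setdiff(arms, c(e[k - 2], e[k - 1]))
          e[k] <- if (runif(1) < q) third else e[k - 2]
        }
        ymaze[[length(ymaze) + 1L]] <- data.frame(
          subject_id = sid, group = gr,
          entries = paste(e, collapse = ""), stringsAsFactors = FALSE)
      }
    }
    list(pbt = do.call(rbind, pbt), noprt = do.call(rbind, noprt),
         ymaze = do.call(rbind, ymaze))
  })
}

#' Generate synthetic assay tables
#'
#' Produces the non-behavioral endpoints with the group structure observed
#' in the study: four-phase OCR traces in which cisplatin lowers the FCCP
#' (maximal) plateau but not baseline respiration; mitochondrial
#' width/opacity rows with an elevated atypical fraction under cisplatin;
#' tumor diameter triples growing over time with a cisplatin growth delay
#' (unaffected by MSC); and a pair of differential-expression tables with a
#' configurable number of reversed genes for the overlap-and-reversal set
#' logic.
#'
#' @param spec a [cohort_spec()].
#' @param n_up_reversed,n_down_reversed,n_same_direction counts of
#'   overlapping significant genes injected as up-reversed, down-reversed,
#'   and same-direction (defaults 45, 30, 30, the structure of the reported
#'   overlap).
#' @param n_cis_only,n_msc_only,n_null counts of genes significant in only
#'   one contrast or in neither.
#' @return List of data.frames `ocr`, `mito`, `tumor`, `de_cis`, `de_msc`.
#' @export
generate_assays <- function(spec, n_up_reversed = 45, n_down_reversed = 30,
                            n_same_direction = 30, n_cis_only = 285,
                            n_msc_only = 1230, n_null = 200) {
  stopifnot(inherits(spec, "cohort_spec"))
  phases <- c("baseline", "oligomycin", "fccp", "rot_aa")
  phase_mean <- c(baseline = 100, oligomycin = 40, fccp = 180, rot_aa = 15)
  fccp_drop <- 55   # OCR units removed from the FCCP plateau at full effect
  atyp_base <- 0.08; atyp_gain <- 0.27
  with_seed(spec$seed + 3L, {
    ocr <- list(); mito <- list(); tumor <- list()
    for (gr in spec$groups) {
      s <- group_effect_scale(gr, spec)
      cis_exposed <- gr %in% c("Cisplatin", "Cisplatin+MSC")
      for (sid in subject_ids(spec, gr)) {
        mu <- phase_mean
        mu["fccp"] <- mu["fccp"] - fccp_drop * s
        ocr[[length(ocr) + 1L]] <- data.frame(
          subject_id = sid, group = gr,
          time = seq_len(12), ocr = rnorm(12, rep(mu, each = 3), 3),
          phase = rep(phases, each = 3), stringsAsFactors = FALSE)
        p_atyp <- atyp_base + atyp_gain * s
        atyp <- runif(40) < p_atyp
        mito[[length(mito) + 1L]] <- data.frame(
          subject_id = sid, group = gr, mito_id = seq_len(40),
          width = ifelse(atyp, runif(40, 310, 450), runif(40, 150, 290)),
          opacity = ifelse(atyp, runif(40, 20, 45), runif(40, 55, 90)),
          stringsAsFactors = FALSE)
        days <- seq(7, 27, by = 4)
        rate <- if (cis_exposed) 0.04 else 0.10   # per-day growth
        d0 <- runif(1, 2.5, 3.5)
        for (day in days) {
          d <- d0 * exp(rate * (day - 7)) * exp(rnorm(3, 0, 0.05))
          tumor[[length(tumor) + 1L]] <- data.frame(
            subject_id = sid, group = gr, day = day,
            d1 = d[1], d2 = d[2], d3 = d[3], stringsAsFactors = FALSE)
        }
      }
    }
    n_genes <- n_up_reversed + n_down_reversed + n_same_direction +
      n_cis_only + n_msc_only + n_null
    gene_id <- sprintf("G%05d", seq_len(n_genes))
    sig_p <- function(n) runif(n, 0, 0.049)
    null_p <- function(n) runif(n, 0.051, 1)
    lfc <- function(n, sign) sign * runif(n, 0.5, 2)
    set <- rep(c("up_reversed", "down_reversed", "same_direction",
                 "cis_only", "msc_only", "null"),
               c(n_up_reversed, n_down_reversed, n_same_direction,
                 n_cis_only, n_msc_only, n_null))
    same_sign <- sample(c(-1, 1), n_same_direction, replace = TRUE)
    sgn_cis <- numeric(n_genes); sgn_msc <- numeric(n_genes)
    sgn_cis[set == "up_reversed"] <- 1
    sgn_msc[set == "up_reversed"] <- -1
    sgn_cis[set == "down_reversed"] <- -1
    sgn_msc[set == "down_reversed"] <- 1
    sgn_cis[set == "same_direction"] <- same_sign
    sgn_msc[set == "same_direction"] <- same_sign
    other <- set %in% c("cis_only", "msc_only", "null")
    sgn_cis[other] <- sample(c(-1, 1), sum(other), replace = TRUE)
    sgn_msc[other] <- sample(c(-1, 1), sum(other), replace = TRUE)
    p_cis <- ifelse(set %in% c("up_reversed", "down_reversed",
                               "same_direction", "cis_only"),
                    sig_p(n_genes), null_p(n_genes))
    p_msc <- ifelse(set %in% c("up_reversed", "down_reversed",
                               "same_direction", "msc_only"),
                    sig_p(n_genes), null_p(n_genes))
    de_cis <- data.frame(gene_id = gene_id,
                         log2_fold_change = lfc(n_genes, sgn_cis),
                         adjusted_p = p_cis, stringsAsFactors = FALSE)
    de_msc <- data.frame(gene_id = gene_id,
                         log2_fold_change = lfc(n_genes, sgn_msc),
                         adjusted_p = p_msc, stringsAsFactors = FALSE)
    list(ocr = do.call(rbind, ocr), mito = do.call(rbind, mito),
         tumor = do.call(rbind, tumor), de_cis = de_cis, de_msc = de_msc)
  })
}

#' Generate a full synthetic cohort
#'
#' Runs [generate_timeseries()], [generate_behavior()], and
#' [generate_assays()] under one spec.
#'
#' @param spec a [cohort_spec()].
#' @param ... passed to [generate_assays()].
#' @return List with `spec`, `timeseries`, `ground_truth`, `behavior`,
#'   `assays`.
#' @export
generate_cohort <- function(spec, ...) {
  ts <- generate_timeseries(spec)
  list(spec = spec, timeseries = ts$timeseries,
       ground_truth = ts$ground_truth,
       behavior = generate_behavior(spec),
       assays = generate_assays(spec, ...))
}

#' Write a synthetic cohort to plain delimited text
#'
#' Writes `timeseries/<subject>.tsv` (timepoints x regions with a header row
#' of region labels), `behavior/{pbt,noprt,ymaze}.tsv`,
#' `assays/{ocr,mito,tumor,de_cis,de_msc}.tsv`, and a `manifest.yaml`
#' echoing the spec and seed.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  for (sub in c("timeseries", "behavior", "assays"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort$timeseries)
    write_tsv(as.data.frame(ts$data),
              file.path(dir, "timeseries", paste0(ts$subject_id, ".tsv")))
  for (nm in names(cohort$behavior))
    write_tsv(cohort$behavior[[nm]],
              file.path(dir, "behavior", paste0(nm, ".tsv")))
  for (nm in names(cohort$assays))
    write_tsv(cohort$assays[[nm]],
              file.path(dir, "assays", paste0(nm, ".tsv")))
  sp <- cohort$spec
  write_flat_yaml(list(
    n_per_group = sp$n_per_group, groups = sp$groups,
    n_regions = sp$n_regions, n_timepoints = sp$n_timepoints,
    tr_seconds = sp$tr_seconds,
    path_length_effect = sp$path_length_effect,
    rescue_fraction = sp$rescue_fraction, noise_sd = sp$noise_sd,
    seed = sp$seed), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a regional time-series TSV
#'
#' Reads a timepoints-by-regions table as written by [write_cohort()] (or
#' any same-shape delimited file with a header row of region labels).
#'
#' @param path file path.
#' @param subject_id,group labels for the subject.
#' @param tr_seconds sampling interval in seconds.
#' @return A [region_ts()].
#' @export
read_region_ts <- function(path, subject_id, group, tr_seconds = 2) {
  df <- read_tsv(path)
  region_ts(as.matrix(df), subject_id, group, colnames(df), tr_seconds)
}
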