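#' Apply the small-worldness inclusion rule
#'
#' Subjects whose small-worldness index is strictly below 1 lack small-world
#' organization and are excluded from group analysis with a machine-readable
#' reason; a subject at exactly sigma = 1 is included. Requires all metrics
#' to have been computed under identical null-model settings.
#'
#' @param metrics data.frame as produced by [cohort_global_metrics()] (needs
#'   columns `subject_id`, `group`, `sigma`, `D`).
#' @return A group-design data.frame: `subject_id`, `group`, `density`,
#'   `included`, `exclusion_reason`.
#' @export
apply_exclusion <- function(metrics) {
  need <- c("subject_id", "group", "sigma", "D")
  if (!all(need %in% names(metrics)))
    stop_chemoconn("metrics must have columns ",
                   paste(need, collapse = ", "),
                   class = "chemoconn_invalid_input")
  excluded <- metrics$sigma < 1
  data.frame(subject_id = metrics$subject_id, group = metrics$group,
             density = metrics$D, included = !excluded,
             exclusion_reason = ifelse(excluded, "small_worldness_lt_1",
                                       NA_character_),
             stringsAsFactors = FALSE)
}

#' Density-covaried group comparison of a connectome metric
#'
#' Fits `metric ~ group + density` by ordinary least squares and tests the
#' categorical group term by extra-sum-of-squares F against the density-only
#' model — individual variation in network density confounds connectome
#' metrics, so density enters as a covariate. Adjusted group means are the
#' model predictions at the grand mean density.
#'
#' @param values numeric per-subject metric, aligned with `design` rows.
#' @param design group-design data.frame from [apply_exclusion()] (columns
#'   `group`, `density`, `included`); only included subjects are analyzed.
#' @param effect name of the metric for reporting.
#' @return An object of class `test_result` with fields `effect`,
#'   `statistic`, `statistic_kind = "F"`, `df`, `p_value`, and `groups`
#'   (data.frame: group, n, mean, sem, adj_mean).
#' @export
glm_group_test <- function(values, design, effect = "metric") {
  stopifnot(length(values) == nrow(design))
  keep <- design$included & !is.na(values)
  v <- values[keep]
  g <- factor(design$group[keep])
  d <- design$density[keep]
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2))
    stop_chemoconn("need at least 2 groups with at least 2 included subjects each",
                   class = "chemoconn_invalid_design")
  X <- model.matrix(~ g + d)
  if (qr(X)$rank < ncol(X))
    stop_chemoconn("singular design: density is collinear with group",
                   class = "chemoconn_collinear_design")
  full <- lm(v ~ g + d)
  reduced <- lm(v ~ d)
  an <- anova(reduced, full)
  Fstat <- an$F[2]
  p <- an$`Pr(>F)`[2]
  newd <- data.frame(g = factor(levels(g), levels = levels(g)),
                     d = mean(d))
  adj <- predict(full, newdata = newd)
  groups <- data.frame(
    group = levels(g), n = as.integer(tab),
    mean = as.numeric(tapply(v, g, mean)),
    sem = as.numeric(tapply(v, g, function(x) sd(x) / sqrt(length(x)))),
    adj_mean = as.numeric(adj), stringsAsFactors = FALSE)
  structure(list(effect = effect, statistic = Fstat, statistic_kind = "F",
                 df = c(an$Df[2], an$Res.Df[2]), p_value = p,
                 groups = groups),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: %s = %.4g", x$effect, x$statistic_kind,
              x$statistic))
  if (!is.null(x$df)) cat(sprintf(" (df %s)", paste(x$df, collapse = ", ")))
  cat(sprintf(", p = %.4g\n", x$p_value))
  if (!is.null(x$groups)) {
    for (i in seq_len(nrow(x$groups)))
      cat(sprintf("  %s: n = %d, mean = %.4g +/- %.4g\n",
                  x$groups$group[i], x$groups$n[i], x$groups$mean[i],
                  x$groups$sem[i]))
  }
  invisible(x)
}

#' Per-region rank-sum comparison of nodal clustering
#'
#' Two-sided Wilcoxon rank-sum test of each region's clustering coefficient
#' between two groups, on values computed at matched (minimum) connection
#' density. P-values are exact for small samples without ties and use the
#' tie-corrected normal approximation otherwise; no multiplicity correction
#' is applied by default (per-region raw p-values are reported, mirroring
#' the original regional table), with Benjamini-Hochberg available as an
#' option. Regions are returned sorted by ascending p.
#'
#' @param nodal subjects x regions matrix of clustering values (rownames =
#'   subject ids) as from [cohort_nodal_clustering()].
#' @param design group-design data.frame (columns `subject_id`, `group`,
#'   `included`).
#' @param group_a,group_b group labels to compare.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame: `region`, `statistic` (rank-sum W), `p_value`,
#'   `tied` (all values identical), and `p_adjusted` when requested.
#' @export
nodal_ranksum <- function(nodal, design, group_a, group_b,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  design <- design[design$included, ]
  ia <- design$subject_id[design$group == group_a]
  ib <- design$subject_id[design$group == group_b]
  if (length(ia) == 0 || length(ib) == 0)
    stop_chemoconn("both groups must be non-empty",
                   class = "chemoconn_invalid_design")
  a <- nodal[match(ia, rownames(nodal)), , drop = FALSE]
  b <- nodal[match(ib, rownames(nodal)), , drop = FALSE]
  res <- lapply(seq_len(ncol(nodal)), function(j) {
    x <- a[, j]; y <- b[, j]
    if (length(unique(c(x, y))) == 1L)
      return(data.frame(region = colnames(nodal)[j], statistic = NA_real_,
                        p_value = 1, tied = TRUE,
                        stringsAsFactors = FALSE))
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    data.frame(region = colnames(nodal)[j],
               statistic = unname(wt$statistic), p_value = wt$p.value,
               tied = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") out$p_adjusted <- p.adjust(out$p_value, "BH")
  out[order(out$p_value), ]
}

#' Two-factor ANOVA with Tukey post hoc contrasts
#'
#' Fits the 2x2 factorial (chemotherapy x treatment) analysis of variance
#' used for behavioral and assay endpoints: main effects and interaction F
#' tests, plus Tukey honest-significant-difference contrasts for all six
#' pairwise cell comparisons with studentized-range q statistics and
#' adjusted p-values.
#'
#' @param values numeric outcome per subject.
#' @param factor_cisplatin,factor_msc logical (or coercible) flags per
#'   subject; each of the four cells needs at least 2 subjects.
#' @return List with `main_cisplatin`, `main_msc`, `interaction` (each a
#'   `test_result` with F and p) and `tukey` (data.frame: contrast, diff, q,
#'   p_adjusted, significant at alpha = 0.05).
#' @export
factorial_anova_tukey <- function(values, factor_cisplatin, factor_msc) {
  cis <- factor(ifelse(as.logical(factor_cisplatin), "cisplatin", "control"),
                levels = c("control", "cisplatin"))
  msc <- factor(ifelse(as.logical(factor_msc), "msc", "vehicle"),
                levels = c("vehicle", "msc"))
  keep <- !is.na(values)
  values <- values[keep]; cis <- cis[keep]; msc <- msc[keep]
  cells <- table(cis, msc)
  if (any(cells < 2) || length(cells) != 4)
    stop_chemoconn("each of the 4 cells needs at least 2 subjects",
                   class = "chemoconn_invalid_design")
  fit <- aov(values ~ cis * msc)
  sm <- summary(fit)[[1]]
  tr <- function(row, nm) structure(
    list(effect = nm, statistic = sm$`F value`[row], statistic_kind = "F",
         df = c(sm$Df[row], sm$Df[4]), p_value = sm$`Pr(>F)`[row],
         groups = NULL),
    class = "test_result")
  cell <- interaction(cis, msc, sep = ":")
  fit_cell <- aov(values ~ cell)
  tk <- TukeyHSD(fit_cell)$cell
  mse <- sum(residuals(fit_cell)^2) / fit_cell$df.residual
  ns <- table(cell)
  pairs <- strsplit(rownames(tk), "-")
  qstat <- vapply(seq_along(pairs), function(i) {
    ni <- ns[pairs[[i]][1]]; nj <- ns[pairs[[i]][2]]
    abs(tk[i, "diff"]) / sqrt(mse / 2 * (1 / ni + 1 / nj))
  }, numeric(1))
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      q = qstat, p_adjusted = tk[, "p adj"],
                      significant = tk[, "p adj"] < 0.05,
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(main_cisplatin = tr(1, "cisplatin"), main_msc = tr(2, "msc"),
       interaction = tr(3, "cisplatin:msc"), tukey = tukey)
}
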