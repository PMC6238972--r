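#' Mitochondrial stress-test respiratory capacities
#'
#' Summarizes an oxygen consumption rate (OCR) trace from the four-phase
#' mitochondrial stress test (baseline, oligomycin, FCCP, rotenone +
#' antimycin A). All values are corrected for non-mitochondrial oxygen
#' consumption, taken as the post-rotenone/antimycin plateau:
#' `basal = mean(baseline) - non_mito`, `max = mean(fccp) - non_mito`,
#' `src = max - basal` (spare respiratory capacity). The FCCP phase can
#' optionally be summarized by its maximum measurement instead of the mean.
#'
#' @param trace data.frame with columns `time`, `ocr`, `phase`; `phase`
#'   values must be among `baseline`, `oligomycin`, `fccp`, `rot_aa`, each
#'   present at least once and appearing in that order.
#' @param fccp_stat `"mean"` (default) or `"max"` summary of the FCCP phase.
#' @return An object of class `respiratory_metrics`: list with `basal`,
#'   `max`, `src`, `non_mito`.
#' @export
respiratory_metrics <- function(trace, fccp_stat = c("mean", "max")) {
  fccp_stat <- match.arg(fccp_stat)
  phases <- c("baseline", "oligomycin", "fccp", "rot_aa")
  if (!all(c("time", "ocr", "phase") %in% names(trace)))
    stop_chemoconn("trace must have columns time, ocr, phase",
                   class = "chemoconn_invalid_input")
  for (p in phases)
    if (!any(trace$phase == p))
      stop_chemoconn("missing phase: ", p,
                     class = "chemoconn_missing_phase")
  trace <- trace[order(trace$time), ]
  ord <- match(unique(trace$phase), phases)
  if (is.unsorted(ord) || anyNA(ord))
    stop_chemoconn("phases must appear in order baseline, oligomycin, fccp, rot_aa",
                   class = "chemoconn_invalid_input")
  non_mito <- mean(trace$ocr[trace$phase == "rot_aa"])
  basal <- mean(trace$ocr[trace$phase == "baseline"]) - non_mito
  mx <- if (fccp_stat == "mean") mean(trace$ocr[trace$phase == "fccp"])
        else max(trace$ocr[trace$phase == "fccp"])
  mx <- mx - non_mito
  structure(list(basal = basal, max = mx, src = mx - basal,
                 non_mito = non_mito),
            class = "respiratory_metrics")
}

#' @export
print.respiratory_metrics <- function(x, ...) {
  cat(sprintf("<respiratory_metrics> basal = %.2f, max = %.2f, SRC = %.2f (non-mito %.2f)\n",
              x$basal, x$max, x$src, x$non_mito))
  invisible(x)
}

#' Classify mitochondria as typical or atypical
#'
#' Atypical mitochondria are those with width strictly greater than 300 nm
#' AND opacity strictly below 50 percent; both thresholds are boundaries
#' excluded (a 300 nm wide or 50 percent opaque mitochondrion is typical).
#'
#' @param rows data.frame with columns `width` (nm, > 0) and `opacity`
#'   (percent, in \[0, 100\]).
#' @return List with `flags` (the input with a logical `atypical` column),
#'   `percent_atypical` (`NA` for empty input), and `defined`.
#' @export
classify_mitochondria <- function(rows) {
  if (!all(c("width", "opacity") %in% names(rows)))
    stop_chemoconn("rows must have columns width, opacity",
                   class = "chemoconn_invalid_input")
  if (nrow(rows) == 0)
    return(list(flags = cbind(rows, atypical = logical(0)),
                percent_atypical = NA_real_, defined = FALSE))
  if (any(rows$width <= 0) || any(rows$opacity < 0 | rows$opacity > 100))
    stop_chemoconn("width must be > 0 and opacity in [0, 100]",
                   class = "chemoconn_invalid_input")
  rows$atypical <- rows$width > 300 & rows$opacity < 50
  list(flags = rows, percent_atypical = 100 * mean(rows$atypical),
       defined = TRUE)
}

#' Ellipsoid tumor volume from three orthogonal diameters
#'
#' `volume = (pi / 6) * d1 * d2 * d3` in cubic millimeters; reduces to the
#' sphere volume when all diameters are equal.
#'
#' @param d1,d2,d3 positive diameters in mm (vectorized).
#' @return Volumes in cubic millimeters.
#' @export
tumor_volume <- function(d1, d2, d3) {
  if (any(d1 <= 0) || any(d2 <= 0) || any(d3 <= 0))
    stop_chemoconn("tumor diameters must be positive",
                   class = "chemoconn_invalid_input")
  (pi / 6) * d1 * d2 * d3
}

#' Overlap-and-reversal logic for two differential-expression contrasts
#'
#' Given the chemotherapy-versus-control table and the treatment-versus-
#' chemotherapy table, finds genes significant in both (the overlap) and
#' splits them into up-reversed (increased by the insult, reduced by the
#' treatment), down-reversed (the mirror), and same-direction genes. The
#' counts satisfy `overlap = up_reversed + down_reversed + same_direction`
#' exactly.
#'
#' @param de_cis,de_msc data.frames with columns `gene_id` (unique),
#'   `log2_fold_change`, `adjusted_p` (in \[0, 1\]).
#' @param alpha significance threshold on the adjusted p-value (default
#'   0.05).
#' @return List with gene-id vectors `overlap`, `up_reversed`,
#'   `down_reversed`, `same_direction`, a per-gene membership data.frame
#'   `genes`, and a named integer vector `counts`.
#' @export
de_reversal_sets <- function(de_cis, de_msc, alpha = 0.05) {
  check_de <- function(de, nm) {
    if (!all(c("gene_id", "log2_fold_change", "adjusted_p") %in% names(de)))
      stop_chemoconn(nm, " must have columns gene_id, log2_fold_change, adjusted_p",
                     class = "chemoconn_invalid_input")
    if (anyDuplicated(de$gene_id))
      stop_chemoconn(nm, ": duplicated gene ids",
                     class = "chemoconn_invalid_input")
    if (any(de$adjusted_p < 0 | de$adjusted_p > 1))
      stop_chemoconn(nm, ": adjusted p-values must lie in [0, 1]",
                     class = "chemoconn_invalid_input")
  }
  check_de(de_cis, "de_cis"); check_de(de_msc, "de_msc")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_chemoconn("alpha must lie in (0, 1)",
                   class = "chemoconn_invalid_parameter")
  s_cis <- de_cis$gene_id[de_cis$adjusted_p < alpha]
  s_msc <- de_msc$gene_id[de_msc$adjusted_p < alpha]
  overlap <- intersect(s_cis, s_msc)
  lfc_cis <- de_cis$log2_fold_change[match(overlap, de_cis$gene_id)]
  lfc_msc <- de_msc$log2_fold_change[match(overlap, de_msc$gene_id)]
  up <- overlap[lfc_cis > 0 & lfc_msc < 0]
  down <- overlap[lfc_cis < 0 & lfc_msc > 0]
  same <- setdiff(overlap, c(up, down))
  genes <- data.frame(
    gene_id = overlap,
    lfc_cis = lfc_cis, lfc_msc = lfc_msc,
    set = ifelse(overlap %in% up, "up_reversed",
                 ifelse(overlap %in% down, "down_reversed",
                        "same_direction")),
    stringsAsFactors = FALSE)
  list(overlap = overlap, up_reversed = up, down_reversed = down,
       same_direction = same, genes = genes,
       counts = c(overlap = length(overlap), up_reversed = length(up),
                  down_reversed = length(down),
                  same_direction = length(same)))
}

#' Aggregate read counts per respiratory-chain complex
#'
#' Sums per-gene read counts within each annotated complex (complex I, III,
#' IV, ATP synthase, rRNA) of the mitochondrially encoded genes, producing
#' the per-complex totals compared by one-way ANOVA downstream.
#'
#' @param counts named numeric vector of per-gene read counts.
#' @param complex_map named character vector mapping gene name to complex
#'   label; every mapped gene must be present in `counts`.
#' @return Named numeric vector of per-complex summed reads.
#' @export
mito_complex_aggregate <- function(counts, complex_map) {
  missing <- setdiff(names(complex_map), names(counts))
  if (length(missing) > 0)
    stop_chemoconn("mapped gene(s) absent from counts: ",
                   paste(missing, collapse = ", "),
                   class = "chemoconn_invalid_input")
  res <- tapply(counts[names(complex_map)], complex_map, sum)
  setNames(as.numeric(res), names(res))
}
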