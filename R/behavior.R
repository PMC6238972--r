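#' Puzzle box trial schedule
#'
#' The 11-trial, 4-day schedule of the puzzle box test (PBT): day 1 holds
#' easy trials 1-3; day 2 holds easy trial 4 and intermediate trials 5-6;
#' day 3 holds intermediate trial 7 and difficult trials 8-9; day 4 holds
#' difficult trials 10-11. Difficulty is fixed by trial index: 1-4 easy
#' (open tunnel), 5-7 intermediate (bedding-covered tunnel), 8-11 difficult
#' (tunnel blocked by a lid).
#'
#' @return A data.frame with columns `day`, `trial_index`, `difficulty`.
#' @export
pbt_schedule <- function() {
  data.frame(
    day = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L),
    trial_index = 1:11,
    difficulty = c(rep("easy", 4), rep("intermediate", 3),
                   rep("difficult", 4)),
    stringsAsFactors = FALSE)
}

#' Novel object/place recognition discrimination index
#'
#' `(t_novel - t_familiar) / (t_novel + t_familiar)`: 0 means no preference
#' for the novel object, positive values mean novelty preference. Bounded in
#' \[-1, 1\] for nonnegative times, reaching the bounds only when one time is
#' zero.
#'
#' @param t_novel,t_familiar nonnegative interaction times in seconds
#'   (vectorized).
#' @return Numeric vector of indices in \[-1, 1\].
#' @export
discrimination_index <- function(t_novel, t_familiar) {
  if (any(t_novel < 0) || any(t_familiar < 0))
    stop_chemoconn("interaction times must be nonnegative",
                   class = "chemoconn_invalid_input")
  tot <- t_novel + t_familiar
  if (any(tot == 0))
    stop_chemoconn("discrimination index undefined: total interaction time is zero",
                   class = "chemoconn_undefined_value")
  (t_novel - t_familiar) / tot
}

#' Total interaction time in the recognition test
#'
#' `t_novel + t_familiar`; a motivation/activity control endpoint reported
#' alongside the discrimination index.
#'
#' @inheritParams discrimination_index
#' @return Numeric vector of total times in seconds.
#' @export
total_interaction <- function(t_novel, t_familiar) {
  if (any(t_novel < 0) || any(t_familiar < 0))
    stop_chemoconn("interaction times must be nonnegative",
                   class = "chemoconn_invalid_input")
  t_novel + t_familiar
}

#' Y-maze spontaneous alternation score
#'
#' A perfect alternation is a run of three consecutive arm entries visiting
#' all three arms before any reentry. The score counts perfect triplets over
#' overlapping windows and divides by `(entries - 2)`, the number of
#' windows, reported as a percentage. Sequences with fewer than 3 entries
#' are flagged undefined rather than thrown.
#'
#' @param entries character vector of arm entries over the alphabet
#'   `{A, B, C}` (a single string like `"ABCAB"` is also accepted).
#' @return List with `pct` (percentage, `NA` if undefined), `n_perfect`,
#'   `total_entries`, and `defined`.
#' @export
perfect_alternation_pct <- function(entries) {
  if (length(entries) == 1L && nchar(entries[1]) > 1L)
    entries <- strsplit(entries, "")[[1]]
  entries <- as.character(entries)
  if (length(entries) > 0 && !all(entries %in% c("A", "B", "C")))
    stop_chemoconn("arm entries must be in {A, B, C}",
                   class = "chemoconn_invalid_input")
  n <- length(entries)
  if (n < 3L)
    return(list(pct = NA_real_, n_perfect = 0L, total_entries = n,
                defined = FALSE))
  perfect <- vapply(seq_len(n - 2L), function(i)
    length(unique(entries[i:(i + 2L)])) == 3L, logical(1))
  list(pct = 100 * sum(perfect) / (n - 2L), n_perfect = sum(perfect),
       total_entries = n, defined = TRUE)
}

#' Per-subject puzzle box difficulty-tier summary
#'
#' Validates a trial table against the fixed 11-trial schedule and averages
#' escape times within each difficulty tier per subject; the validated
#' per-trial table is returned alongside for repeated-measures export.
#'
#' @param trials data.frame with columns `subject_id`, `trial_index`,
#'   `escape_time` (seconds, nonnegative); `day`/`difficulty` columns, if
#'   present, must agree with [pbt_schedule()].
#' @return List with `tier_means` (data.frame: subject_id, easy,
#'   intermediate, difficult) and `trials` (the validated table with schedule
#'   columns attached).
#' @export
pbt_difficulty_summary <- function(trials) {
  sched <- pbt_schedule()
  need <- c("subject_id", "trial_index", "escape_time")
  if (!all(need %in% names(trials)))
    stop_chemoconn("trials must have columns ",
                   paste(need, collapse = ", "),
                   class = "chemoconn_invalid_input")
  if (any(trials$escape_time < 0))
    stop_chemoconn("escape times must be nonnegative",
                   class = "chemoconn_invalid_input")
  for (sid in unique(trials$subject_id)) {
    have <- sort(trials$trial_index[trials$subject_id == sid])
    missing <- setdiff(1:11, have)
    if (length(missing) > 0 || !identical(have, 1:11))
      stop_chemoconn(sprintf(
        "subject %s: missing or duplicated trial(s) %s", sid,
        paste(if (length(missing)) missing else "(duplicates)",
              collapse = ", ")),
        class = "chemoconn_invalid_input")
  }
  trials$day <- sched$day[trials$trial_index]
  trials$difficulty <- sched$difficulty[trials$trial_index]
  agg <- aggregate(escape_time ~ subject_id + difficulty, trials, mean)
  wide <- reshape(agg, idvar = "subject_id", timevar = "difficulty",
                  direction = "wide")
  names(wide) <- sub("^escape_time\\.", "", names(wide))
  wide <- wide[, c("subject_id", "easy", "intermediate", "difficult")]
  rownames(wide) <- NULL
  list(tier_means = wide, trials = trials)
}

#' Behavioral endpoint table for a synthetic or recorded cohort
#'
#' Assembles the per-subject cognition endpoints: discrimination index and
#' total interaction time (novel object/place recognition), spontaneous
#' alternation percentage and total arm entries (Y-maze), and puzzle box
#' tier means. Undefined endpoints (zero total interaction time; fewer than
#' 3 arm entries) are surfaced as flagged `NA`, never silently dropped.
#'
#' @param behavior list as returned by [generate_behavior()]: elements
#'   `pbt`, `noprt`, `ymaze`.
#' @return A data.frame, one row per subject.
#' @export
behavior_endpoints <- function(behavior) {
  noprt <- behavior$noprt
  tot <- total_interaction(noprt$t_novel, noprt$t_familiar)
  di <- ifelse(tot > 0,
               (noprt$t_novel - noprt$t_familiar) / ifelse(tot > 0, tot, 1),
               NA_real_)
  ym <- lapply(behavior$ymaze$entries, perfect_alternation_pct)
  tiers <- pbt_difficulty_summary(behavior$pbt)$tier_means
  out <- data.frame(
    subject_id = noprt$subject_id, group = noprt$group,
    di = di, di_defined = tot > 0, total_interaction = tot,
    alternation_pct = vapply(ym, `[[`, numeric(1), "pct"),
    alternation_defined = vapply(ym, `[[`, logical(1), "defined"),
    total_entries = vapply(ym, `[[`, integer(1), "total_entries"),
    stringsAsFactors = FALSE)
  merge(out, tiers, by = "subject_id", sort = FALSE)
}
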