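# Opinion-change coding. Three scenarios (travel, murder trial,
# vaccination) answered at T0 (baseline), T1 (after social media
# interaction) and T2 (after in-person discussion). Change in the
# social-media interval is T1 vs T0; change in the in-person interval is
# T2 vs T1. A subject's interval score is the number of scenarios that
# changed (0-3); the "change" group (C) is score >= 1, "no change" (NC)
# is score 0.

scenario_fields <- list(
  travel = c("travel_destination", "travel_volunteer", "travel_hours"),
  murder = c("murder_verdict", "murder_sentence"),
  vaccination = "vaccinate"
)

#' Code a single scenario's opinion change
#'
#' Travel: change if the destination choice flipped, the volunteer
#' decision was modified, or (by default) the offered volunteer hours
#' changed. Murder: change if the verdict flipped or the prison
#' time/punishment changed. Vaccination: change if the binary answer
#' differs.
#'
#' @param pre,post Named list / one-row data frame with the scenario's
#'   answer fields.
#' @param scenario One of `"travel"`, `"murder"`, `"vaccination"`.
#' @param hours_counts Whether a change in volunteer hours alone counts
#'   as a travel change (default TRUE; the disjunctive rule is ambiguous
#'   on hours, so the sub-rule is a flag).
#' @return Integer 0 (no change) or 1 (change).
#' @export
score_scenario_change <- function(pre, post, scenario,
                                  hours_counts = TRUE) {
  scenario <- match.arg(scenario, names(scenario_fields))
  fields <- scenario_fields[[scenario]]
  if (scenario == "travel" && !hours_counts)
    fields <- setdiff(fields, "travel_hours")
  for (f in fields) {
    a <- pre[[f]]
    b <- post[[f]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b))
      param_error("missing field '%s' needed to code scenario '%s'",
                  f, scenario)
    if (as.character(a) != as.character(b)) return(1L)
  }
  0L
}

#' Aggregate per-subject change codes, scores and groups
#'
#' @param records Long data frame of questionnaire answers: one row per
#'   subject x timepoint, columns `subject_id`, `timepoint`
#'   (T0/T1/T2), `travel_destination`, `travel_volunteer`,
#'   `travel_hours`, `murder_verdict`, `murder_sentence`, `vaccinate`.
#' @param hours_counts Passed to [score_scenario_change()].
#' @return Data frame, one row per subject: per-scenario change codes
#'   for both intervals, interval scores `score_s` / `score_i` (0-3) and
#'   group labels `group_s` / `group_i` (`"C"` / `"NC"`).
#' @export
aggregate_changes <- function(records, hours_counts = TRUE) {
  if (!is.data.frame(records) || nrow(records) == 0)
    param_error("records must be a non-empty data frame")
  need <- c("subject_id", "timepoint", unlist(scenario_fields))
  miss <- setdiff(need, names(records))
  if (length(miss))
    param_error("records missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(records[, c("subject_id", "timepoint")]))
    param_error("duplicate subject_id x timepoint rows")
  subjects <- unique(records$subject_id)
  out <- lapply(subjects, function(id) {
    sub <- records[records$subject_id == id, ]
    tps <- c("T0", "T1", "T2")
    if (!all(tps %in% sub$timepoint))
      param_error("subject %s lacks timepoints: %s", id,
                  paste(setdiff(tps, sub$timepoint), collapse = ", "))
    r <- lapply(tps, function(tp) sub[sub$timepoint == tp, ])
    names(r) <- tps
    code <- function(pre, post) vapply(
      names(scenario_fields),
      function(sc) score_scenario_change(pre, post, sc, hours_counts),
      integer(1))
    cs <- code(r$T0, r$T1)   # social-media interval: T1 vs T0
    ci <- code(r$T1, r$T2)   # in-person interval:   T2 vs T1
    data.frame(subject_id = id,
               travel_s = cs[["travel"]], murder_s = cs[["murder"]],
               vaccination_s = cs[["vaccination"]],
               travel_i = ci[["travel"]], murder_i = ci[["murder"]],
               vaccination_i = ci[["vaccination"]],
               score_s = sum(cs), score_i = sum(ci),
               group_s = if (sum(cs) >= 1) "C" else "NC",
               group_i = if (sum(ci) >= 1) "C" else "NC",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Transition statistics of opinion change across the two intervals
#'
#' Percentages (one decimal, half-up) of the no-change / change groups
#' in each interval and the conditional retention/persistence
#' percentages: NC after in-person given NC after social media, and C
#' after in-person given C after social media.
#'
#' @param codings Output of [aggregate_changes()].
#' @return Named list of percentages (`nc_s`, `c_s`, `nc_i`, `c_i`,
#'   `nc_i_given_nc_s`, `c_i_given_c_s`) plus the underlying counts.
#' @export
transition_statistics <- function(codings) {
  if (!is.data.frame(codings) || nrow(codings) == 0)
    param_error("codings must be a non-empty data frame")
  stopifnot(all(c("group_s", "group_i") %in% names(codings)))
  n <- nrow(codings)
  n_nc_s <- sum(codings$group_s == "NC")
  n_nc_i <- sum(codings$group_i == "NC")
  n_nc_both <- sum(codings$group_s == "NC" & codings$group_i == "NC")
  n_c_both <- sum(codings$group_s == "C" & codings$group_i == "C")
  pct <- function(num, den) {
    if (den == 0) return(NA_real_)
    round_half_up(100 * num / den, 1)
  }
  list(
    n = n,
    counts = list(nc_s = n_nc_s, c_s = n - n_nc_s,
                  nc_i = n_nc_i, c_i = n - n_nc_i,
                  nc_both = n_nc_both, c_both = n_c_both),
    nc_s = pct(n_nc_s, n), c_s = pct(n - n_nc_s, n),
    nc_i = pct(n_nc_i, n), c_i = pct(n - n_nc_i, n),
    nc_i_given_nc_s = pct(n_nc_both, n_nc_s),
    c_i_given_c_s = pct(n_c_both, n - n_nc_s)
  )
}
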