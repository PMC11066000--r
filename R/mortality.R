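#' Cumulative mortality with scheduled-autopsy denominator adjustment
#'
#' Mortality through a given post-operative day counts deaths and
#' humane-endpoint euthanasias with `event_day <= day`. The denominator
#' is the scored cohort minus animals removed for scheduled autopsy
#' *strictly before* that day: an animal autopsied on day 3 still counts
#' in the day-3 denominator but not from day 4 on. This convention
#' reproduces the published overall rates (4/29 on day 3, 8/21 on days 4
#' and 7 after eight day-3 autopsies).
#'
#' @param cohort Scored cohort ledger (the `scored` element of
#'   [build_valid_cohort()], or any validated ledger).
#' @param day Post-operative day(s), integer `>= 1` ("day one" is 1).
#' @param severity Optional severity class (`"severe"`, `"moderate"`,
#'   `"mild"`) restricting the computation to one subgroup.
#' @return Tibble with one row per requested day: `day`, `deaths`,
#'   `at_risk`, `mortality_pct` (rounded to 2 decimals for display;
#'   `mortality_frac` carries the exact value).
#' @examples
#' scored <- build_valid_cohort(cwp_example_cohort())$scored
#' cumulative_mortality(scored, day = c(3, 4, 7))
#' cumulative_mortality(scored, day = 3, severity = "severe")  # 4/6
#' @export
cumulative_mortality <- function(cohort, day, severity = NULL) {
  cohort <- validate_ledger(cohort)
  if (any(day < 1 | day != round(day)))
    stop_robscore("day must be integer >= 1 (post-operative day one is 1)")
  if (!is.null(severity)) {
    severity <- match.arg(severity, SEVERITY_LEVELS)
    cohort <- filter(cohort, .data$severity == !!severity)
  }
  purrr::map_df(as.integer(day), function(d) {
    deaths <- sum(cohort$event_kind %in% MORTALITY_EVENTS &
                    cohort$event_day <= d, na.rm = TRUE)
    removed <- sum(cohort$event_kind == "scheduled_autopsy" &
                     cohort$event_day < d, na.rm = TRUE)
    at_risk <- nrow(cohort) - removed
    frac <- if (at_risk > 0) deaths / at_risk else 0
    tibble(day = d, deaths = deaths, at_risk = at_risk,
           mortality_frac = frac,
           mortality_pct = round(100 * frac, 2))
  })
}

#' @rdname cumulative_mortality
#' @param days Days to tabulate (default 1:7).
#' @param by_severity If `TRUE`, adds per-severity rows alongside the
#'   overall ones.
#' @return `mortality_table()` returns the same columns plus `severity`
#'   (`"overall"` or the class).
#' @export
mortality_table <- function(cohort, days = 1:7, by_severity = TRUE) {
  cohort <- validate_ledger(cohort)
  out <- mutate(cumulative_mortality(cohort, days), severity = "overall",
                .before = 1)
  if (by_severity) {
    present <- intersect(SEVERITY_LEVELS, unique(cohort$severity))
    per <- purrr::map_df(present, function(s)
      mutate(cumulative_mortality(cohort, days, severity = s),
             severity = s, .before = 1))
    out <- bind_rows(out, per)
  }
  out
}

#' Survivors at a given day, by severity class
#'
#' An animal is alive at `day` if it has no mortality event on or before
#' `day` and was not removed for scheduled autopsy strictly before
#' `day` (animals euthanized on `day` itself for tissue harvest count as
#' survivors at that day). Counts satisfy the conservation identity
#' `alive + cumulative deaths + prior scheduled removals = scored n`.
#'
#' @inheritParams cumulative_mortality
#' @param day A single post-operative day, integer `>= 1`.
#' @return Tibble with `severity`, `alive` (one row per class present,
#'   plus a `total` row).
#' @examples
#' scored <- build_valid_cohort(cwp_example_cohort())$scored
#' survivor_summary(scored, 7)  # 13 total: 11 moderate, 2 mild, 0 severe
#' @export
survivor_summary <- function(cohort, day) {
  cohort <- validate_ledger(cohort)
  if (length(day) != 1 || day < 1 || day != round(day))
    stop_robscore("day must be a single integer >= 1")
  dead <- cohort$event_kind %in% MORTALITY_EVENTS &
    !is.na(cohort$event_day) & cohort$event_day <= day
  removed <- !is.na(cohort$event_kind) &
    cohort$event_kind == "scheduled_autopsy" & cohort$event_day < day
  alive <- cohort[!dead & !removed, , drop = FALSE]
  counts <- purrr::map_df(SEVERITY_LEVELS, function(s)
    tibble(severity = s, alive = sum(alive$severity == s, na.rm = TRUE)))
  counts <- filter(counts, .data$severity %in% cohort$severity |
                     .data$alive > 0)
  bind_rows(counts, tibble(severity = "total", alive = nrow(alive)))
}

#' First day of score decline per animal
#'
#' Scans each animal's daily ROB totals for the first scored day whose
#' total is strictly below the previous scored day's total — the early
#' warning the protocol uses for deterioration (in the validation cohort
#' this occurred on post-operative day four or five among survivors).
#'
#' @param scores Data frame with columns `animal_id`, `day`, `total`
#'   (ROB totals); at least two scored days per animal.
#' @return Tibble `animal_id`, `decline_day` (`NA` when the series never
#'   declines).
#' @examples
#' s <- tibble::tibble(animal_id = "a", day = 1:4, total = c(10, 10, 10, 8))
#' first_decline_day(s)  # day 4
#' @export
first_decline_day <- function(scores) {
  scores <- as_tibble(scores)
  need <- c("animal_id", "day", "total")
  if (!all(need %in% names(scores)))
    stop_robscore("scores needs columns animal_id, day, total")
  if (any(scores$day < 1 | scores$day != round(scores$day)))
    stop_robscore("score days must be integers >= 1")
  if (anyDuplicated(scores[c("animal_id", "day")]))
    stop_robscore("duplicate (animal_id, day) rows in scores")
  scores |>
    arrange(.data$animal_id, .data$day) |>
    group_by(.data$animal_id) |>
    group_modify(function(df, key) {
      if (nrow(df) < 2)
        stop_robscore(sprintf(
          "animal '%s' has fewer than 2 scored days", key$animal_id))
      drop <- which(diff(df$total) < 0)
      tibble(decline_day = if (length(drop)) df$day[drop[1] + 1]
             else NA_integer_)
    }) |>
    ungroup()
}
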