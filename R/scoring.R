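#' Component sub-scores on the 1--5 scale
#'
#' Map raw component measurements to their ROB sub-scores. All three are
#' vectorized and validate their domains: Rotarod latencies must lie in
#' `[0, 300]` (the accelerating-rod test is capped at 300 s; clamp raw
#' trial times with [mean_rotarod()] before scoring), open-field distances
#' must be non-negative, and body-weight loss must be finite (negative
#' values -- weight gain -- score 5, the healthiest band).
#'
#' @param seconds Mean Rotarod latency to fall, seconds, in `[0, 300]`.
#' @param distance Open-field key-frame path distance, tracker units, `>= 0`.
#' @param bwl_percent Body-weight loss percent; negative when weight gained.
#' @param criteria A [rob_criteria()] object.
#' @return Integer vector of sub-scores in `1:5`.
#' @examples
#' score_rotarod(c(38, 154, 300))
#' score_openfield(c(39, 643, 1305))
#' score_bwl(c(16.23, 1.24, -2))
#' @seealso [compute_rob()] for the aggregate score.
#' @export
score_rotarod <- function(seconds, criteria = rob_criteria()) {
  check_numeric(seconds, "seconds")
  bad <- which(seconds < 0 | seconds > 300)
  if (length(bad))
    stop_robscore(sprintf(
      "Rotarod latency out of [0, 300] s: %s",
      paste(format(seconds[head(bad, 5)]), collapse = ", ")))
  score_band(seconds, criteria$rotarod)
}

#' @rdname score_rotarod
#' @export
score_openfield <- function(distance, criteria = rob_criteria()) {
  check_numeric(distance, "distance")
  bad <- which(distance < 0)
  if (length(bad))
    stop_robscore(sprintf(
      "open-field distance must be >= 0, got %s",
      paste(format(distance[head(bad, 5)]), collapse = ", ")))
  score_band(distance, criteria$openfield)
}

#' @rdname score_rotarod
#' @export
score_bwl <- function(bwl_percent, criteria = rob_criteria()) {
  check_numeric(bwl_percent, "bwl_percent")
  score_band(bwl_percent, criteria$bwl)
}

check_numeric <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)))
    stop_robscore(sprintf("'%s' must be finite numeric, got: %s", what,
                          paste(format(head(x, 5)), collapse = ", ")))
  invisible(x)
}

#' Severity class of a ROB total
#'
#' Partitions the 3--15 total into severe / moderate / mild at the
#' configured cut points (defaults: severe 3--6, moderate 7--10,
#' mild 11--15).
#'
#' @param total Integer ROB totals in `3:15`.
#' @inheritParams score_rotarod
#' @return Factor with levels `severe`, `moderate`, `mild`.
#' @export
rob_severity <- function(total, criteria = rob_criteria()) {
  if (any(total < 3 | total > 15 | total != round(total)))
    stop_robscore("ROB total must be an integer in 3..15")
  cuts <- criteria$severity_cuts
  severity_factor(ifelse(total <= cuts[1], "severe",
                  ifelse(total <= cuts[2], "moderate", "mild")))
}

#' Aggregate ROB score from the three raw components
#'
#' Computes the three sub-scores from raw measurements, sums them to the
#' 3--15 total and assigns the severity class. Sub-scores are always
#' recomputed from the raw values for traceability; pre-binned scores are
#' only accepted through [score_assessments()] with
#' `allow_prebinned = TRUE`.
#'
#' @param rotarod_seconds,openfield_distance,bwl_percent Raw component
#'   measurements (recycled to a common length).
#' @inheritParams score_rotarod
#' @return A tibble with one row per input: `r_score`, `o_score`,
#'   `b_score`, `total`, `severity`.
#' @examples
#' compute_rob(300, 1200, 1.0)   # total 15, mild
#' compute_rob(0, 50, 25)        # total 3, severe
#' @export
compute_rob <- function(rotarod_seconds, openfield_distance, bwl_percent,
                        criteria = rob_criteria()) {
  r <- score_rotarod(rotarod_seconds, criteria)
  o <- score_openfield(openfield_distance, criteria)
  b <- score_bwl(bwl_percent, criteria)
  total <- r + o + b
  tibble(
    r_score = r, o_score = o, b_score = b,
    total = as.integer(total),
    severity = rob_severity(total, criteria)
  )
}

#' Score a table of component measurements
#'
#' Data-frame-first wrapper over [compute_rob()]: takes one row per
#' animal-day with columns `rotarod_s`, `openfield_dist` and `bwl_pct`
#' (as produced by [compute_components()]) and appends the five score
#' columns.
#'
#' @param components A data frame with columns `rotarod_s`,
#'   `openfield_dist`, `bwl_pct` and any identifier columns.
#' @param allow_prebinned If `TRUE` and the input already carries
#'   `r_score`, `o_score`, `b_score` columns, those are kept as-is and
#'   only the total and severity are (re)computed. Default `FALSE`:
#'   sub-scores are always derived from raw values.
#' @inheritParams score_rotarod
#' @return The input tibble with `r_score`, `o_score`, `b_score`,
#'   `total`, `severity` columns appended (or recomputed).
#' @export
score_assessments <- function(components, criteria = rob_criteria(),
                              allow_prebinned = FALSE) {
  components <- as_tibble(components)
  prebinned <- all(c("r_score", "o_score", "b_score") %in% names(components))
  if (allow_prebinned && prebinned) {
    sub <- components[c("r_score", "o_score", "b_score")]
    if (any(!unlist(sub) %in% 1:5))
      stop_robscore("pre-binned sub-scores must all be in 1..5")
    total <- as.integer(rowSums(sub))
    return(mutate(components, total = total,
                  severity = rob_severity(total, criteria)))
  }
  need <- c("rotarod_s", "openfield_dist", "bwl_pct")
  missing_cols <- setdiff(need, names(components))
  if (length(missing_cols))
    stop_robscore(paste0("missing component columns: ",
                         paste(missing_cols, collapse = ", ")))
  scores <- compute_rob(components$rotarod_s, components$openfield_dist,
                        components$bwl_pct, criteria)
  bind_cols(select(components, -any_of(names(scores))), scores)
}
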