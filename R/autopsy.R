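#' Autopsy grading over six basal-cistern segments
#'
#' Post-mortem severity grading of subarachnoid blood: the basal cistern
#' is divided into six segments and each is graded 0 (no subarachnoid
#' blood) to 3 (clot obliterating all arteries within the segment); the
#' total runs 0--18. The total maps to a severity class at configurable
#' cut points; the defaults (mild 0--7, moderate 8--12, severe 13--18)
#' follow the established convention for this grading scheme and can be
#' changed per laboratory.
#'
#' @param grades Data frame with columns `animal_id` and `seg1`..`seg6`
#'   (each integer 0--3), or for a single animal a bare numeric vector of
#'   six grades.
#' @param cut_points Two increasing totals: upper bounds of the mild and
#'   moderate bands. Default `c(7, 12)`.
#' @return Tibble with `animal_id` (when supplied), `total` and
#'   `severity`.
#' @examples
#' autopsy_total(c(1, 2, 0, 3, 1, 2))  # total 9, moderate
#' @export
autopsy_total <- function(grades, cut_points = c(7L, 12L)) {
  if (length(cut_points) != 2 || cut_points[1] >= cut_points[2] ||
      cut_points[1] < 0 || cut_points[2] > 17)
    stop_robscore("cut_points must be two increasing totals within 0..17")
  seg_cols <- paste0("seg", 1:6)
  if (is.numeric(grades) && is.null(dim(grades))) {
    grades <- as_tibble(as.list(setNames(grades,
                                         seg_cols[seq_along(grades)])))
  }
  grades <- as_tibble(grades)
  if (!all(seg_cols %in% names(grades)))
    stop_robscore("exactly six segment grades required (columns seg1..seg6)")
  seg <- as.matrix(grades[seg_cols])
  if (any(!seg %in% 0:3))
    stop_robscore("segment grades must each be in 0..3")
  total <- as.integer(rowSums(seg))
  out <- tibble(
    total = total,
    severity = severity_factor(
      ifelse(total <= cut_points[1], "mild",
      ifelse(total <= cut_points[2], "moderate", "severe")))
  )
  if ("animal_id" %in% names(grades))
    out <- bind_cols(grades["animal_id"], out)
  out
}

#' Concordance between behavioral and autopsy severity classes
#'
#' Agreement between the ROB severity class and the autopsy-derived
#' class over the animals present in both tables. By default agreement
#' means exact label equality; `tolerance = 1` also accepts adjacent
#' classes (severe vs. moderate, moderate vs. mild), since "similar
#' severity-level evaluations" admits either reading.
#'
#' @param rob Data frame with columns `animal_id`, `severity` (ROB).
#' @param autopsy Data frame with columns `animal_id`, `severity`
#'   (autopsy), e.g. the output of [autopsy_total()].
#' @param tolerance 0 (exact agreement, default) or 1 (within one
#'   class).
#' @return An object of class `rob_concordance`: list with `n_compared`,
#'   `n_agreeing`, `agreement` and a per-animal `pairs` tibble.
#'   [tidy()] returns the pairs, [glance()] the summary.
#' @examples
#' rob <- tibble::tibble(animal_id = letters[1:4],
#'                       severity = c("mild", "mild", "severe", "moderate"))
#' aut <- tibble::tibble(animal_id = letters[1:4],
#'                       severity = c("mild", "moderate", "severe", "moderate"))
#' glance(concordance(rob, aut))  # 3 of 4 agree
#' @export
concordance <- function(rob, autopsy, tolerance = 0) {
  rob <- as_tibble(rob); autopsy <- as_tibble(autopsy)
  for (nm in list(rob, autopsy))
    if (!all(c("animal_id", "severity") %in% names(nm)))
      stop_robscore("both inputs need columns animal_id, severity")
  only_rob <- setdiff(rob$animal_id, autopsy$animal_id)
  only_aut <- setdiff(autopsy$animal_id, rob$animal_id)
  if (length(only_rob) || length(only_aut))
    stop_robscore(paste0(
      "animal ids do not match; only in ROB table: ",
      paste(only_rob, collapse = ", "), "; only in autopsy table: ",
      paste(only_aut, collapse = ", ")))
  if (!tolerance %in% c(0, 1))
    stop_robscore("tolerance must be 0 (exact) or 1 (within one class)")
  pairs <- inner_join(
    transmute(rob, .data$animal_id,
              rob_severity = as.character(.data$severity)),
    transmute(autopsy, .data$animal_id,
              autopsy_severity = as.character(.data$severity)),
    by = "animal_id")
  lev <- function(x) match(x, SEVERITY_LEVELS)
  pairs$agree <- abs(lev(pairs$rob_severity) -
                       lev(pairs$autopsy_severity)) <= tolerance
  n <- nrow(pairs)
  structure(list(
    n_compared = n,
    n_agreeing = sum(pairs$agree),
    agreement = if (n > 0) sum(pairs$agree) / n else NA_real_,
    tolerance = tolerance,
    pairs = pairs
  ), class = "rob_concordance")
}

#' @export
print.rob_concordance <- function(x, ...) {
  cat(sprintf("Severity concordance: %d of %d agree (%.2f)%s\n",
              x$n_agreeing, x$n_compared, x$agreement,
              if (x$tolerance > 0) " [within one class]" else ""))
  invisible(x)
}

#' @rdname concordance
#' @param x A `rob_concordance` object.
#' @param ... Unused.
#' @method tidy rob_concordance
#' @export
tidy.rob_concordance <- function(x, ...) x$pairs

#' @rdname concordance
#' @method glance rob_concordance
#' @export
glance.rob_concordance <- function(x, ...) {
  tibble(n_compared = x$n_compared, n_agreeing = x$n_agreeing,
         agreement = x$agreement, tolerance = x$tolerance)
}
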