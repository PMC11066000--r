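#' Scoring criteria for the ROB composite score
#'
#' The ROB score sums three sub-scores (Rotarod, Open-field,
#' Body-weight-loss), each on a 1--5 scale defined by four band edges per
#' component. `rob_criteria()` builds the criteria object; called with no
#' arguments it returns the protocol defaults:
#'
#' * Rotarod latency (s): 1 for `s <= 50`, 2 for `50 < s <= 100`,
#'   3 for `100 < s <= 200`, 4 for `200 < s < 300`, 5 for `s = 300`
#'   (the 300-s test endpoint is the only way to score 5).
#' * Open-field distance (tracker units): 1 for `[0, 300)`, 2 for
#'   `[300, 500)`, 3 for `[500, 800)`, 4 for `[800, 1000]`, 5 above 1000.
#' * Body-weight loss (%): 5 below 5, 4 for `[5, 10)`, 3 for `[10, 15)`,
#'   2 for `[15, 20]`, 1 above 20. Weight gain (negative loss) scores 5.
#'
#' The published criteria table prints touching bin edges; the conventions
#' above respect every strict inequality it prints (the "> 1000", "< 5%"
#' and "> 20%" end bands and the "201--299" Rotarod band) and resolve the
#' remaining ties lower-inclusive. Laboratories can reconfigure any edge:
#' each component is four `thresholds` plus a logical `strict` vector
#' (`TRUE` at position i means the score steps only strictly beyond
#' `thresholds[i]`) and a `direction` (`"asc"` if larger raw values are
#' healthier, `"desc"` if larger values are worse, as for weight loss).
#'
#' Severity classes partition the 3--15 total at `severity_cuts`:
#' total `<= cuts[1]` is severe, `<= cuts[2]` moderate, above mild.
#'
#' @param rotarod,openfield,bwl Component band definitions, each a list
#'   with `thresholds` (ascending numeric of length 4), `strict`
#'   (logical of length 4) and `direction` (`"asc"` or `"desc"`).
#' @param severity_cuts Two increasing integers: upper totals of the
#'   severe and moderate bands. Default `c(6, 10)`.
#' @return An object of class `rob_criteria`.
#' @examples
#' crit <- rob_criteria()
#' score_rotarod(c(38, 154, 300), crit)
#' @export
rob_criteria <- function(rotarod = NULL, openfield = NULL, bwl = NULL,
                         severity_cuts = c(6L, 10L)) {
  crit <- list(
    rotarod = rotarod %||% list(
      thresholds = c(50, 100, 200, 300),
      strict = c(TRUE, TRUE, TRUE, FALSE),
      direction = "asc"
    ),
    openfield = openfield %||% list(
      thresholds = c(300, 500, 800, 1000),
      strict = c(FALSE, FALSE, FALSE, TRUE),
      direction = "asc"
    ),
    bwl = bwl %||% list(
      thresholds = c(5, 10, 15, 20),
      strict = c(FALSE, FALSE, FALSE, TRUE),
      direction = "desc"
    ),
    severity_cuts = as.integer(severity_cuts)
  )
  validate_criteria(crit)
  structure(crit, class = "rob_criteria")
}

validate_criteria <- function(crit) {
  for (comp in c("rotarod", "openfield", "bwl")) {
    b <- crit[[comp]]
    if (length(b$thresholds) != 4 || is.unsorted(b$thresholds, strictly = TRUE))
      stop_robscore(sprintf(
        "criteria for '%s' must have 4 strictly increasing thresholds", comp))
    if (length(b$strict) != 4 || !is.logical(b$strict))
      stop_robscore(sprintf("criteria for '%s': 'strict' must be logical(4)", comp))
    if (!b$direction %in% c("asc", "desc"))
      stop_robscore(sprintf("criteria for '%s': direction must be 'asc' or 'desc'", comp))
  }
  cuts <- crit$severity_cuts
  if (length(cuts) != 2 || cuts[1] >= cuts[2] || cuts[1] < 3 || cuts[2] > 14)
    stop_robscore("severity_cuts must be two increasing totals within 3..14")
  invisible(crit)
}

# Generic band scorer: counts how many thresholds the value has passed.
score_band <- function(x, band) {
  passed <- vapply(seq_along(band$thresholds), function(i) {
    t <- band$thresholds[i]
    if (band$strict[i]) as.integer(x > t) else as.integer(x >= t)
  }, integer(length(x)))
  if (length(x) == 1L) passed <- matrix(passed, nrow = 1L)
  n_passed <- rowSums(passed)
  if (band$direction == "asc") as.integer(1L + n_passed)
  else as.integer(5L - n_passed)
}

#' Read or write scoring criteria as YAML
#'
#' The criteria object serializes to a plain YAML block so a lab can keep
#' its configuration under version control. `write_criteria()` writes the
#' defaults unless given another object; `read_criteria()` validates on
#' load.
#'
#' @param criteria A `rob_criteria` object.
#' @param path File path.
#' @return `read_criteria()` returns a `rob_criteria` object;
#'   `write_criteria()` returns `path` invisibly.
#' @export
write_criteria <- function(criteria = rob_criteria(), path) {
  yaml::write_yaml(unclass(criteria), path)
  invisible(path)
}

#' @rdname write_criteria
#' @export
read_criteria <- function(path) {
  raw <- yaml::read_yaml(path)
  rob_criteria(
    rotarod = raw$rotarod, openfield = raw$openfield, bwl = raw$bwl,
    severity_cuts = raw$severity_cuts
  )
}
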