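#' Mean Rotarod latency over the three daily trials
#'
#' The accelerating-rod test (4--40 RPM) is run three times per animal
#' per day; a trial ends when the animal falls or at the 300-s endpoint.
#' The scored quantity is the arithmetic mean of the three latencies,
#' each clamped to the endpoint first (timer overruns above 300 s are
#' recording artifacts, not performance).
#'
#' @param trials Numeric vector of exactly three latencies in seconds.
#' @return Mean latency in seconds, in `[0, 300]`.
#' @examples
#' mean_rotarod(c(100, 200, 300))  # 200
#' mean_rotarod(c(350, 320, 310))  # 300: clamped at the endpoint
#' @export
mean_rotarod <- function(trials) {
  if (!is.numeric(trials) || length(trials) != 3 || any(!is.finite(trials)))
    stop_robscore(sprintf("exactly 3 finite Rotarod trials required, got %d",
                          length(trials)))
  if (any(trials < 0))
    stop_robscore("Rotarod latencies cannot be negative")
  mean(pmin(trials, 300))
}

#' Body-weight loss percent
#'
#' `(pre - post) / pre * 100`: the fraction of the preoperative body
#' weight lost by the day of measurement. Negative when the animal gained
#' weight.
#'
#' @param pre_g Preoperative baseline weight, grams (> 0).
#' @param post_g Postoperative weight, grams (> 0). Vectorized; `pre_g`
#'   is recycled.
#' @return Percent weight loss.
#' @examples
#' body_weight_loss(30, 27)  # 10
#' body_weight_loss(25, 26)  # -4: weight gain
#' @export
body_weight_loss <- function(pre_g, post_g) {
  if (any(!is.finite(pre_g)) || any(!is.finite(post_g)) ||
      any(pre_g <= 0) || any(post_g <= 0))
    stop_robscore("body weights must be positive and finite (grams)")
  (pre_g - post_g) / pre_g * 100
}

as_track <- function(track) {
  track <- as_tibble(track)
  need <- c("frame", "x", "y")
  if (!all(need %in% names(track)))
    stop_robscore("a track needs columns frame, x, y")
  if (nrow(track) < 1)
    stop_robscore("a track needs at least one frame")
  if (is.unsorted(track$frame, strictly = TRUE))
    stop_robscore("track frame indices must be strictly increasing")
  track
}

#' Key-frame sampling of an open-field track
#'
#' The open-field video protocol records at 30 frames per second; the
#' analysis window is the 160 frames following the release frame (the
#' first frame of unrestricted movement, chosen by the operator), with
#' key frames every 5 frames. Both endpoints are included, so the
#' defaults yield 33 key positions.
#'
#' @param track A data frame with columns `frame`, `x`, `y` (tracker
#'   pixel units), frames strictly increasing.
#' @param start_frame Release frame index (the window anchor).
#' @param n_frames Window length in frames after the anchor (default 160).
#' @param step Key-frame interval in frames (default 5).
#' @return The key-frame rows of `track`, as a tibble.
#' @examples
#' trk <- tibble::tibble(frame = 0:200, x = rnorm(201), y = rnorm(201))
#' nrow(sample_keyframes(trk, start_frame = 0))  # 33
#' @export
sample_keyframes <- function(track, start_frame, n_frames = 160L, step = 5L) {
  track <- as_track(track)
  if (n_frames < step || n_frames %% step != 0)
    stop_robscore("n_frames must be a positive multiple of step")
  wanted <- seq(start_frame, start_frame + n_frames, by = step)
  idx <- match(wanted, track$frame)
  if (anyNA(idx))
    stop_robscore(sprintf("track is missing frame %d in the requested window",
                          wanted[which(is.na(idx))[1]]))
  track[idx, , drop = FALSE]
}

#' Path length of a tracked trajectory
#'
#' Sum of Euclidean distances between consecutive tracked positions, in
#' raw tracker pixel units (the protocol applies no spatial calibration).
#' This total path length -- not the net start-to-end displacement -- is
#' the scored open-field quantity; the displacement is available via
#' `net_displacement()`.
#'
#' @param track A data frame with columns `frame`, `x`, `y`; at least two
#'   rows.
#' @return Total path length, `>= 0`; zero iff all positions coincide.
#' @examples
#' trk <- tibble::tibble(frame = 0:32, x = 0:32, y = 0)
#' path_distance(trk)  # 32
#' @export
path_distance <- function(track) {
  track <- as_track(track)
  if (nrow(track) < 2)
    stop_robscore("path_distance needs at least 2 positions")
  sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
}

#' @rdname path_distance
#' @export
net_displacement <- function(track) {
  track <- as_track(track)
  if (nrow(track) < 2)
    stop_robscore("net_displacement needs at least 2 positions")
  n <- nrow(track)
  sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2)
}

#' Derive the three ROB components from raw daily assessments
#'
#' Turns a raw assessment table (one row per animal-day with the three
#' Rotarod trial latencies, an open-field distance, and the day's body
#' weight) plus a baseline table (preoperative weight per animal) into
#' the component table consumed by [score_assessments()].
#'
#' @param assessments Data frame with columns `animal_id`, `day`,
#'   `rt_trial1`, `rt_trial2`, `rt_trial3` (seconds; values above the
#'   300-s endpoint are clamped), `ot_distance` (tracker units), and
#'   `weight_g`.
#' @param baselines Data frame with columns `animal_id` and
#'   `preop_weight_g`.
#' @return Tibble with `animal_id`, `day`, `rotarod_s`, `openfield_dist`,
#'   `bwl_pct`.
#' @export
compute_components <- function(assessments, baselines) {
  assessments <- as_tibble(assessments)
  need <- c("animal_id", "day", "rt_trial1", "rt_trial2", "rt_trial3",
            "ot_distance", "weight_g")
  missing_cols <- setdiff(need, names(assessments))
  if (length(missing_cols))
    stop_robscore(paste0("assessments missing columns: ",
                         paste(missing_cols, collapse = ", ")))
  if (!all(c("animal_id", "preop_weight_g") %in% names(baselines)))
    stop_robscore("baselines needs columns animal_id, preop_weight_g")
  unmatched <- setdiff(assessments$animal_id, baselines$animal_id)
  if (length(unmatched))
    stop_robscore(paste0("no baseline weight for: ",
                         paste(unique(unmatched), collapse = ", ")))
  assessments |>
    left_join(as_tibble(baselines)[c("animal_id", "preop_weight_g")],
              by = "animal_id") |>
    rowwise() |>
    mutate(rotarod_s = mean_rotarod(c(.data$rt_trial1, .data$rt_trial2,
                                      .data$rt_trial3))) |>
    ungroup() |>
    mutate(
      openfield_dist = .data$ot_distance,
      bwl_pct = body_weight_loss(.data$preop_weight_g, .data$weight_g)
    ) |>
    select("animal_id", "day", "rotarod_s", "openfield_dist", "bwl_pct")
}
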