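# Truncated-normal draws by inverse-CDF on the truncated quantile range.
r_tnorm <- function(n, mean, sd, min, max) {
  if (sd < 0) stop_robscore("truncated normal needs sd >= 0")
  if (min > max) stop_robscore("truncation range is empty")
  if (sd == 0) {
    if (mean < min || mean > max)
      stop_robscore("degenerate (sd = 0) distribution outside its range")
    return(rep(mean, n))
  }
  p_lo <- pnorm(min, mean, sd)
  p_hi <- pnorm(max, mean, sd)
  if (p_hi - p_lo < 1e-12)
    stop_robscore(sprintf(
      "infeasible truncation: [%g, %g] carries no mass under N(%g, %g)",
      min, max, mean, sd))
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and standard deviation of a normal distribution with
#' parameters `mean`, `sd` truncated to `[min, max]` — the day-1
#' measurement family used by [simulate_cohort()]. Useful as the
#' reference value in parameter-recovery checks: when the truncation
#' range is asymmetric about the mean, the realized mean of draws
#' differs from the untruncated `mean` by design.
#'
#' @param mean,sd Parameters of the parent normal.
#' @param min,max Truncation bounds.
#' @return Named list with `mean` and `sd` of the truncated distribution.
#' @export
tnorm_moments <- function(mean, sd, min, max) {
  if (sd == 0) return(list(mean = mean, sd = 0))
  a <- (min - mean) / sd
  b <- (max - mean) / sd
  z <- pnorm(b) - pnorm(a)
  dn <- dnorm(a) - dnorm(b)
  mu <- mean + sd * dn / z
  var <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - (dn / z)^2)
  list(mean = mu, sd = sqrt(pmax(var, 0)))
}

day1_defaults <- function() {
  list(
    severe   = list(rt = c(mean = 38, sd = 60, min = 0, max = 154),
                    ot = c(mean = 130, sd = 92, min = 39, max = 277),
                    bwl = c(mean = 11.00, sd = 5.36, min = 3.21, max = 16.23)),
    moderate = list(rt = c(mean = 106, sd = 51, min = 0, max = 177),
                    ot = c(mean = 425, sd = 251, min = 90, max = 944),
                    bwl = c(mean = 9.07, sd = 3.87, min = 2.73, max = 14.89)),
    mild     = list(rt = c(mean = 188, sd = 30, min = 151, max = 215),
                    ot = c(mean = 643, sd = 169, min = 492, max = 891),
                    bwl = c(mean = 2.23, sd = 1.00, min = 1.57, max = 4.00)),
    sham     = list(rt = c(mean = 289, sd = 12, min = 276, max = 300),
                    ot = c(mean = 1156, sd = 163, min = 982, max = 1305),
                    bwl = c(mean = 1.87, sd = 0.59, min = 1.24, max = 2.40))
  )
}

#' Simulation configuration for synthetic ROB cohorts
#'
#' Bundles every tunable of the cohort simulator. The defaults encode
#' the validation study's conditions: subgroup sizes 6/18/5
#' (severe/moderate/mild), day-1 Rotarod / open-field / body-weight-loss
#' measurements drawn from normal distributions with the published
#' per-class mean, SD and range (truncated to the range), daily death
#' hazards calibrated to the published pattern (half the severe class
#' dies on day 2, a third of the remainder on day 3, the rest on day 4;
#' 1/9 of the moderate class on day 4; no mild deaths), a decline onset
#' day drawn as 4 with probability 2/3 and 5 otherwise, eight scheduled
#' autopsies on day 3, and terminal euthanasia of all survivors on day
#' 7.
#'
#' @param n_severe,n_moderate,n_mild,n_sham Animals per class.
#' @param day1 Per-class day-1 distribution parameters: named list with
#'   elements `severe`, `moderate`, `mild`, `sham`, each a list of `rt`,
#'   `ot`, `bwl` vectors `c(mean, sd, min, max)`.
#' @param hazards Per-class daily death probabilities, days 1..
#'   `follow_up_day` (named list of numeric vectors in `[0, 1]`).
#' @param p_humane Probability a mortality event is recorded as a
#'   humane-endpoint euthanasia rather than a found death (default 0.25).
#' @param decline_day_probs Named numeric: probability the score decline
#'   begins on each day (default `c("4" = 2/3, "5" = 1/3)`).
#' @param decline Post-onset daily trajectory: multiplicative factors
#'   for Rotarod and open-field and an additive step for weight loss.
#' @param drift Pre-onset day-to-day measurement noise SDs.
#' @param autopsy_day,autopsy_n Scheduled-autopsy plan: `autopsy_n`
#'   survivors drawn uniformly on `autopsy_day`.
#' @param follow_up_day Last study day; survivors are euthanized
#'   (censored) on this day.
#' @param tracks If `TRUE` (default) each animal-day open-field distance
#'   is realized as a synthetic random-walk track whose key-frame path
#'   length equals the drawn distance, so the behavior operations are
#'   exercised end-to-end. Set `FALSE` for large calibration runs.
#' @param fps,n_frames,step Video parameters of the generated tracks.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated list of class `rob_sim_config`.
#' @export
sim_config <- function(n_severe = 6, n_moderate = 18, n_mild = 5,
                       n_sham = 0,
                       day1 = day1_defaults(),
                       hazards = list(
                         severe = c(0, 1 / 2, 1 / 3, 1, 0, 0, 0),
                         moderate = c(0, 0, 0, 1 / 9, 0, 0, 0),
                         mild = rep(0, 7),
                         sham = rep(0, 7)),
                       p_humane = 0.25,
                       decline_day_probs = c("4" = 2 / 3, "5" = 1 / 3),
                       decline = list(rt_factor = 0.6, ot_factor = 0.6,
                                      bwl_step = 2.5),
                       drift = list(rt_sd = 10, ot_sd = 30, bwl_sd = 0.5),
                       autopsy_day = 3, autopsy_n = 8,
                       follow_up_day = 7,
                       tracks = TRUE, fps = 30, n_frames = 160, step = 5,
                       seed = 1L) {
  cfg <- list(
    n = c(severe = n_severe, moderate = n_moderate, mild = n_mild,
          sham = n_sham),
    day1 = day1, hazards = hazards, p_humane = p_humane,
    decline_day_probs = decline_day_probs, decline = decline, drift = drift,
    autopsy_day = autopsy_day, autopsy_n = autopsy_n,
    follow_up_day = follow_up_day,
    tracks = tracks, fps = fps, n_frames = n_frames, step = step,
    seed = as.integer(seed)
  )
  if (any(cfg$n < 0)) stop_robscore("group sizes must be >= 0")
  for (cls in names(cfg$hazards)) {
    h <- cfg$hazards[[cls]]
    if (any(h < 0 | h > 1))
      stop_robscore(sprintf("hazards for '%s' must lie in [0, 1]", cls))
    if (length(h) < cfg$follow_up_day)
      stop_robscore(sprintf("hazards for '%s' must cover days 1..%d",
                            cls, cfg$follow_up_day))
  }
  for (cls in names(cfg$day1)) for (m in c("rt", "ot", "bwl")) {
    p <- cfg$day1[[cls]][[m]]
    if (p[["sd"]] < 0) stop_robscore("day-1 SDs must be >= 0")
    if (p[["mean"]] < p[["min"]] || p[["mean"]] > p[["max"]])
      stop_robscore(sprintf(
        "day-1 %s/%s: range [%g, %g] must contain the mean %g",
        cls, m, p[["min"]], p[["max"]], p[["mean"]]))
  }
  if (abs(sum(cfg$decline_day_probs) - 1) > 1e-8)
    stop_robscore("decline_day_probs must sum to 1")
  structure(cfg, class = "rob_sim_config")
}

#' Synthetic random-walk track with a prescribed key-frame path length
#'
#' Generates a 2-D random walk over `n_frames + 1` consecutive frames
#' and rescales it about its start so that the path length of its
#' key-frame subsample (every `step`-th frame, both endpoints included)
#' equals `target_distance` to within numerical precision. A target of
#' zero yields a stationary track.
#'
#' @param target_distance Desired key-frame path length, `>= 0`.
#' @param n_frames Window length in frames (default 160; must be a
#'   positive multiple of `step`).
#' @param step Key-frame interval (default 5).
#' @param fps Frame rate recorded on the track (default 30).
#' @param origin Starting position `c(x, y)` (default `c(0, 0)`).
#' @param seed Optional integer; when given, the walk is drawn under
#'   this seed without disturbing the global RNG stream.
#' @return Track tibble (`frame`, `x`, `y`) with attribute `fps`.
#' @examples
#' trk <- make_track_fixture(643, seed = 7)
#' path_distance(sample_keyframes(trk, 0))  # 643
#' @export
make_track_fixture <- function(target_distance, n_frames = 160L, step = 5L,
                               fps = 30, origin = c(0, 0), seed = NULL) {
  if (target_distance < 0) stop_robscore("target_distance must be >= 0")
  if (n_frames < step || n_frames %% step != 0)
    stop_robscore("n_frames must be a positive multiple of step")
  if (!is.null(seed)) return(withr::with_seed(
    seed, make_track_fixture(target_distance, n_frames, step, fps, origin)))
  n_pos <- n_frames + 1
  if (target_distance == 0) {
    xy <- matrix(rep(origin, each = n_pos), ncol = 2)
  } else {
    steps <- matrix(stats::rnorm(2 * (n_pos - 1)), ncol = 2)
    xy <- rbind(c(0, 0), apply(steps, 2, cumsum))
    key <- seq(1, n_pos, by = step)
    len <- sum(sqrt(rowSums(diff(xy[key, , drop = FALSE])^2)))
    xy <- sweep(xy * (target_distance / len), 2, origin, `+`)
  }
  out <- tibble(frame = 0:(n_pos - 1), x = xy[, 1], y = xy[, 2])
  attr(out, "fps") <- fps
  out
}

#' Simulate a complete synthetic ROB cohort
#'
#' Draws a cohort under a [sim_config()]: per animal a latent severity
#' class, day-1 measurements from the class's truncated-normal
#' distributions, a post-onset decline trajectory, daily mortality from
#' the class hazard (recorded as death or humane-endpoint euthanasia),
#' scheduled autopsies drawn uniformly among survivors on the planned
#' day, terminal euthanasia of survivors at follow-up, segment-wise
#' autopsy grades for euthanized animals, and (optionally) a synthetic
#' open-field track per animal-day whose key-frame path length equals
#' the drawn distance. Everything is reproducible from `config$seed`.
#'
#' Within a day the order is: assessment of animals alive that morning,
#' then mortality, then scheduled-autopsy selection among the remaining
#' survivors. Every animal therefore has assessments through its
#' terminal day inclusive — a humane-endpoint euthanasia is triggered by
#' that day's assessment, and found deaths are dated to the last
#' assessed day.
#'
#' @param config A [sim_config()] object.
#' @return List of class `rob_simulation`:
#'   `ledger` (enrollment ledger; `severity` holds the day-1 ROB class),
#'   `assessments` (raw per-animal-day: three Rotarod trials,
#'   open-field distance, weight), `baselines` (preoperative weights),
#'   `components`, `scores` (derived via [compute_components()] and
#'   [score_assessments()]), `tracks` (long track table or `NULL`),
#'   `autopsy` (segment grades for euthanized animals), and `truth`
#'   (latent class, decline day and day-1 draws per animal).
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 42))
#' nrow(sim$ledger)  # 29
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "rob_sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  classes <- rep(names(cfg$n), times = cfg$n)
  n <- length(classes)
  if (n == 0) {
    warn("empty simulation: all group sizes are zero")
    empty <- tibble(animal_id = character(), group = character(),
                    severity = character(), event_day = integer(),
                    event_kind = character(), exclusion_reason = character())
    return(structure(list(ledger = empty, assessments = NULL,
                          baselines = NULL, components = NULL, scores = NULL,
                          tracks = NULL, autopsy = NULL, truth = NULL,
                          config = cfg), class = "rob_simulation"))
  }
  ids <- sprintf("sim%03d", seq_len(n))
  truth <- tibble(
    animal_id = ids, class = classes,
    rt1 = NA_real_, ot1 = NA_real_, bwl1 = NA_real_,
    decline_day = NA_integer_
  )
  for (cls in unique(classes)) {
    idx <- which(classes == cls)
    p <- cfg$day1[[cls]]
    truth$rt1[idx] <- r_tnorm(length(idx), p$rt[["mean"]], p$rt[["sd"]],
                              p$rt[["min"]], p$rt[["max"]])
    truth$ot1[idx] <- r_tnorm(length(idx), p$ot[["mean"]], p$ot[["sd"]],
                              p$ot[["min"]], p$ot[["max"]])
    truth$bwl1[idx] <- r_tnorm(length(idx), p$bwl[["mean"]], p$bwl[["sd"]],
                               p$bwl[["min"]], p$bwl[["max"]])
  }
  days_onset <- as.integer(names(cfg$decline_day_probs))
  truth$decline_day <- days_onset[
    1 + findInterval(runif(n), cumsum(cfg$decline_day_probs),
                     left.open = TRUE)]
  baselines <- tibble(animal_id = ids,
                      preop_weight_g = r_tnorm(n, 25, 1.5, 20, 30))

  # Latent daily component values, then events.
  event_day <- rep(NA_integer_, n)
  event_kind <- rep(NA_character_, n)
  rows <- vector("list", n)
  rt_now <- truth$rt1; ot_now <- truth$ot1; bwl_now <- truth$bwl1
  alive <- rep(TRUE, n)
  sham <- classes == "sham"
  for (d in seq_len(cfg$follow_up_day)) {
    for (i in which(alive)) {
      if (d > 1) {
        if (d >= truth$decline_day[i] && !sham[i]) {
          rt_now[i] <- rt_now[i] * cfg$decline$rt_factor
          ot_now[i] <- ot_now[i] * cfg$decline$ot_factor
          bwl_now[i] <- bwl_now[i] + cfg$decline$bwl_step
        } else {
          rt_now[i] <- min(max(rt_now[i] + stats::rnorm(1, 0, cfg$drift$rt_sd),
                               0), 300)
          ot_now[i] <- max(ot_now[i] + stats::rnorm(1, 0, cfg$drift$ot_sd), 0)
          bwl_now[i] <- bwl_now[i] + stats::rnorm(1, 0, cfg$drift$bwl_sd)
        }
      }
      rows[[i]] <- c(rows[[i]], list(tibble(
        animal_id = ids[i], day = d,
        rt = min(max(rt_now[i], 0), 300), ot = max(ot_now[i], 0),
        bwl = bwl_now[i])))
    }
    # Mortality after the day's assessment.
    for (i in which(alive)) {
      h <- cfg$hazards[[classes[i]]][d]
      if (h > 0 && runif(1) < h) {
        alive[i] <- FALSE
        event_day[i] <- d
        event_kind[i] <- if (runif(1) < cfg$p_humane) "humane_endpoint"
          else "death"
      }
    }
    # Sham animals are euthanized after their day-1 assessment.
    if (d == 1 && any(sham & alive)) {
      for (i in which(sham & alive)) {
        alive[i] <- FALSE
        event_day[i] <- 1L
        event_kind[i] <- "scheduled_autopsy"
      }
    }
    # Scheduled autopsies among survivors.
    if (d == cfg$autopsy_day && cfg$autopsy_n > 0) {
      pool <- which(alive & !sham)
      take <- utils::head(pool[sample.int(length(pool))], cfg$autopsy_n)
      for (i in take) {
        alive[i] <- FALSE
        event_day[i] <- d
        event_kind[i] <- "scheduled_autopsy"
      }
    }
  }
  event_day[alive] <- cfg$follow_up_day
  event_kind[alive] <- "scheduled_autopsy"

  latent <- bind_rows(unlist(rows, recursive = FALSE))
  # Realize measurements: three Rotarod trials whose mean is the latent
  # latency (spread clipped so no trial leaves [0, 300]), the weight
  # implied by the latent loss percent, and the latent OT distance.
  spread <- pmin(abs(stats::rnorm(nrow(latent), 0, 15)),
                 latent$rt, 300 - latent$rt)
  assessments <- latent |>
    left_join(baselines, by = "animal_id") |>
    mutate(
      rt_trial1 = .data$rt - spread,
      rt_trial2 = .data$rt,
      rt_trial3 = .data$rt + spread,
      ot_distance = .data$ot,
      weight_g = pmax(.data$preop_weight_g * (1 - .data$bwl / 100), 1)
    ) |>
    select("animal_id", "day", "rt_trial1", "rt_trial2", "rt_trial3",
           "ot_distance", "weight_g")

  tracks <- NULL
  if (isTRUE(cfg$tracks)) {
    tracks <- purrr::map2_df(latent$animal_id, seq_len(nrow(latent)),
      function(id, j) {
        trk <- make_track_fixture(latent$ot[j], cfg$n_frames, cfg$step,
                                  cfg$fps)
        mutate(trk, animal_id = id, day = latent$day[j], .before = 1)
      })
    # Path lengths recomputed from the tracks replace the latent draw,
    # so the behavior ops sit on the actual data path.
    keyed <- tracks |>
      group_by(.data$animal_id, .data$day) |>
      group_modify(function(df, key)
        tibble(ot_distance = path_distance(
          sample_keyframes(df, 0, cfg$n_frames, cfg$step)))) |>
      ungroup()
    assessments <- assessments |>
      select(-"ot_distance") |>
      left_join(keyed, by = c("animal_id", "day"))
  }

  # Autopsy grades for every euthanized animal (scheduled harvests).
  seg_probs <- list(
    severe = c(0, 0.05, 0.35, 0.60),
    moderate = c(0.05, 0.40, 0.45, 0.10),
    mild = c(0.50, 0.45, 0.05, 0),
    sham = c(1, 0, 0, 0)
  )
  harvested <- which(event_kind == "scheduled_autopsy")
  autopsy <- purrr::map_df(harvested, function(i) {
    seg <- sample(0:3, 6, replace = TRUE, prob = seg_probs[[classes[i]]])
    tibble(animal_id = ids[i], day = event_day[i],
           seg1 = seg[1], seg2 = seg[2], seg3 = seg[3],
           seg4 = seg[4], seg5 = seg[5], seg6 = seg[6])
  })

  components <- compute_components(assessments, baselines)
  scores <- score_assessments(components)
  day1_class <- scores |>
    filter(.data$day == 1) |>
    select("animal_id", "severity")
  ledger <- tibble(
    animal_id = ids,
    group = ifelse(sham, "sham", "sah"),
    severity = ifelse(sham, NA_character_,
                      as.character(day1_class$severity[
                        match(ids, day1_class$animal_id)])),
    event_day = event_day,
    event_kind = event_kind,
    exclusion_reason = NA_character_
  )
  structure(list(
    ledger = ledger, assessments = assessments, baselines = baselines,
    components = components, scores = scores, tracks = tracks,
    autopsy = autopsy, truth = truth, config = cfg
  ), class = "rob_simulation")
}

#' @export
print.rob_simulation <- function(x, ...) {
  cat(sprintf("Synthetic ROB cohort: %d animals (seed %d)\n",
              nrow(x$ledger), x$config$seed))
  if (!is.null(x$truth)) print(table(x$truth$class))
  invisible(x)
}
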