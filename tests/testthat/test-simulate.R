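test_that("a fixed seed reproduces the cohort exactly", {
  a <- simulate_cohort(sim_config(seed = 101, tracks = FALSE))
  b <- simulate_cohort(sim_config(seed = 101, tracks = FALSE))
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$assessments, b$assessments)
  expect_identical(a$autopsy, b$autopsy)
  c <- simulate_cohort(sim_config(seed = 102, tracks = FALSE))
  expect_false(identical(a$assessments, c$assessments))
})

test_that("day-1 distributions recover their truncated-normal means at n = 1000", {
  for (cls in c("severe", "moderate", "mild")) {
    cfg <- sim_config(
      n_severe = if (cls == "severe") 1000 else 0,
      n_moderate = if (cls == "moderate") 1000 else 0,
      n_mild = if (cls == "mild") 1000 else 0,
      autopsy_n = 0, tracks = FALSE, seed = 300 + match(cls, levels(factor(cls))))
    sim <- simulate_cohort(cfg)
    p <- cfg$day1[[cls]]
    for (m in c("rt", "ot", "bwl")) {
      mom <- tnorm_moments(p[[m]][["mean"]], p[[m]][["sd"]],
                           p[[m]][["min"]], p[[m]][["max"]])
      draws <- sim$truth[[paste0(m, "1")]]
      se <- mom$sd / sqrt(length(draws))
      expect_lt(abs(mean(draws) - mom$mean), 3 * se)
      expect_true(all(draws >= p[[m]][["min"]] & draws <= p[[m]][["max"]]))
    }
  }
})

test_that("the severe-class hazard reproduces complete day-4 mortality", {
  rates <- vapply(1:200, function(s) {
    sim <- simulate_cohort(sim_config(n_severe = 6, n_moderate = 0,
                                      n_mild = 0, autopsy_n = 0,
                                      tracks = FALSE, seed = 1000 + s))
    cumulative_mortality(sim$ledger, 4)$mortality_frac
  }, numeric(1))
  expect_lt(abs(mean(rates) * 100 - 100), 5)
})

test_that("track fixtures hit their target key-frame path length", {
  still <- make_track_fixture(0, seed = 51)
  expect_equal(path_distance(still), 0)
  trk <- make_track_fixture(643, seed = 52)
  expect_equal(path_distance(sample_keyframes(trk, 0)), 643,
               tolerance = 1e-6 / 643)
  expect_equal(nrow(trk), 161L)
  expect_error(make_track_fixture(-1), "target_distance")
  expect_error(make_track_fixture(100, n_frames = 3, step = 5), "multiple")
})

test_that("generated tracks carry the assessed open-field distances end-to-end", {
  sim <- simulate_cohort(sim_config(seed = 61))
  one <- sim$assessments[5, ]
  trk <- dplyr::filter(sim$tracks, animal_id == one$animal_id,
                       day == one$day)
  expect_equal(path_distance(sample_keyframes(trk, 0)), one$ot_distance,
               tolerance = 1e-9)
})

test_that("every simulated animal appears once with a consistent history", {
  sim <- simulate_cohort(sim_config(seed = 71, tracks = FALSE))
  expect_equal(anyDuplicated(sim$ledger$animal_id), 0L)
  expect_equal(nrow(sim$ledger), 29L)
  expect_silent(validate_ledger(sim$ledger, sim$scores))
  # everyone has a terminal event by follow-up
  expect_true(all(!is.na(sim$ledger$event_day)))
  expect_true(all(sim$ledger$event_day <= 7))
  # assessments run through the terminal day inclusive, never past it
  last_seen <- sim$assessments |>
    dplyr::group_by(animal_id) |>
    dplyr::summarise(last = max(day), first = min(day))
  joined <- dplyr::left_join(sim$ledger, last_seen, by = "animal_id")
  expect_true(all(joined$last == joined$event_day))
  expect_true(all(joined$first == 1))
})

test_that("day-1 scoring recovers the latent class for most animals at defaults", {
  sim <- simulate_cohort(sim_config(seed = 81, tracks = FALSE))
  truth <- sim$truth$class[match(sim$ledger$animal_id, sim$truth$animal_id)]
  agreement <- mean(sim$ledger$severity == truth)
  expect_gte(agreement, 0.6)
})

test_that("infeasible configurations are rejected", {
  bad_day1 <- day1_defaults <- sim_config()$day1
  bad_day1$severe$rt <- c(mean = 500, sd = 1, min = 0, max = 154)
  expect_error(sim_config(day1 = bad_day1), "contain the mean")
  expect_error(sim_config(hazards = list(severe = rep(2, 7),
                                         moderate = rep(0, 7),
                                         mild = rep(0, 7),
                                         sham = rep(0, 7))), "\\[0, 1\\]")
  expect_error(sim_config(n_severe = -1), ">= 0")
  expect_warning(sim <- simulate_cohort(
    sim_config(n_severe = 0, n_moderate = 0, n_mild = 0, seed = 1)), "empty")
  expect_equal(nrow(sim$ledger), 0L)
})
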