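test_that("component sub-scores reproduce the published band examples", {
  # Rotarod: 300 s endpoint is the only score-5 value
  expect_equal(score_rotarod(300), 5L)
  expect_equal(score_rotarod(154), 3L)
  expect_equal(score_rotarod(38), 1L)
  expect_equal(score_rotarod(200.5), 4L)
  # Open-field: top band is strictly above 1000, shared edges lower-inclusive
  expect_equal(score_openfield(1305), 5L)
  expect_equal(score_openfield(39), 1L)
  expect_equal(score_openfield(300), 2L)
  expect_equal(score_openfield(1000), 4L)
  # Body-weight loss: weight gain is the healthiest band
  expect_equal(score_bwl(16.23), 2L)
  expect_equal(score_bwl(1.24), 5L)
  expect_equal(score_bwl(-2.0), 5L)
  expect_equal(score_bwl(20), 2L)
  expect_equal(score_bwl(20.01), 1L)
})

test_that("sub-score domain violations are rejected with the offending value", {
  expect_error(score_rotarod(-1), "-1")
  expect_error(score_rotarod(301), "301")
  expect_error(score_openfield(-5), "-5")
  expect_error(score_bwl(NaN), "finite")
  expect_error(score_bwl(Inf), "finite")
})

test_that("every finite input lands in exactly one band, monotonically", {
  crit <- rob_criteria()
  rt_grid <- seq(0, 300, by = 0.25)
  rt_scores <- score_rotarod(rt_grid, crit)
  expect_true(all(rt_scores %in% 1:5))
  expect_true(all(diff(rt_scores) >= 0))
  ot_grid <- seq(0, 1500, by = 0.5)
  ot_scores <- score_openfield(ot_grid, crit)
  expect_true(all(ot_scores %in% 1:5))
  expect_true(all(diff(ot_scores) >= 0))
  bwl_grid <- seq(-10, 40, by = 0.05)
  bwl_scores <- score_bwl(bwl_grid, crit)
  expect_true(all(bwl_scores %in% 1:5))
  expect_true(all(diff(bwl_scores) <= 0))  # more loss never scores higher
})

test_that("randomized pairs never reverse the better-performance ordering", {
  withr::local_seed(11)
  for (i in 1:200) {
    s <- sort(runif(2, 0, 300))
    expect_gte(score_rotarod(s[2]), score_rotarod(s[1]))
    d <- sort(runif(2, 0, 1400))
    expect_gte(score_openfield(d[2]), score_openfield(d[1]))
    w <- sort(runif(2, -5, 30))
    expect_lte(score_bwl(w[2]), score_bwl(w[1]))
  }
})

test_that("aggregate score matches the published aggregation examples", {
  expect_equal(compute_rob(300, 1200, 1.0)$total, 15L)
  expect_equal(as.character(compute_rob(300, 1200, 1.0)$severity), "mild")
  expect_equal(compute_rob(0, 50, 25.0)$total, 3L)
  expect_equal(as.character(compute_rob(0, 50, 25.0)$severity), "severe")
  expect_equal(compute_rob(120, 900, 12.0)$total, 10L)
  expect_equal(as.character(compute_rob(120, 900, 12.0)$severity), "moderate")
})

test_that("all 125 sub-score combinations span totals 3..15 and the severity bands partition them", {
  # One representative raw value per band of each component
  rt <- c(25, 75, 150, 250, 300)
  ot <- c(100, 400, 650, 900, 1100)
  bw <- c(25, 17, 12, 7, 2)
  grid <- expand.grid(rt = rt, ot = ot, bw = bw)
  res <- compute_rob(grid$rt, grid$ot, grid$bw)
  expect_equal(nrow(res), 125L)
  expect_equal(res$total, res$r_score + res$o_score + res$b_score)
  expect_setequal(unique(res$total), 3:15)
  expect_true(all(res$total >= 3 & res$total <= 15))
  # Partition: each total maps to exactly one class, no gaps or overlaps
  by_total <- tapply(as.character(res$severity), res$total,
                     function(s) unique(s))
  expect_true(all(lengths(by_total) == 1))
  expect_equal(as.vector(unlist(by_total[as.character(3:6)])), rep("severe", 4))
  expect_equal(as.vector(unlist(by_total[as.character(7:10)])), rep("moderate", 4))
  expect_equal(as.vector(unlist(by_total[as.character(11:15)])), rep("mild", 5))
})

test_that("criteria are reconfigurable and survive a YAML round trip", {
  crit <- rob_criteria(severity_cuts = c(5L, 9L))
  expect_equal(as.character(rob_severity(6L, crit)), "moderate")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_criteria(rob_criteria(), path)
  reread <- read_criteria(path)
  grid <- seq(0, 300, by = 1)
  expect_equal(score_rotarod(grid, reread), score_rotarod(grid))
  expect_error(rob_criteria(severity_cuts = c(10L, 6L)), "severity_cuts")
  expect_error(
    rob_criteria(rotarod = list(thresholds = c(50, 40, 200, 300),
                                strict = rep(TRUE, 4), direction = "asc")),
    "increasing")
})

test_that("score_assessments recomputes from raw values unless explicitly overridden", {
  comp <- tibble::tibble(animal_id = "a", day = 1, rotarod_s = 300,
                         openfield_dist = 1200, bwl_pct = 1,
                         r_score = 1L, o_score = 1L, b_score = 1L)
  recomputed <- score_assessments(comp)
  expect_equal(recomputed$total, 15L)  # pre-binned 1/1/1 ignored
  overridden <- score_assessments(comp, allow_prebinned = TRUE)
  expect_equal(overridden$total, 3L)
  expect_error(score_assessments(tibble::tibble(animal_id = "a")), "missing")
})
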