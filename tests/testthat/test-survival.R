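scored_study <- build_valid_cohort(cwp_example_cohort())$scored

test_that("KM estimates handle all-censored and all-event extremes", {
  censored <- mini_ledger(rep(c("mild", "moderate"), each = 3), rep(7, 6),
                          rep("scheduled_autopsy", 6))
  expect_warning(km <- km_curves(censored), "severe")
  expect_true(all(km$surv == 1))
  doomed <- mini_ledger(rep(c("severe", "moderate"), each = 3), rep(1, 6),
                        rep("death", 6))
  km2 <- suppressWarnings(km_curves(doomed))
  expect_equal(km2$surv[km2$time == 1], rep(0, 2))
})

test_that("KM severe arm of the study ledger reaches zero at day four", {
  km <- km_curves(scored_study)
  severe <- dplyr::filter(km, severity == "severe")
  expect_equal(severe$surv[severe$time == 4], 0)
  expect_true(all(diff(severe$surv) <= 0))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
})

test_that("without censoring KM equals the empirical survival fraction", {
  withr::local_seed(13)
  days <- sample(1:6, 12, replace = TRUE)
  ledger <- mini_ledger(rep("moderate", 12), days, rep("death", 12))
  km <- suppressWarnings(km_curves(ledger))
  for (t in sort(unique(days))) {
    expect_equal(km$surv[km$time == t], mean(days > t), tolerance = 1e-12)
  }
})

test_that("log-rank statistic agrees with a from-scratch oracle and survdiff", {
  dat <- cohort_survival_data(scored_study)
  oracle <- logrank_chisq_oracle(dat$time, dat$status, dat$severity)
  lr <- logrank_test(scored_study)
  expect_equal(lr$statistic, oracle, tolerance = 1e-10)
  expect_equal(lr$df, 2L)
  expect_lt(lr$p_value, 0.05)
})

test_that("identical group event tables give a near-zero statistic", {
  twin <- mini_ledger(rep(c("mild", "moderate"), each = 4),
                      rep(c(2, 3, 5, 7), 2),
                      rep(c("death", "death", "death", "scheduled_autopsy"), 2))
  lr <- suppressWarnings(logrank_test(twin))
  expect_lt(lr$statistic, 1e-10)
  expect_gt(lr$p_value, 0.999)
  solo <- mini_ledger(rep("mild", 4), rep(7, 4), rep("scheduled_autopsy", 4))
  expect_error(suppressWarnings(logrank_test(solo)), "2")
})

test_that("asymptotic log-rank p agrees with a permutation oracle on a small table", {
  withr::local_seed(17)
  ledger <- mini_ledger(
    rep(c("severe", "mild"), each = 8),
    c(1, 2, 2, 3, 4, 5, 7, 7, 3, 5, 6, 7, 7, 7, 7, 7),
    c(rep("death", 6), rep("scheduled_autopsy", 2),
      rep("death", 3), rep("scheduled_autopsy", 5)))
  dat <- suppressWarnings(cohort_survival_data(ledger))
  p_perm <- logrank_permutation_p(dat$time, dat$status, dat$severity,
                                  n_perm = 10000)
  p_asym <- suppressWarnings(logrank_test(ledger))$p_value
  # Monte-Carlo error ~ sqrt(p(1-p)/1e4) plus asymptotic slack at n=16
  expect_lt(abs(p_asym - p_perm), 0.05)
})

test_that("log-rank is invariant to relabeling and to censoring-time shifts past the last event", {
  lr <- logrank_test(scored_study)
  relabeled <- scored_study
  relabeled$severity <- c(severe = "mild", moderate = "severe",
                          mild = "moderate")[relabeled$severity]
  expect_equal(logrank_test(relabeled)$statistic, lr$statistic,
               tolerance = 1e-12)
  # moving censoring times beyond the last event day cannot change the
  # statistic (risk sets at event times are unaffected)
  shifted <- scored_study
  late <- shifted$event_kind == "scheduled_autopsy" & shifted$event_day == 7
  shifted$event_day[late] <- 10L
  expect_equal(logrank_test(shifted)$statistic, lr$statistic,
               tolerance = 1e-12)
})

test_that("one-way ANOVA F matches the sums-of-squares oracle to 1e-10", {
  withr::local_seed(19)
  for (i in 1:10) {
    g <- rep(c("a", "b", "c"), times = sample(3:12, 3, replace = TRUE))
    y <- rnorm(length(g), mean = as.integer(factor(g)))
    fit <- oneway_anova(tibble::tibble(y = y, g = g), y, g)
    expect_equal(fit$f_statistic, anova_f_oracle(y, g), tolerance = 1e-10)
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::local_seed(23)
  y1 <- rnorm(8); y2 <- rnorm(10, 1)
  dat <- tibble::tibble(y = c(y1, y2), g = rep(c("a", "b"), c(8, 10)))
  fit <- oneway_anova(dat, y, g)
  t2 <- t.test(y1, y2, var.equal = TRUE)$statistic^2
  expect_equal(fit$f_statistic, unname(t2), tolerance = 1e-10)
})

test_that("degenerate ANOVA inputs warn or error as appropriate", {
  flat <- tibble::tibble(y = rep(5, 6), g = rep(c("a", "b"), 3))
  expect_warning(fit <- oneway_anova(flat, y, g), "zero variance")
  expect_equal(fit$p_value, 1)
  tiny <- tibble::tibble(y = c(1, 2, 3), g = c("a", "a", "b"))
  expect_error(oneway_anova(tiny, y, g), "b")
  expect_error(oneway_anova(tibble::tibble(y = 1:4, g = "a"), y, g), "2 groups")
})

test_that("pairwise comparisons carry the requested adjustment", {
  withr::local_seed(29)
  dat <- tibble::tibble(y = rnorm(30, rep(c(0, 1, 3), each = 10)),
                        g = rep(c("a", "b", "c"), each = 10))
  tk <- oneway_anova(dat, y, g)
  expect_equal(nrow(tidy(tk)), 3L)
  bf <- oneway_anova(dat, y, g, adjust = "bonferroni")
  hl <- oneway_anova(dat, y, g, adjust = "holm")
  expect_true(all(hl$pairwise$p_adj <= bf$pairwise$p_adj + 1e-12))
  expect_equal(glance(tk)$statistic, glance(bf)$statistic)
})
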