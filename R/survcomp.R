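#' Survival-format view of a cohort ledger
#'
#' Deaths and humane-endpoint euthanasias become events at their day;
#' scheduled autopsies are right-censored at their day; animals with no
#' terminal event are censored at `end_day`.
#'
#' @inheritParams cumulative_mortality
#' @param end_day Censoring day for animals with no recorded event
#'   (default: the latest event day in the ledger).
#' @return Tibble `animal_id`, `severity`, `time`, `status`
#'   (1 = mortality event, 0 = censored).
#' @export
cohort_survival_data <- function(cohort, end_day = NULL) {
  cohort <- validate_ledger(cohort)
  if (any(is.na(cohort$severity)))
    stop_robscore(paste0("severity missing for: ",
                         paste(cohort$animal_id[is.na(cohort$severity)],
                               collapse = ", ")))
  end_day <- end_day %||% max(cohort$event_day, na.rm = TRUE)
  tibble(
    animal_id = cohort$animal_id,
    severity = severity_factor(cohort$severity),
    time = ifelse(is.na(cohort$event_day), end_day, cohort$event_day),
    status = as.integer(cohort$event_kind %in% MORTALITY_EVENTS &
                          !is.na(cohort$event_kind))
  )
}

#' Kaplan-Meier survival curves per severity class
#'
#' Standard product-limit estimate per severity class, with mortality
#' events (deaths and humane-endpoint euthanasias) as events and
#' scheduled autopsies as right-censoring. Severity classes with no
#' animals are omitted with a warning.
#'
#' @inheritParams cohort_survival_data
#' @return A tibble of class `rob_km` with columns `severity`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (each class starts with a
#'   `time = 0`, `surv = 1` anchor row). Plot with [autoplot()].
#' @examples
#' scored <- build_valid_cohort(cwp_example_cohort())$scored
#' km <- km_curves(scored)
#' dplyr::filter(km, severity == "severe")  # reaches 0 at day 4
#' @export
km_curves <- function(cohort, end_day = NULL) {
  dat <- cohort_survival_data(cohort, end_day)
  empty <- setdiff(SEVERITY_LEVELS, as.character(unique(dat$severity)))
  if (length(empty))
    warn(paste0("no animals in severity class(es): ",
                paste(empty, collapse = ", ")))
  dat$severity <- droplevels(dat$severity)
  fit <- survival::survfit(survival::Surv(time, status) ~ severity,
                           data = dat)
  smry <- summary(fit, censored = TRUE)
  strata <- if (is.null(smry$strata))
    rep(levels(dat$severity)[1], length(smry$time))
  else sub("^severity=", "", as.character(smry$strata))
  curves <- tibble(
    severity = severity_factor(strata),
    time = smry$time, n_risk = smry$n.risk, n_event = smry$n.event,
    n_censor = smry$n.censor, surv = smry$surv
  )
  anchors <- curves |>
    distinct(.data$severity) |>
    mutate(time = 0, n_risk = NA_integer_, n_event = 0L, n_censor = 0L,
           surv = 1)
  anchors$n_risk <- vapply(as.character(anchors$severity), function(s)
    sum(as.character(dat$severity) == s), integer(1))
  out <- bind_rows(anchors, curves) |>
    arrange(.data$severity, .data$time)
  class(out) <- c("rob_km", class(out))
  out
}

#' K-group log-rank test across severity classes
#'
#' Compares the survival distributions of the severity subgroups with
#' the standard log-rank (Mantel-Haenszel) test; the p-value comes from
#' the chi-square asymptotic distribution with `k - 1` degrees of
#' freedom. Tied event days use the usual hypergeometric tie handling;
#' deaths recorded "on day d" are taken to occur at time d exactly.
#'
#' @inheritParams cohort_survival_data
#' @return An object of class `rob_logrank`: list with `statistic`,
#'   `df`, `p_value`, and a per-group `table` (n, observed, expected).
#'   [tidy()] returns the per-group table, [glance()] the test summary.
#' @examples
#' scored <- build_valid_cohort(cwp_example_cohort())$scored
#' glance(logrank_test(scored))
#' @export
logrank_test <- function(cohort, end_day = NULL) {
  dat <- cohort_survival_data(cohort, end_day)
  dat$severity <- droplevels(dat$severity)
  k <- nlevels(dat$severity)
  if (k < 2)
    stop_robscore("log-rank test needs at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, status) ~ severity,
                           data = dat)
  df <- k - 1
  structure(list(
    statistic = unname(sd$chisq),
    df = df,
    p_value = pchisq(unname(sd$chisq), df, lower.tail = FALSE),
    table = tibble(
      severity = sub("^severity=", "", names(sd$n)),
      n = as.integer(sd$n),
      observed = as.numeric(sd$obs),
      expected = as.numeric(sd$exp)
    )
  ), class = "rob_logrank")
}

#' @export
print.rob_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$table)
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `rob_logrank` object.
#' @param ... Unused.
#' @method tidy rob_logrank
#' @export
tidy.rob_logrank <- function(x, ...) x$table

#' @rdname logrank_test
#' @method glance rob_logrank
#' @export
glance.rob_logrank <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value)
}

#' One-way ANOVA with pairwise multiple comparisons
#'
#' Ordinary one-way ANOVA of a measurement across groups (the protocol
#' compares day-1 Rotarod, open-field and body-weight-loss values across
#' severity classes and sham), followed by pairwise comparisons with a
#' family-wise adjustment: Tukey's HSD by default, or Bonferroni/Holm
#' adjusted pairwise t tests.
#'
#' If every group is a constant with zero variance the F statistic is
#' undefined; the test returns `p = 1` with a warning rather than
#' failing.
#'
#' @param data Data frame in long format.
#' @param value,group Column names (unquoted) of the measurement and the
#'   grouping variable.
#' @param adjust `"tukey"` (default), `"bonferroni"`, or `"holm"`.
#' @return An object of class `rob_anova`: list with `f_statistic`,
#'   `df`, `p_value`, `pairwise` (tibble `comparison`, `estimate`,
#'   `p_adj`), and `adjust`. [glance()] returns the omnibus test,
#'   [tidy()] the pairwise table.
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 5),
#'                  y = c(rnorm(5), rnorm(5, 2), rnorm(5, 4)))
#' glance(oneway_anova(df, y, g))
#' @export
oneway_anova <- function(data, value, group,
                         adjust = c("tukey", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  data <- as_tibble(data)
  y <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- is.finite(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (nlevels(g) < 2)
    stop_robscore("one-way ANOVA needs at least 2 groups")
  if (any(sizes < 2))
    stop_robscore(paste0("every group needs >= 2 values; too small: ",
                         paste(names(sizes)[sizes < 2], collapse = ", ")))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  within_ss <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (within_ss == 0 && all(tapply(y, g, sd) == 0)) {
    warn("all groups have zero variance; F is undefined, returning p = 1")
    pair_names <- utils::combn(levels(g), 2, paste, collapse = " - ")
    return(structure(list(
      f_statistic = NA_real_, df = c(df1, df2), p_value = 1,
      pairwise = tibble(comparison = pair_names, estimate = NA_real_,
                        p_adj = NA_real_),
      adjust = adjust
    ), class = "rob_anova"))
  }
  fit <- aov(y ~ g)
  tab <- anova(fit)
  pairwise <- if (adjust == "tukey") {
    hsd <- TukeyHSD(fit)$g
    tibble(comparison = rownames(hsd), estimate = hsd[, "diff"],
           p_adj = hsd[, "p adj"])
  } else {
    pt <- pairwise.t.test(y, g, p.adjust.method = adjust)$p.value
    means <- tapply(y, g, mean)
    purrr::map_df(rownames(pt), function(a)
      purrr::map_df(colnames(pt), function(b) {
        if (is.na(pt[a, b])) return(NULL)
        tibble(comparison = paste(a, "-", b),
               estimate = unname(means[a] - means[b]),
               p_adj = pt[a, b])
      }))
  }
  structure(list(
    f_statistic = tab$`F value`[1],
    df = c(df1, df2),
    p_value = tab$`Pr(>F)`[1],
    pairwise = pairwise,
    adjust = adjust
  ), class = "rob_anova")
}

#' @export
print.rob_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  cat(sprintf("Pairwise comparisons (%s):\n", x$adjust))
  print(x$pairwise)
  invisible(x)
}

#' @rdname oneway_anova
#' @param x A `rob_anova` object.
#' @param ... Unused.
#' @method tidy rob_anova
#' @export
tidy.rob_anova <- function(x, ...) x$pairwise

#' @rdname oneway_anova
#' @method glance rob_anova
#' @export
glance.rob_anova <- function(x, ...) {
  tibble(statistic = x$f_statistic, df = x$df[1], df.residual = x$df[2],
         p.value = x$p_value, adjust = x$adjust)
}
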