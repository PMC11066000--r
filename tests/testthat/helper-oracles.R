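# Independent oracles used to cross-check the package's computations.

# Brute-force path length: explicit loop over consecutive pairs.
path_length_oracle <- function(x, y) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    total <- total + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  total
}

# From-scratch k-group log-rank chi-square (hypergeometric variance with
# the standard tie correction), independent of the survival package.
logrank_chisq_oracle <- function(time, status, group) {
  group <- factor(group)
  k <- nlevels(group)
  lev <- levels(group)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[status == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(status == 1 & time == t)
    nj <- vapply(lev, function(g) sum(at_risk & group == g), numeric(1))
    dj <- vapply(lev, function(g) sum(status == 1 & time == t & group == g),
                 numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      for (a in seq_len(k)) for (b in seq_len(k)) {
        V[a, b] <- V[a, b] + d * (n - d) / (n - 1) *
          (if (a == b) nj[a] * (n - nj[a]) else -nj[a] * nj[b]) / n^2
      }
    }
  }
  u <- (O - E)[-1]
  Vm <- V[-1, -1, drop = FALSE]
  drop(t(u) %*% solve(Vm) %*% u)
}

# Monte-Carlo permutation p-value for the log-rank statistic.
logrank_permutation_p <- function(time, status, group, n_perm = 10000) {
  obs <- logrank_chisq_oracle(time, status, group)
  hits <- 0
  for (b in seq_len(n_perm)) {
    perm <- sample(group)
    if (logrank_chisq_oracle(time, status, perm) >= obs - 1e-12)
      hits <- hits + 1
  }
  hits / n_perm
}

# Direct sums-of-squares one-way ANOVA F statistic.
anova_f_oracle <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  (ssb / df1) / (ssw / df2)
}

# A simple ledger with one row per animal, for survival edge cases.
mini_ledger <- function(severity, event_day, event_kind) {
  tibble::tibble(
    animal_id = sprintf("a%02d", seq_along(severity)),
    group = "sah", severity = severity,
    event_day = as.integer(event_day), event_kind = event_kind,
    exclusion_reason = NA_character_
  )
}
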