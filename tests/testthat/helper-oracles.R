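# independent oracles used by the stats and acceptance suites

# general-linear-model oracle for the split-plot 2x2 design (aov with an
# explicit Error stratum), fitted independently of mixed_anova_2x2
aov_oracle <- function(values, group) {
  df <- data.frame(
    y = c(values[, 1], values[, 2]),
    cond = factor(rep(c("a", "b"), each = nrow(values))),
    subj = factor(rep(seq_len(nrow(values)), 2)),
    grp = factor(rep(group, 2)))
  fit <- summary(stats::aov(y ~ grp * cond + Error(subj / cond), data = df))
  between <- fit[["Error: subj"]][[1]]
  within <- fit[["Error: subj:cond"]][[1]]
  list(F = c(group = between["grp", "F value"],
             condition = within["cond", "F value"],
             interaction = within["grp:cond", "F value"]),
       p = c(group = between["grp", "Pr(>F)"],
             condition = within["cond", "Pr(>F)"],
             interaction = within["grp:cond", "Pr(>F)"]))
}

# independent exhaustive enumerator for the paired permutation scheme
enum_oracle <- function(a, b) {
  n <- length(a)
  swaps <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  t_obs <- sum(a)^2 + sum(b)^2
  t_null <- apply(swaps, 1L, function(s) {
    s1 <- ifelse(s, b, a)
    s2 <- ifelse(s, a, b)
    sum(s1)^2 + sum(s2)^2
  })
  mean(t_null >= t_obs - 1e-9 * max(1, abs(t_obs)))
}

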