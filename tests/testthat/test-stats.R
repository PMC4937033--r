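test_that("the split-plot ANOVA matches the general-linear-model oracle", {
  set.seed(21)
  for (rep in 1:25) {
    v <- cbind(rnorm(24, sd = runif(1, 0.5, 2)), rnorm(24))
    g <- rep(c("ASD", "CTRL"), each = 12)
    mine <- mixed_anova_2x2(v, g)
    orc <- aov_oracle(v, g)
    expect_equal(stats::setNames(mine$effects$F, mine$effects$effect),
                 orc$F, tolerance = 1e-8)
    expect_equal(stats::setNames(mine$effects$p, mine$effects$effect),
                 orc$p, tolerance = 1e-8)
    expect_equal(mine$effects$df2, rep(22L, 3))
  }
})

test_that("degenerate and structured ANOVA inputs behave", {
  # identical groups and identical conditions: all F are zero
  v0 <- cbind(rep(1, 8), rep(1, 8))
  a0 <- mixed_anova_2x2(v0, rep(c("x", "y"), each = 4))
  expect_equal(a0$effects$F, rep(0, 3))

  # the interaction F is the squared two-sample t on condition differences
  set.seed(22)
  v <- cbind(rnorm(20), rnorm(20))
  g <- rep(c("x", "y"), each = 10)
  a <- mixed_anova_2x2(v, g)
  d <- v[, 2] - v[, 1]
  tt <- stats::t.test(d[g == "x"], d[g == "y"], var.equal = TRUE)
  expect_equal(a$effects$F[a$effects$effect == "interaction"],
               unname(tt$statistic^2), tolerance = 1e-10)

  expect_error(mixed_anova_2x2(v, rep("x", 20)), "two groups")
  expect_error(mixed_anova_2x2(v[1:3, ], c("x", "x", "y")), "at least 2")
})

test_that("exhaustive paired permutation enumerates all 2^n assignments", {
  set.seed(23)
  a <- rnorm(12); b <- rnorm(12)
  res <- paired_permutation_test(a, b)
  expect_equal(res$n_null, 4096)
  expect_identical(res$scheme, "exhaustive_paired")
  expect_true(res$p > 0 && res$p <= 1)

  # identical conditions: p = 1
  expect_equal(paired_permutation_test(a, a)$p, 1)

  # all pair differences equal and nonzero: only the identity and the
  # full swap reach the observed statistic
  n <- 12
  a2 <- 1:12 + 0.5; b2 <- 1:12 - 0.5
  expect_equal(paired_permutation_test(a2, b2)$p, 2 / 2^n)

  expect_error(paired_permutation_test(rnorm(21), rnorm(21)), "n > 20")
})

test_that("permutation p-values equal an independently coded enumerator", {
  set.seed(24)
  for (n in c(3, 5, 8)) {
    for (rep in 1:3) {
      a <- rnorm(n); b <- rnorm(n)
      expect_equal(paired_permutation_test(a, b)$p, enum_oracle(a, b))
    }
  }
})

test_that("T is monotone in the squared difference of sums", {
  # with the totals fixed, the T-based p equals the squared-difference p
  set.seed(25)
  a <- rnorm(10); b <- rnorm(10)
  d <- a - b
  swaps <- as.matrix(expand.grid(rep(list(c(1, -1)), 10)))
  diff_null <- (swaps %*% d)^2
  p_diff <- mean(diff_null >= sum(d)^2 - 1e-12)
  expect_equal(paired_permutation_test(a, b)$p, p_diff)
})

test_that("randomization tests separate what should be separated", {
  set.seed(26)
  a <- rnorm(12)
  res <- randomization_test(a, a, n_rand = 2000, seed = 5)
  expect_gt(res$p, 0.5)
  # strongly separated groups
  res2 <- randomization_test(rnorm(12, 10, 0.1), rnorm(12, 0, 0.1),
                             n_rand = 10000, seed = 5)
  expect_lte(res2$p, 0.001)
  expect_gt(res2$p, 0)                       # the +1 rule forbids zero
  # deterministic under the same seed
  res3 <- randomization_test(rnorm(12, 10, 0.1), rnorm(12, 0, 0.1),
                             n_rand = 1000, seed = 77)
  res4 <- randomization_test(rnorm(12, 10, 0.1), rnorm(12, 0, 0.1),
                             n_rand = 1000, seed = 77)
  expect_identical(res3$p, res4$p)
})

test_that("the adjacency rule keeps only clusters of >= 4 electrodes", {
  # toy graph: a path of six electrodes plus two isolated ones
  adj <- structure(list(names = paste0("e", 1:8),
                        edges = cbind(1:5, 2:6)),
                   class = "electrode_adjacency")
  set.seed(27)
  n_subj <- 16
  g <- rep(c("A", "B"), each = n_subj / 2)
  mk <- function(effect_at) {
    ca <- array(rnorm(8 * 1 * n_subj, sd = 0.1), c(8, 1, n_subj),
                dimnames = list(adj$names, NULL, NULL))
    cb <- ca
    # strong condition-by-group interaction at the chosen electrodes
    cb[effect_at, 1, g == "B"] <- cb[effect_at, 1, g == "B"] + 5
    list(ca = ca, cb = cb)
  }
  # effect on a connected path of 4: retained
  d4 <- mk(1:4)
  m4 <- mass_univariate(d4$ca, d4$cb, g, adj, alpha_corrected = 0.00125)
  expect_true(all(m4$mask[1:4, 1, "interaction"]))
  # effect on only 3 adjacent electrodes: masked out entirely
  d3 <- mk(1:3)
  m3 <- mass_univariate(d3$ca, d3$cb, g, adj, alpha_corrected = 0.00125)
  expect_false(any(m3$mask[, , "interaction"]))
  # effect on 4 electrodes, one disconnected: masked out
  dd <- mk(c(1:3, 7))
  md <- mass_univariate(dd$ca, dd$cb, g, adj, alpha_corrected = 0.00125)
  expect_false(any(md$mask[, , "interaction"]))
  # raising the threshold never removes a masked electrode
  m4b <- mass_univariate(d4$ca, d4$cb, g, adj, alpha_corrected = 0.01)
  expect_true(all(m4b$mask[m4$mask]))
})

test_that("injected effects are recovered on the standard montage", {
  lay <- standard_layout_64()
  adj <- electrode_adjacency(lay)
  # the left-central patch around C3/C5 with its graph neighbours
  target <- c("C3", "C5", "C1", "CP3", "CP5", "FC3")
  ti <- match(target, adj$names)
  set.seed(28)
  jac <- replicate(10, {
    n_subj <- 20
    g <- rep(c("A", "B"), each = 10)
    ca <- array(rnorm(64 * 1 * n_subj), c(64, 1, n_subj),
                dimnames = list(adj$names, NULL, NULL))
    cb <- ca + array(rnorm(64 * 1 * n_subj, sd = 0.3), c(64, 1, n_subj))
    cb[ti, 1, g == "B"] <- cb[ti, 1, g == "B"] + 4
    m <- mass_univariate(ca, cb, g, adj, alpha_corrected = 0.005)
    found <- which(m$mask[, 1, "interaction"])
    length(intersect(found, ti)) / length(union(found, ti))
  })
  expect_gt(mean(jac), 0.5)
})

test_that("spearman matches the reference implementation and handles ties", {
  x <- 1:10
  expect_equal(spearman_cor(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  set.seed(29)
  a <- rnorm(22); b <- 0.4 * a + rnorm(22)
  res <- spearman_cor(a, b)
  ref <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  # average ranks under ties
  xt <- c(1, 1, 2, 3); yt <- c(2, 2, 4, 9)
  expect_equal(spearman_cor(c(xt, 5:8), c(yt, 9:12))$rho,
               cor(rank(c(xt, 5:8)), rank(c(yt, 9:12))))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:3, 1:3), "length")
})

test_that("stat maps export as tidy tables", {
  adj <- structure(list(names = paste0("e", 1:5),
                        edges = cbind(1:4, 2:5)),
                   class = "electrode_adjacency")
  set.seed(30)
  ca <- array(rnorm(5 * 2 * 8), c(5, 2, 8),
              dimnames = list(adj$names, NULL, NULL))
  cb <- ca + rnorm(length(ca), sd = 0.5)
  m <- mass_univariate(ca, cb, rep(c("A", "B"), each = 4), adj, 0.05,
                       min_cluster = 2)
  tab <- stat_map_table(m, grid = scan_grid(c(0, 0.02), 0.01))
  expect_equal(nrow(tab), 5 * 2 * 3)
  expect_true(all(c("effect", "electrode", "F", "p", "significant",
                    "window_start_ms") %in% names(tab)))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
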