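# Inference layer -------------------------------------------------------------

#' Split-plot 2x2 mixed ANOVA
#'
#' Repeated-measures analysis of variance with one between-subject factor
#' (group, 2 levels) and one within-subject factor (condition, e.g.
#' predictability: predictable vs. random). Sums of squares are computed
#' from scratch with the classic split-plot partition: between-subject
#' variation into group and subject-within-group (the error term for the
#' group effect); within-subject variation into condition, condition x
#' group, and the condition x subject residual (the error term for both
#' within effects). With two levels per factor no sphericity correction is
#' needed. All three effects have df = (1, n1 + n2 - 2).
#'
#' @param values numeric matrix, subjects x 2 conditions (columns:
#'   condition A, condition B).
#' @param group factor or vector of length `nrow(values)` with exactly two
#'   levels; each group needs at least 2 subjects. Group sizes should be
#'   equal (balanced design).
#' @return An object of class `mixed_anova`: list of `effects` (data frame
#'   with F, df1, df2, p for `group`, `condition`, `interaction`) plus the
#'   full SS table.
#' @export
#' @examples
#' set.seed(1)
#' v <- cbind(rnorm(24), rnorm(24))
#' mixed_anova_2x2(v, rep(c("A", "B"), each = 12))
mixed_anova_2x2 <- function(values, group) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == 2L, nrow(values) == length(group),
            !anyNA(values))
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  ng <- table(g)
  if (any(ng < 2L)) stop("each group needs at least 2 subjects")
  n <- nrow(values)
  grand <- mean(values)
  subj_means <- rowMeans(values)
  cond_means <- colMeans(values)
  group_means <- tapply(subj_means, g, mean)
  # cell means: group x condition
  cell <- rbind(colMeans(values[g == levels(g)[1L], , drop = FALSE]),
                colMeans(values[g == levels(g)[2L], , drop = FALSE]))

  ss_total <- sum((values - grand)^2)
  ss_subjects <- 2 * sum((subj_means - grand)^2)
  ss_group <- 2 * sum(ng * (group_means - grand)^2)
  ss_subj_err <- ss_subjects - ss_group
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_int <- sum(2 * ng *
                rowSums((cell - matrix(group_means, 2L, 2L) -
                         matrix(cond_means, 2L, 2L, byrow = TRUE) +
                         grand)^2) / 2)
  ss_within_err <- ss_total - ss_subjects - ss_cond - ss_int

  # guard the subtractive partitions against catastrophic cancellation
  eps <- 1e-12 * max(ss_total, 1)
  ss_subj_err <- max(ss_subj_err, 0)
  ss_within_err <- max(ss_within_err, 0)

  df_err <- n - 2L
  eff <- data.frame(
    effect = c("group", "condition", "interaction"),
    ss = c(ss_group, ss_cond, ss_int),
    df1 = 1L, df2 = df_err,
    ms_error = c(ss_subj_err / df_err, ss_within_err / df_err,
                 ss_within_err / df_err),
    stringsAsFactors = FALSE)
  # a zero effect SS is F = 0 even when its error term is also zero; a
  # positive effect SS over a zero error term is F = Inf (p = 0)
  eff$F <- ifelse(eff$ss <= eps, 0,
                  ifelse(eff$ms_error <= eps, Inf,
                         (eff$ss / eff$df1) / eff$ms_error))
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  structure(list(effects = eff,
                 ss = c(total = ss_total, group = ss_group,
                        subject_within_group = ss_subj_err,
                        condition = ss_cond, interaction = ss_int,
                        within_error = ss_within_err),
                 n_subjects = n, groups = levels(g)),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed 2x2 ANOVA (between: group", paste(x$groups, collapse = " vs "),
      "; within: condition)\n")
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-12s F(%d, %d) = %.3f, p = %.4g\n", e$effect[i],
                e$df1[i], e$df2[i], e$F[i], e$p[i]))
  }
  invisible(x)
}

# permutation statistic: sum of squared sums of the two samples
sum_sq_sums <- function(a, b) sum(a)^2 + sum(b)^2

#' Exhaustive paired permutation test
#'
#' Within-subject comparison of two conditions over n paired values. For
#' every one of the 2^n within-pair swap assignments the two condition
#' samples are re-formed and the statistic T = (sum of sample 1)^2 + (sum of
#' sample 2)^2 is computed; the p-value is the fraction of assignments whose
#' T is at least the observed one (the identity assignment is part of the
#' enumeration, so p >= 1/2^n). With the pair totals fixed, T is a monotone
#' function of the squared difference of the condition sums, so this is the
#' two-sided test of zero mean difference. For the study's 12 subjects the
#' null distribution has exactly 4096 entries.
#'
#' @param a,b numeric vectors of paired condition values (same length n <=
#'   20; for larger n use [randomization_test()] on the differences).
#' @return An object of class `perm_test`: list with `statistic`, `p`,
#'   `n_null` (2^n), `scheme = "exhaustive_paired"`.
#' @export
paired_permutation_test <- function(a, b) {
  stopifnot(length(a) == length(b), !anyNA(a), !anyNA(b))
  n <- length(a)
  if (n > 20L) stop("n > 20: exhaustive enumeration infeasible; ",
                    "use randomization_test on the differences")
  if (n < 1L) stop("need at least one pair")
  d <- a - b
  s_tot <- sum(a + b)
  # all 2^n values of sum(+-d); T = (s_tot^2 + (sum +-d)^2) / 2
  sums <- 0
  for (i in seq_len(n)) sums <- c(sums + d[i], sums - d[i])
  t_null <- (s_tot^2 + sums^2) / 2
  t_obs <- sum_sq_sums(a, b)
  tol <- 1e-9 * max(1, abs(t_obs))
  p <- mean(t_null >= t_obs - tol)
  structure(list(statistic = t_obs, p = p, n_null = 2^n,
                 n_pairs = n, scheme = "exhaustive_paired"),
            class = "perm_test")
}

#' Randomization test for two independent groups
#'
#' Between-group comparison: group labels are shuffled `n_rand` times
#' (default 10,000) preserving the group sizes; the statistic is the same
#' sum of squared group sums as in [paired_permutation_test()]. The p-value
#' uses the add-one rule p = (1 + #\{T_rand >= T_obs\}) / (1 + n_rand), so
#' it is never exactly zero.
#'
#' @param a,b numeric vectors (the two groups, any sizes >= 1).
#' @param n_rand number of random label assignments.
#' @param seed integer RNG seed.
#' @return A `perm_test` with `scheme = "random_unpaired"`.
#' @export
randomization_test <- function(a, b, n_rand = 10000L, seed = 1L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L, !anyNA(a), !anyNA(b))
  set.seed(as.integer(seed))
  pool <- c(a, b)
  na <- length(a)
  t_obs <- sum_sq_sums(a, b)
  s_tot <- sum(pool)
  tol <- 1e-9 * max(1, abs(t_obs))
  hits <- 0L
  for (r in seq_len(n_rand)) {
    ia <- sample.int(length(pool), na)
    sa <- sum(pool[ia])
    if (sa^2 + (s_tot - sa)^2 >= t_obs - tol) hits <- hits + 1L
  }
  structure(list(statistic = t_obs, p = (1 + hits) / (1 + n_rand),
                 n_null = n_rand, scheme = "random_unpaired"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s test: T = %.4g, p = %.4g (null size %d)\n",
              if (x$scheme == "exhaustive_paired") "Exhaustive paired permutation"
              else "Randomization", x$statistic, x$p, x$n_null))
  invisible(x)
}

#' Mass-univariate electrode-by-window scan
#'
#' Runs the split-plot 2x2 ANOVA independently in every electrode x window
#' cell of per-subject measure arrays (from [scan_windows()] or band-power
#' tables), then applies the multiple-comparison rule: a cell is significant
#' when its p-value is below `alpha_corrected` (the base alpha divided by
#' the number of windows, e.g. 0.05/40 = 0.00125 for the 10 ms transient
#' scan grid, or the fixed 0.005 used for the 200 ms time-frequency grid)
#' AND its electrode belongs, within that window, to a connected set of at
#' least `min_cluster` sub-threshold electrodes on the adjacency graph.
#'
#' @param cond_a,cond_b numeric arrays, channels x windows x subjects: the
#'   per-subject measures under the two within-subject conditions.
#' @param group group labels (one per subject).
#' @param adjacency an [electrode_adjacency()] graph covering the channels.
#' @param alpha_corrected corrected per-cell threshold.
#' @param min_cluster minimum connected significant set size (default 4).
#' @return An object of class `stat_map`: list with per-effect F and p
#'   matrices (channels x windows), the `mask` array (channels x windows x
#'   effect), `alpha_corrected`, `min_cluster`, `adjacency`.
#' @export
mass_univariate <- function(cond_a, cond_b, group, adjacency,
                            alpha_corrected, min_cluster = 4L) {
  stopifnot(identical(dim(cond_a), dim(cond_b)))
  chans <- dimnames(cond_a)[[1L]]
  if (is.null(chans)) stop("channel dimnames required")
  ai <- match(chans, adjacency$names)
  if (anyNA(ai)) stop("adjacency graph does not cover all electrodes")
  nch <- dim(cond_a)[1L]; nw <- dim(cond_a)[2L]
  effects <- c("group", "condition", "interaction")
  Fm <- pm <- array(NA_real_, c(nch, nw, 3L),
                    dimnames = list(chans, NULL, effects))
  for (e_i in seq_len(nch)) {
    for (w in seq_len(nw)) {
      v <- cbind(cond_a[e_i, w, ], cond_b[e_i, w, ])
      res <- mixed_anova_2x2(v, group)
      Fm[e_i, w, ] <- res$effects$F
      pm[e_i, w, ] <- res$effects$p
    }
  }
  mask <- array(FALSE, dim(pm), dimnames = dimnames(pm))
  for (eff in seq_len(3L)) {
    for (w in seq_len(nw)) {
      sig <- which(pm[, w, eff] < alpha_corrected)
      if (length(sig) < min_cluster) next
      comps <- adjacency_components(adjacency, ai[sig])
      for (comp in comps) {
        if (length(comp) >= min_cluster) {
          mask[match(comp, ai), w, eff] <- TRUE
        }
      }
    }
  }
  structure(list(F = Fm, p = pm, mask = mask,
                 alpha_corrected = alpha_corrected,
                 min_cluster = min_cluster, adjacency = adjacency,
                 channels = chans),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("Mass-univariate scan: %d electrodes x %d windows, threshold p < %g, cluster >= %d adjacent electrodes\n",
              dim(x$p)[1L], dim(x$p)[2L], x$alpha_corrected, x$min_cluster))
  for (eff in dimnames(x$mask)[[3L]]) {
    cat(sprintf("  %-12s %d significant cells\n", eff,
                sum(x$mask[, , eff])))
  }
  invisible(x)
}

#' Export a stat map as a tidy table
#'
#' @param x a `stat_map`.
#' @param grid optional scan grid (from [scan_grid()]) supplying window
#'   start times in seconds.
#' @return Data frame with effect, electrode, window (and start/end if
#'   `grid` given), F, p, significant.
#' @export
stat_map_table <- function(x, grid = NULL) {
  effects <- dimnames(x$mask)[[3L]]
  out <- do.call(rbind, lapply(effects, function(eff) {
    df <- expand.grid(electrode = x$channels,
                      window = seq_len(dim(x$p)[2L]),
                      stringsAsFactors = FALSE)
    df$effect <- eff
    df$F <- as.vector(x$F[, , eff])
    df$p <- as.vector(x$p[, , eff])
    df$significant <- as.vector(x$mask[, , eff])
    df
  }))
  if (!is.null(grid)) {
    out$window_start_ms <- grid[out$window, 1L] * 1000
    out$window_end_ms <- grid[out$window, 2L] * 1000
  }
  out[, c("effect", setdiff(names(out), "effect"))]
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value comes from the
#' exact null distribution for small samples without ties and from the
#' t-approximation otherwise (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param exact_n use the exact null distribution for n up to this size.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y, exact_n = 10L) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  rho <- stats::cor(rank(x), rank(y))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) <= exact_n))
  list(rho = unname(rho), p = ct$p.value)
}
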