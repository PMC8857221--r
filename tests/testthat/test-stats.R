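test_that("Welch t handles identity, separation and location shifts", {
  x <- c(1, 2, 3)
  r0 <- welch_t(x, x)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  # p shrinks as the shift grows
  p <- vapply(c(1, 5, 25), function(d) welch_t(x, x + d)$p.value, 1)
  expect_true(all(diff(p) < 0))
  expect_lt(p[3], 1e-4)
  # location invariance: adding a constant to everything changes nothing
  set.seed(8)
  a <- rnorm(6); b <- rnorm(6, 1)
  expect_equal(welch_t(a + 10, b + 10)$p.value, welch_t(a, b)$p.value)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("one-way ANOVA reports the (k-1, N-k) df convention", {
  set.seed(21)
  groups <- replicate(9, rnorm(6), simplify = FALSE)
  r <- anova1(groups)
  expect_equal(r$df, c(8, 45))
  # identical data: F = 0, p = 1
  same <- replicate(3, c(2, 2, 2), simplify = FALSE)
  r0 <- anova1(same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  expect_error(anova1(list(1:3, 5)), "n >= 2")
  # two-group ANOVA is the squared pooled t test
  a <- rnorm(8); b <- rnorm(8, 0.5)
  f <- anova1(list(a, b))$statistic
  t2 <- stats::t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(f, unname(t2), tolerance = 1e-10)
})

test_that("type-I error of the 5% tests is calibrated under the null", {
  # designs chosen so the true rejection rate sits near 0.05: Welch at
  # n = 15/15 (0.0498), 4 x 8 ANOVA (0.0508), exact rank-sum at n = 8/8
  # where the largest attainable p below 0.05 is 0.0499
  set.seed(101)
  reps <- 2000
  welch_rej <- mean(replicate(reps,
    welch_t(rnorm(15), rnorm(15))$p.value < 0.05))
  expect_gt(welch_rej, 0.04); expect_lt(welch_rej, 0.06)
  anova_rej <- mean(replicate(reps,
    anova1(replicate(4, rnorm(8), simplify = FALSE))$p.value < 0.05))
  expect_gt(anova_rej, 0.04); expect_lt(anova_rej, 0.06)
  wil_rej <- mean(replicate(reps,
    wilcoxon_ranksum(rnorm(8), rnorm(8))$p.value < 0.05))
  expect_gt(wil_rej, 0.04); expect_lt(wil_rej, 0.06)
})

test_that("Tukey HSD letters group means as expected", {
  set.seed(5)
  base <- lapply(1:3, function(i) rnorm(8, 0, 0.5))
  names(base) <- c("a1", "a2", "a3")
  r <- tukey_hsd(base)
  expect_true(all(r$letters == r$letters[1]))  # one shared letter
  shifted <- c(base, list(far = rnorm(8, 30, 0.5)))
  r2 <- tukey_hsd(shifted)
  expect_false(any(grepl(r2$letters[["far"]],
                         r2$letters[c("a1", "a2", "a3")], fixed = TRUE)))
  expect_equal(nrow(r2$pairwise), choose(4, 2))
})

test_that("Tukey pairwise p values agree with a permutation oracle", {
  set.seed(77)
  groups <- list(g1 = rnorm(6, 0), g2 = rnorm(6, 0.4), g3 = rnorm(6, 2))
  r <- tukey_hsd(groups)
  # permutation distribution of the studentized range statistic:
  # permute observations, recompute max pairwise |mean diff| / SE
  obs <- unlist(groups); lab <- rep(1:3, each = 6)
  qstat <- function(values) {
    m <- tapply(values, lab, mean)
    s2 <- sum((values - ave(values, lab))^2) / (length(values) - 3)
    abs(outer(m, m, "-")) / sqrt(s2 / 6)
  }
  q_obs <- qstat(obs)
  nperm <- 4000
  exceed <- matrix(0, 3, 3)
  for (b in seq_len(nperm)) {
    q_b <- max(qstat(sample(obs)))
    exceed <- exceed + (q_b >= q_obs)
  }
  p_perm <- exceed / nperm
  for (row in seq_len(nrow(r$pairwise))) {
    nm <- strsplit(r$pairwise$comparison[row], "-")[[1]]
    i <- match(nm[1], names(groups)); j <- match(nm[2], names(groups))
    # agree within Monte-Carlo error (3 SE, floored for tiny p)
    mc_se <- sqrt(p_perm[i, j] * (1 - p_perm[i, j]) / nperm)
    expect_lt(abs(r$pairwise$p.adj[row] - p_perm[i, j]),
              max(3 * mc_se, 0.02))
  }
})

test_that("exact Wilcoxon matches enumeration and its distribution sums to 1", {
  # fully separated n = 3 vs 3: only 1 of choose(6,3)=20 assignments per
  # tail is as extreme -> two-sided p = 2/20 = 0.1
  r <- wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p.value, 0.1)
  # all attainable U values have probabilities summing to 1
  expect_equal(sum(stats::dwilcox(0:9, 3, 3)), 1, tolerance = 1e-12)
  # identical samples -> maximal p
  expect_gte(wilcoxon_ranksum(c(1, 2, 3), c(1.5, 2.5, 0.5))$p.value, 0.7)
  expect_warning(r2 <- wilcoxon_ranksum(c(2, 2), c(2, 2)), "tied")
  expect_equal(r2$p.value, 1)
})

test_that("normal approximation converges to the exact rank-sum p", {
  set.seed(13)
  x <- rnorm(50); y <- rnorm(50, 0.3)
  p_exact <- wilcoxon_ranksum(x, y, exact = TRUE)$p.value
  p_norm <- wilcoxon_ranksum(x, y, exact = FALSE)$p.value
  expect_lt(abs(p_exact - p_norm), 0.005)
})

test_that("the assumption gate routes clean data parametric, violations nonparametric", {
  set.seed(30)
  clean <- replicate(3, rnorm(80), simplify = FALSE)
  expect_equal(stat_gate(clean)$decision, "parametric")
  # lognormal heteroscedastic: nonparametric in >= 95% of seeded runs
  hits <- mean(replicate(100, {
    g <- list(rlnorm(30, 0, 1), rlnorm(30, 0, 0.2) * 5)
    stat_gate(g)$decision == "nonparametric"
  }))
  expect_gte(hits, 0.95)
  expect_warning(g2 <- stat_gate(list(c(1, 2), c(3, 4))), "n < 3")
  expect_equal(g2$decision, "nonparametric")
})

test_that("the arcsine transform is the asin-sqrt map on [0, 1]", {
  expect_equal(arcsine_transform(c(0, 1)), c(0, pi / 2))
  expect_equal(arcsine_transform(0.25), pi / 6)
  x <- seq(0, 1, by = 0.05)
  expect_true(all(diff(arcsine_transform(x)) > 0))
  expect_error(arcsine_transform(1.2), "\\[0, 1\\]")
})
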