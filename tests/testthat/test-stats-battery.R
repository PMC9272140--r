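test_that("signed-rank exact branch matches full sign enumeration", {
  t1 <- wilcoxon_signed_rank(c(-1, -1, -1))
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p, 0.25)

  expect_equal(wilcoxon_signed_rank(c(-1, 1))$p, 1.0)

  set.seed(12)
  for (k in 1:20) {
    n <- sample(4:11, 1)
    d <- round(rnorm(n, 0.3), 2)
    d <- d[d != 0]
    if (length(d) < 2) next
    got <- wilcoxon_signed_rank(d)
    orc <- oracle_signed_rank(d)
    expect_equal(got$statistic, orc$W)
    expect_equal(got$p, orc$p, tolerance = 1e-12)
  }
  # zeros are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, -1, -1, -1, 0))$p, 0.25)
})

test_that("signed-rank normal approximation tracks the exact null at n = 30", {
  set.seed(3)
  d <- rnorm(30, 0.25)  # continuous, ties-free
  approx <- wilcoxon_signed_rank(d)
  expect_match(approx$method, "normal")
  r <- rank(abs(d))
  null <- gazepref:::signed_rank_null(as.integer(round(2 * r)))
  w2 <- round(2 * approx$statistic)
  exact <- min(1, 2 * min(sum(null[seq_len(w2 + 1)]),
                          sum(null[(w2 + 1):length(null)])))
  expect_lt(abs(approx$p - exact), 0.005)
})

test_that("rank-sum exact branch matches rank-assignment enumeration", {
  t1 <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p, 2 / 6, tolerance = 1e-12)

  same <- wilcoxon_rank_sum(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p, 1.0)

  set.seed(8)
  for (k in 1:15) {
    na <- sample(3:6, 1); nb <- sample(3:8, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.5)  # continuous: no ties
    got <- wilcoxon_rank_sum(a, b)
    orc <- oracle_rank_sum(a, b)
    expect_equal(got$statistic, orc$U)
    expect_equal(got$p, orc$p, tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum detects a 1-SD shift with good power", {
  set.seed(21)
  hits <- mean(replicate(300, {
    wilcoxon_rank_sum(rnorm(50), rnorm(50, 1))$p < 0.05
  }))
  expect_gt(hits, 0.8)
})

test_that("chi-squared statistics match hand computation", {
  t1 <- chi2_proportion(78, 100, 0.5)
  expect_equal(t1$statistic, 31.36)
  expect_equal(t1$df, 1)

  t2 <- chi2_proportion(50, 100, 0.5)
  expect_equal(t2$statistic, 0)
  expect_equal(t2$p, 1)

  tab <- rbind(c(20, 30, 10), c(20, 30, 10))
  expect_equal(chi2_contingency(tab)$statistic, 0)
  expect_equal(chi2_contingency(tab)$df, 2)
  # agreement with the textbook Pearson formula on an arbitrary table
  tab2 <- rbind(c(12, 5), c(7, 16))
  exp2 <- outer(rowSums(tab2), colSums(tab2)) / sum(tab2)
  expect_equal(chi2_contingency(tab2)$statistic, sum((tab2 - exp2)^2 / exp2))

  expect_error(chi2_proportion(1, 10, 0.01), "expected count")
})

test_that("factorial ANOVA reproduces hand-computed sums of squares", {
  a <- anova_factorial(c(1, 2, 3, 3, 4, 5),
                       data.frame(g = rep(c("a", "b"), each = 3)))
  expect_equal(a$sum_sq, 6)   # SSB: 3*(2-3)^2 + 3*(4-3)^2
  expect_equal(a$df, 1)
  expect_equal(a$F, 6)        # SSW = 4 on 4 df
  expect_equal(attr(a, "df_residual"), 4)

  # balanced 2x2 with exactly additive cell means (within-cell deviations
  # of +/-1 keep residual df while leaving cell means additive):
  # interaction SS is exactly 0
  d <- expand.grid(f1 = c("a", "b"), f2 = c("x", "y"), rep = 1:2)
  d$y <- ifelse(d$f1 == "b", 2, 0) + ifelse(d$f2 == "y", 5, 0) +
    ifelse(d$rep == 1, 1, -1)
  a2 <- anova_factorial(d$y, d[c("f1", "f2")], include_interactions = TRUE)
  expect_equal(a2$sum_sq[a2$effect == "f1:f2"], 0, tolerance = 1e-12)

  # one-factor F equals the squared two-sample t
  set.seed(5)
  x <- rnorm(10); y <- rnorm(12, 0.8)
  a3 <- anova_factorial(c(x, y), data.frame(g = rep(c("a", "b"), c(10, 12))))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a3$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a3$p, tt$p.value, tolerance = 1e-10)

  # empty cell with interactions requested is an informative error
  d_bad <- d[!(d$f1 == "a" & d$f2 == "x"), ]
  expect_error(anova_factorial(d_bad$y, d_bad[c("f1", "f2")],
                               include_interactions = TRUE), "empty cell")
  expect_error(anova_factorial(1:5, data.frame(g = rep("a", 5))), "fewer than 2")
})

test_that("Tukey HSD degenerates properly and matches the studentized-range CDF", {
  set.seed(9)
  # identical groups: all adjusted p near 1
  y0 <- rep(rnorm(8), 3) + rnorm(24, 0, 1e-6)
  g3 <- rep(c("a", "b", "c"), each = 8)
  a0 <- anova_factorial(y0, data.frame(g = g3))
  expect_true(all(tukey_hsd(a0)$p_adj > 0.99))

  # two groups: adjusted p equals the unadjusted pooled t-test p
  y2 <- rnorm(16, rep(c(0, 1), each = 8))
  g2 <- rep(c("a", "b"), each = 8)
  a2 <- anova_factorial(y2, data.frame(g = g2))
  tk2 <- tukey_hsd(a2)
  tt <- t.test(y2[g2 == "b"], y2[g2 == "a"], var.equal = TRUE)
  expect_equal(tk2$p_adj, tt$p.value, tolerance = 1e-8)

  # three groups: adjusted p from an independent studentized-range computation
  y3 <- rnorm(24, rep(c(0, 0.5, 1.5), each = 8))
  a3 <- anova_factorial(y3, data.frame(g = rep(c("a", "b", "c"), each = 8)))
  tk3 <- tukey_hsd(a3)
  mse <- sum(resid(attr(a3, "fit"))^2) / attr(a3, "df_residual")
  means <- tapply(y3, rep(c("a", "b", "c"), each = 8), mean)
  for (i in seq_len(nrow(tk3))) {
    pair <- strsplit(tk3$pair[i], "-")[[1]]
    q_obs <- abs(means[pair[1]] - means[pair[2]]) / sqrt(mse / 8)
    p_hand <- stats::ptukey(q_obs, 3, attr(a3, "df_residual"), lower.tail = FALSE)
    expect_equal(tk3$p_adj[i], unname(p_hand), tolerance = 1e-4)
  }
  expect_error(tukey_hsd(list()), "anova_factorial")
})

test_that("Pearson r handles exact and degenerate cases; p matches a permutation oracle", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(x, x)$statistic, 1)
  expect_equal(pearson_r(x, -x)$statistic, -1)
  expect_error(pearson_r(x, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")

  set.seed(14)
  x <- rnorm(10); y <- 0.6 * x + rnorm(10)
  got <- pearson_r(x, y)
  r_obs <- abs(cor(x, y))
  perm <- mean(replicate(1e5, abs(cor(x, sample(y)))) >= r_obs - 1e-12)
  expect_lt(abs(got$p - perm), 0.02)
})

test_that("every battery p-value is two-tailed and in [0, 1]", {
  set.seed(30)
  results <- list(
    wilcoxon_signed_rank(rnorm(12, 1)),
    wilcoxon_signed_rank(rnorm(40, 0.2)),
    wilcoxon_rank_sum(rnorm(6), rnorm(8, 2)),
    wilcoxon_rank_sum(rnorm(30), rnorm(30, 0.1)),
    chi2_proportion(60, 100, 0.5),
    pearson_r(rnorm(20), rnorm(20)))
  for (t in results) {
    expect_gte(t$p, 0)
    expect_lte(t$p, 1)
  }
  # two-tailed symmetry: mirrored effects give identical p
  d <- c(0.5, 1.2, -0.3, 0.8, 1.5, 0.9, 1.8)
  expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_signed_rank(-d)$p)
  a <- c(1.2, 2.5, 3.1); b <- c(4.0, 5.2, 6.3)
  expect_equal(wilcoxon_rank_sum(a, b)$p, wilcoxon_rank_sum(b, a)$p)
  expect_equal(chi2_proportion(30, 100, 0.5)$p, chi2_proportion(70, 100, 0.5)$p)
})
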