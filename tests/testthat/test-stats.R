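# Group statistics: effect sizes, tests, ROC/Youden, screening. Expected
# values come from printed cohort summaries (verified by hand from the
# published tables), closed forms, or independent oracles computed here.

test_that("pooled-SD Cohen's d reproduces the published effect sizes", {
  ref <- sle_reference_tables()$mri
  d <- mapply(function(i) {
    cohens_d_pooled(group_summary(ref$n_sle[i], ref$mean_sle[i], ref$sd_sle[i]),
                    group_summary(ref$n_hc[i], ref$mean_hc[i], ref$sd_hc[i]))
  }, seq_len(nrow(ref)))
  expect_equal(round(d, 2), ref$published_d)
})

test_that("Cohen's d basics: antisymmetry, zero for identical groups, errors", {
  a <- group_summary(20, 5, 2); b <- group_summary(15, 3, 1.5)
  expect_equal(cohens_d_pooled(a, b), -cohens_d_pooled(b, a))
  expect_equal(cohens_d_pooled(a, a), 0)
  expect_equal(cohens_d_pooled(group_summary(5, 1, 0), group_summary(5, 1, 0)), 0)
  expect_error(cohens_d_pooled(group_summary(5, 1, 0), group_summary(5, 2, 0)),
               "infinite")
})

test_that("summary-based Student t matches published p and stats::t.test on raw data", {
  # published BrainAGE z row: 0.6 (1.1) n=70 vs 0 (1.0) n=24 -> p rounds to 0.02
  tt <- two_sample_t(group_summary(70, 0.6, 1.1), group_summary(24, 0, 1.0))
  expect_equal(round(tt$p_value, 2), 0.02)
  expect_equal(tt$df, 92)

  set.seed(41)
  x <- rnorm(25, 1); y <- rnorm(18, 0.2, 1.4)
  expect_equal(two_sample_t(x, y, "student")$p_value,
               t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(two_sample_t(x, y, "welch")$p_value, t.test(x, y)$p.value)
  expect_equal(two_sample_t(x, x)$statistic, 0)
  expect_equal(two_sample_t(x, x)$p_value, 1)
})

test_that("Student t agrees with a permutation oracle", {
  set.seed(99)
  x <- rnorm(20, 0.5); y <- rnorm(20)
  obs <- abs(two_sample_t(x, y)$statistic)
  pooled <- c(x, y)
  perm <- replicate(40000, {
    idx <- sample.int(40, 20)
    abs(two_sample_t(pooled[idx], pooled[-idx])$statistic)
  })
  expect_lt(abs(mean(perm >= obs) - two_sample_t(x, y)$p_value), 0.015)
})

test_that("Mann-Whitney: exhaustive-enumeration oracle for a 3v3 design", {
  # enumerate all C(6,3) = 20 assignments of {1..6} to x
  combos <- utils::combn(6, 3)
  u_stat <- function(x, y) sum(outer(x, y, `>`)) # count of x > y pairs
  u_all <- apply(combos, 2, function(ix) u_stat((1:6)[ix], (1:6)[-ix]))
  u_obs <- u_stat(1:3, 4:6)
  p_exact <- mean(u_all <= u_obs | u_all >= (9 - u_obs)) # two-sided
  expect_equal(p_exact, 0.1)

  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p_value, 0.1)

  expect_equal(mann_whitney(1:10, 1:10)$p_value, 1)
  set.seed(3)
  expect_lt(mann_whitney(rnorm(60), rnorm(60, 3))$p_value, 0.001)
})

test_that("one-way ANOVA: F = t^2 for two groups, identical groups give p = 1", {
  set.seed(11)
  g <- list(a = rnorm(12, 1), b = rnorm(15))
  av <- anova_oneway(g, "anova")
  tt <- two_sample_t(g$a, g$b)
  expect_equal(av$statistic, tt$statistic^2)
  expect_equal(av$p_value, tt$p_value)

  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(anova_oneway(same, "anova")$statistic, 0)
  expect_equal(anova_oneway(same, "anova")$p_value, 1)

  kw <- anova_oneway(g, "kruskal")
  expect_equal(kw$p_value, kruskal.test(list(g$a, g$b))$p.value)
})

test_that("ANOVA p agrees with a permutation oracle on three shifted normals", {
  set.seed(5)
  g <- list(a = rnorm(12), b = rnorm(12, 0.8), c = rnorm(12, 0.4))
  obs <- anova_oneway(g, "anova")$statistic
  pooled <- unlist(g)
  lab <- rep(1:3, each = 12)
  perm <- replicate(20000, {
    sh <- sample(lab)
    anova_oneway(split(pooled, sh), "anova")$statistic
  })
  expect_lt(abs(mean(perm >= obs) - anova_oneway(g, "anova")$p_value), 0.02)
})

test_that("pairwise follow-ups are Bonferroni-adjusted", {
  set.seed(21)
  g <- list(a = rnorm(10), b = rnorm(10, 3), c = rnorm(10))
  res <- anova_oneway(g, "anova", pairwise = TRUE)
  expect_equal(nrow(res$pairwise), 3)
  raw_ab <- two_sample_t(g$a, g$b)$p_value
  expect_equal(res$pairwise$p_adj[res$pairwise$a == "a" &
                                  res$pairwise$b == "b"],
               min(1, raw_ab * 3))
})

test_that("ANCOVA recovers constructed group offsets and age slope exactly", {
  set.seed(8)
  n <- 60
  grp <- rep(c("x", "y", "z"), each = n / 3)
  ages <- runif(n, 20, 60)
  offs <- c(x = 0, y = 2, z = -1)
  vals <- 5 + 0.3 * ages + offs[grp] # no noise: exact recovery
  res <- ancova_age_adjusted(vals, grp, ages)
  expect_equal(res$age_slope, 0.3, tolerance = 1e-10)
  adj <- res$adjusted_means
  expect_equal(unname(adj["y"] - adj["x"]), 2, tolerance = 1e-10)
  expect_equal(unname(adj["z"] - adj["x"]), -1, tolerance = 1e-10)

  # zero age slope in the generating model: adjusted means = raw means
  vals2 <- 10 + offs[grp]
  res2 <- ancova_age_adjusted(vals2 + rnorm(n, 0, 1e-8), grp, ages)
  expect_equal(unname(res2$adjusted_means),
               unname(as.vector(tapply(vals2, grp, mean)[c("x", "y", "z")])),
               tolerance = 1e-4)
})

test_that("ANCOVA matches a normal-equations oracle with noise", {
  set.seed(13)
  n <- 45
  grp <- factor(rep(c("a", "b", "c"), each = 15))
  ages <- runif(n, 20, 60)
  vals <- 2 + 0.1 * ages + c(a = 0, b = 1.5, c = 3)[grp] + rnorm(n, 0, 0.5)
  res <- ancova_age_adjusted(vals, grp, ages)
  # brute-force normal equations for value ~ 1 + age + I(b) + I(c)
  Xd <- cbind(1, ages, grp == "b", grp == "c")
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% vals)
  adj_oracle <- beta[1] + beta[2] * mean(ages) + c(0, beta[3], beta[4])
  expect_equal(unname(res$adjusted_means), unname(adj_oracle),
               tolerance = 1e-10)
})

test_that("correlation tests: identities and sampling behaviour", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -x^3, "spearman")$r, -1)
  expect_error(correlate(x, rep(1, 5)), "zero variance")

  set.seed(31)
  inside <- replicate(10, {
    z <- MASS::mvrnorm(200, c(0, 0), matrix(c(1, .5, .5, 1), 2))
    r <- correlate(z[, 1], z[, 2])$r
    r > 0.35 && r < 0.62
  })
  expect_gte(sum(inside), 9)
})

test_that("2x2 chi-square reproduces the published DMARD result", {
  tab <- matrix(c(19, 22, 5, 24), 2, 2)
  res <- chi_square_2x2(tab)
  expect_equal(round(res$p_value, 2), 0.01)
  expect_equal(round(res$odds_ratio, 2), 4.15)
  expect_equal(res$p_value, chisq.test(tab, correct = FALSE)$p.value)

  flat <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
})

test_that("Youden cutoff: separation, brute-force oracle, monotone invariance", {
  # perfectly separated scores: J = 1, threshold at the gap midpoint
  r <- roc_youden(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(r$youden, 1)
  expect_equal(r$threshold, 6.5)
  expect_equal(r$auc, 1)

  # exhaustive oracle: evaluate J at every candidate rule directly
  oracle_max_j <- function(scores, outcome) {
    cand <- c(-Inf, sort(unique(scores)), Inf)
    best <- -Inf
    for (t in cand) {
      sens <- mean(scores[outcome] >= t)
      spec <- mean(scores[!outcome] < t)
      best <- max(best, sens + spec - 1)
    }
    best
  }
  set.seed(17)
  for (i in 1:1000) {
    n <- sample(8:40, 1)
    sc <- round(rnorm(n), sample(0:2, 1)) # ties included
    out <- runif(n) < 0.4
    if (!any(out) || all(out)) next
    r <- roc_youden(sc, out)
    expect_equal(r$youden, oracle_max_j(sc, out), tolerance = 1e-12)
  }

  # strictly monotone transform: J and the selected partition are invariant
  set.seed(23)
  sc <- rnorm(50); out <- runif(50) < 0.5
  r1 <- roc_youden(sc, out)
  r2 <- roc_youden(exp(sc), out)
  expect_equal(r1$youden, r2$youden)
  expect_equal(sc >= r1$threshold, exp(sc) >= r2$threshold)
})

test_that("Youden cutoff agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (i in 1:25) {
    sc <- rnorm(60); out <- c(rep(TRUE, 30), rep(FALSE, 30))
    sc[out] <- sc[out] + 1
    r <- roc_youden(sc, out)
    pr <- pROC::roc(out, sc, direction = "<", quiet = TRUE)
    co <- pROC::coords(pr, "best", best.method = "youden",
                       ret = c("sensitivity", "specificity"))
    expect_equal(r$youden, max(co$sensitivity + co$specificity - 1),
                 tolerance = 1e-12)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  }
})

test_that("screening: collinear duplicates dropped, spurious entry rate low", {
  set.seed(37)
  n <- 200
  d <- data.frame(a = rnorm(n))
  d$b <- d$a # r = 1 duplicate
  d$c <- rnorm(n)
  out <- d$a + rnorm(n) > 0
  rep1 <- screen_and_fit_logistic(d, out)
  expect_true("a" %in% rep1$entered)
  expect_true("b" %in% rep1$excluded_collinear)
  expect_false("b" %in% rep1$entered)

  # outcome independent of 10 covariates: few pass p < 0.2 by chance
  set.seed(43)
  spurious <- replicate(20, {
    dd <- as.data.frame(matrix(rnorm(n * 10), n))
    sum(screen_and_fit_logistic(dd, runif(n) < 0.5)$univariate$p_value < 0.2)
  })
  expect_lt(mean(spurious), 4) # expectation 2 of 10
})

test_that("screened logistic model recovers a strong covariate's odds ratio", {
  set.seed(47)
  hits <- replicate(10, {
    n <- 200
    x <- rnorm(n)
    p <- plogis(-0.5 + log(6) * x)
    out <- runif(n) < p
    d <- data.frame(x = x, noise1 = rnorm(n), noise2 = rnorm(n))
    rep <- screen_and_fit_logistic(d, out)
    row <- rep$model[rep$model$variable == "x", ]
    nrow(row) == 1 && row$or_ci_low <= 6 && 6 <= row$or_ci_high
  })
  expect_gte(sum(hits), 9)
})

test_that("null p-values are uniform for the implemented tests", {
  set.seed(53)
  nsim <- 2000
  ks_ok <- function(p) suppressWarnings(stats::ks.test(p, "punif"))$p.value > 0.001
  p_t <- replicate(nsim, two_sample_t(rnorm(15), rnorm(15))$p_value)
  p_mw <- replicate(nsim, mann_whitney(rnorm(30), rnorm(30))$p_value)
  p_av <- replicate(nsim, anova_oneway(list(rnorm(15), rnorm(15),
                                            rnorm(15)), "anova")$p_value)
  p_kw <- replicate(nsim, anova_oneway(list(rnorm(15), rnorm(15),
                                            rnorm(15)), "kruskal")$p_value)
  p_r <- replicate(nsim, correlate(rnorm(30), rnorm(30))$p_value)
  expect_true(ks_ok(p_t))
  expect_true(ks_ok(p_mw))
  expect_true(ks_ok(p_av))
  expect_true(ks_ok(p_kw))
  expect_true(ks_ok(p_r))
})
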